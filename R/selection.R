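# Information-criterion model selection over a grid of candidate
# (K, R, d) specifications.

#' Number of free parameters of a mixRHLP specification
#'
#' `(K-1)` mixing proportions, `2 K (R-1)` switching coefficients (the
#' reference regime is pinned), `K R (d+1)` regression coefficients, and
#' `K R` variances (1 when homoskedastic).
#'
#' @param spec a [model_spec].
#' @return integer count.
#' @examples
#' count_parameters(model_spec(2, 3, 1))  # 27
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "rhlp_spec"))
  v <- if (spec$variance == "heteroskedastic") spec$K * spec$R else 1L
  as.integer((spec$K - 1L) + 2L * spec$K * (spec$R - 1L) +
               spec$K * spec$R * (spec$d + 1L) + v)
}

#' Information criteria from a maximized log-likelihood
#'
#' With effective sample size `n = N_t * N_p` and `q` free parameters:
#' `BIC = log(n) q - 2 l`, `saBIC = log((n+2)/24) q - 2 l` (Sclove's
#' sample-size adjustment), `AIC = 2 q - 2 l`, and
#' `AICc = AIC + (2 q^2 + 2 q) / (n - q - 1)`. Smaller is better. `AICc` is
#' `NA` when its denominator is not positive.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters `q`.
#' @param n_times,n_subjects grid length and subject count.
#' @return named list with `BIC`, `saBIC`, `AIC`, `AICc`.
#' @export
information_criteria <- function(loglik, n_params, n_times, n_subjects) {
  n <- n_times * n_subjects
  q <- n_params
  aic <- 2 * q - 2 * loglik
  list(
    BIC = log(n) * q - 2 * loglik,
    saBIC = log((n + 2) / 24) * q - 2 * loglik,
    AIC = aic,
    AICc = if (n - q - 1 > 0) aic + (2 * q^2 + 2 * q) / (n - q - 1)
           else NA_real_
  )
}

#' Fit and rank a grid of candidate models
#'
#' Fits every combination of the supplied `K`, `R` and `d` values to the
#' panel, records failures without aborting, and ranks the surviving fits
#' under each criterion (ascending; ties broken toward smaller
#' `(K, R, d)` lexicographically).
#'
#' @param data a complete [panel_data].
#' @param Ks,Rs,ds integer vectors of candidate values; the defaults give
#'   the 32-model grid `K = 1..4, R = 1..4, d = 1..2`.
#' @param variance variance structure used for every fit.
#' @param controls a [fit_controls].
#' @param verbose print a line per fitted model.
#' @return An object of class `selection_report`: list with `table` (data
#'   frame of spec, loglik, n_params, criteria, ranks), `fits` (list of
#'   `rhlp_fit` or `NULL` for failures), `best` (per-criterion winning row
#'   index).
#' @export
select_models <- function(data, Ks = 1:4, Rs = 1:4, ds = 1:2,
                          variance = "heteroskedastic",
                          controls = fit_controls(), verbose = FALSE) {
  require_complete(data)
  grid <- expand.grid(K = sort(Ks), R = sort(Rs), d = sort(ds),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$K, grid$R, grid$d), , drop = FALSE]
  n <- nrow(grid)
  fits <- vector("list", n)
  tab <- data.frame(K = grid$K, R = grid$R, d = grid$d,
                    loglik = NA_real_, n_params = NA_integer_,
                    BIC = NA_real_, saBIC = NA_real_, AIC = NA_real_,
                    AICc = NA_real_, error = NA_character_)
  for (m in seq_len(n)) {
    spec <- model_spec(grid$K[m], grid$R[m], grid$d[m], variance)
    fit <- tryCatch(fit_rhlpmix(data, spec, controls),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tab$error[m] <- conditionMessage(fit)
      next
    }
    fits[[m]] <- fit
    tab$loglik[m] <- fit$loglik
    tab$n_params[m] <- fit$n_params
    tab[m, c("BIC", "saBIC", "AIC", "AICc")] <- unlist(fit$criteria)
    if (verbose)
      message(sprintf("K=%d R=%d d=%d: loglik %.2f BIC %.2f",
                      spec$K, spec$R, spec$d, fit$loglik, fit$criteria$BIC))
  }
  if (all(is.na(tab$loglik)))
    stop("every model in the grid failed to fit", call. = FALSE)
  for (cr in c("BIC", "saBIC", "AIC", "AICc")) {
    rk <- rep(NA_integer_, n)
    ok <- which(!is.na(tab[[cr]]))
    ord <- ok[order(tab[[cr]][ok], tab$K[ok], tab$R[ok], tab$d[ok])]
    rk[ord] <- seq_along(ord)
    tab[[paste0("rank_", cr)]] <- rk
  }
  best <- vapply(c("BIC", "saBIC", "AIC", "AICc"), function(cr)
    which(tab[[paste0("rank_", cr)]] == 1L)[1], integer(1))
  structure(list(table = tab, fits = fits, best = best,
                 variance = variance),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("model grid: %d candidates, %d fitted\n",
              nrow(x$table), sum(!is.na(x$table$loglik))))
  for (cr in c("BIC", "saBIC", "AIC", "AICc")) {
    b <- x$best[[cr]]
    if (is.na(b)) next
    cat(sprintf("  best by %-5s: K=%d R=%d d=%d (%.3f)\n", cr,
                x$table$K[b], x$table$R[b], x$table$d[b], x$table[[cr]][b]))
  }
  invisible(x)
}

#' Rank of a specification under a criterion
#'
#' @param report a [select_models()] result.
#' @param K,R,d the specification to look up.
#' @param criterion one of `"BIC"`, `"saBIC"`, `"AIC"`, `"AICc"`.
#' @return integer rank (1 = smallest criterion value), `NA` if the spec
#'   failed to fit.
#' @export
rank_of <- function(report, K, R, d, criterion = "BIC") {
  stopifnot(inherits(report, "selection_report"))
  i <- which(report$table$K == K & report$table$R == R & report$table$d == d)
  if (!length(i)) stop("spec not in the fitted grid", call. = FALSE)
  report$table[[paste0("rank_", criterion)]][i[1]]
}

#' Parsimony-window model choice
#'
#' Among the `window` best models under a criterion, returns the row index
#' of the one with the fewest free parameters (ties toward smaller
#' `(K, R, d)`), mirroring the practice of preferring a more parsimonious
#' model whose criterion value is close to the minimum.
#'
#' @inheritParams rank_of
#' @param window how many top-ranked models to consider (default 1, i.e.
#'   the plain criterion minimum).
#' @return row index into `report$table`.
#' @export
parsimony_pick <- function(report, criterion = "BIC", window = 1L) {
  stopifnot(inherits(report, "selection_report"), window >= 1)
  tab <- report$table
  rk <- tab[[paste0("rank_", criterion)]]
  cand <- which(!is.na(rk) & rk <= window)
  cand[order(tab$n_params[cand], tab$K[cand], tab$R[cand], tab$d[cand])][1]
}
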