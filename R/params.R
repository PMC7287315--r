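#' Candidate model structure
#'
#' A mixRHLP model is indexed by the number of subject clusters `K`, the
#' number of within-subject regimes `R`, the polynomial order `d` of the
#' per-regime trend, and whether each (cluster, regime) pair carries its own
#' residual variance.
#'
#' @param K integer >= 1, number of clusters.
#' @param R integer >= 1, number of regimes per cluster.
#' @param d integer >= 0, polynomial order of the regime trends.
#' @param variance `"heteroskedastic"` (per-regime variances, the default)
#'   or `"homoskedastic"` (one pooled variance).
#' @return An object of class `rhlp_spec`.
#' @examples
#' model_spec(K = 2, R = 3, d = 1)
#' @export
model_spec <- function(K, R, d,
                       variance = c("heteroskedastic", "homoskedastic")) {
  variance <- match.arg(variance)
  K <- as.integer(K); R <- as.integer(R); d <- as.integer(d)
  if (K < 1L || R < 1L || d < 0L)
    stop("need K >= 1, R >= 1, d >= 0", call. = FALSE)
  structure(list(K = K, R = R, d = d, variance = variance),
            class = "rhlp_spec")
}

#' @export
print.rhlp_spec <- function(x, ...) {
  cat(sprintf("mixRHLP spec: K = %d clusters, R = %d regimes, degree d = %d, %s variances (%d free parameters)\n",
              x$K, x$R, x$d, x$variance, count_parameters(x)))
  invisible(x)
}

#' Full parameter set of a mixRHLP model
#'
#' Holds the cluster mixing proportions `alpha`, the logistic
#' regime-switching coefficients `omega` (intercept and time slope per
#' cluster and regime, with the reference regime -- the last one -- pinned
#' at zero), the polynomial regression coefficients `beta`, and the residual
#' variances `sigma2`.
#'
#' @param alpha length-`K` probability vector of cluster proportions.
#' @param omega `K x R x 2` array; `omega[k, r, ]` is `(intercept, slope)`
#'   of regime `r`'s log-odds against the reference regime `R`, whose row
#'   must be zero.
#' @param beta `K x R x (d+1)` array of polynomial coefficients
#'   (constant term first).
#' @param sigma2 `K x R` matrix of positive residual variances; constant
#'   when the spec is homoskedastic.
#' @param spec the [model_spec] the dimensions must agree with.
#' @return An object of class `rhlp_params`.
#' @export
rhlp_params <- function(alpha, omega, beta, sigma2, spec) {
  if (is.matrix(sigma2)) sigma2 <- sigma2 else
    sigma2 <- matrix(sigma2, spec$K, spec$R)
  out <- structure(
    list(alpha = as.numeric(alpha), omega = omega, beta = beta,
         sigma2 = sigma2, spec = spec),
    class = "rhlp_params"
  )
  validate_params(out)
  out
}

validate_params <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "rhlp_params"))
  s <- p$spec
  if (length(p$alpha) != s$K || any(p$alpha < -tol) || any(p$alpha > 1 + tol) ||
      abs(sum(p$alpha) - 1) > 1e-8)
    stop("`alpha` must be a length-K probability vector summing to 1",
         call. = FALSE)
  if (!identical(dim(p$omega), c(s$K, s$R, 2L)) &&
      !identical(dim(p$omega), as.integer(c(s$K, s$R, 2))))
    stop("`omega` must be K x R x 2", call. = FALSE)
  if (!all(is.finite(p$omega)))
    stop("`omega` must be finite", call. = FALSE)
  if (any(abs(p$omega[, s$R, , drop = FALSE]) > 0))
    stop("the reference regime's omega row must be zero", call. = FALSE)
  if (!identical(dim(p$beta), as.integer(c(s$K, s$R, s$d + 1))))
    stop("`beta` must be K x R x (d+1)", call. = FALSE)
  if (!all(is.finite(p$beta))) stop("`beta` must be finite", call. = FALSE)
  if (!identical(dim(p$sigma2), as.integer(c(s$K, s$R))) ||
      any(!is.finite(p$sigma2)) || any(p$sigma2 <= 0))
    stop("`sigma2` must be a K x R matrix of positive values", call. = FALSE)
  if (s$variance == "homoskedastic" &&
      diff(range(p$sigma2)) > 1e-12 * max(p$sigma2))
    stop("homoskedastic spec requires a single shared variance", call. = FALSE)
  invisible(p)
}

#' @export
print.rhlp_params <- function(x, ...) {
  print(x$spec)
  cat("alpha:", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  for (k in seq_len(x$spec$K)) {
    cat(sprintf("cluster %d (sigma: %s)\n", k,
                paste(signif(sqrt(x$sigma2[k, ]), 4), collapse = ", ")))
    for (r in seq_len(x$spec$R)) {
      cat(sprintf("  regime %d: beta = (%s), omega = (%s)\n", r,
                  paste(signif(x$beta[k, r, ], 4), collapse = ", "),
                  paste(signif(x$omega[k, r, ], 4), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Benchmark two-cluster, three-regime generative model
#'
#' The true parameter values used throughout the package's Monte Carlo
#' study: two equally weighted clusters, three linear regimes each, with
#' regime membership drifting over `[0, 1]` through the logistic switching
#' process, and a common residual standard deviation `sigma` across all
#' (cluster, regime) pairs. The two clusters' trend lines interleave so the
#' clusters are hard to separate by eye.
#'
#' @param sigma residual standard deviation; the study's levels are 0.10,
#'   0.15 and 0.20 (other positive values are accepted with a warning).
#' @return an [rhlp_params] for the spec `model_spec(2, 3, 1)`.
#' @examples
#' benchmark_params(0.1)
#' @export
benchmark_params <- function(sigma = 0.10) {
  if (!isTRUE(sigma > 0)) stop("`sigma` must be positive", call. = FALSE)
  if (!any(abs(sigma - c(0.10, 0.15, 0.20)) < 1e-12))
    warning("`sigma` is outside the study's levels {0.10, 0.15, 0.20}")
  spec <- model_spec(K = 2, R = 3, d = 1)
  omega <- array(0, c(2, 3, 2))
  omega[1, 1, ] <- c(-2.0, 3.0)
  omega[1, 2, ] <- c(1.0, -2.5)
  omega[2, 1, ] <- c(-1.0, 2.0)
  omega[2, 2, ] <- c(0.5, -2.0)
  beta <- array(0, c(2, 3, 2))
  beta[1, 1, ] <- c(0.0, -1.5)
  beta[1, 2, ] <- c(0.6, -0.9)
  beta[1, 3, ] <- c(1.2, -0.3)
  beta[2, 1, ] <- c(0.6, 0.3)
  beta[2, 2, ] <- c(1.2, 0.9)
  beta[2, 3, ] <- c(1.8, 1.5)
  rhlp_params(alpha = c(0.5, 0.5), omega = omega, beta = beta,
              sigma2 = matrix(sigma^2, 2, 3), spec = spec)
}

#' Factor levels of the Monte Carlo study design
#'
#' The full factorial design crosses the number of subjects, the number of
#' time points, the residual standard deviation and the
#' missing-completely-at-random proportion; `M` replications are run per
#' condition.
#'
#' @param Np_levels,Nt_levels,sigma_levels,pmiss_levels factor levels.
#' @param M Monte Carlo runs per condition.
#' @return list of class `sim_design` with a `conditions` data frame
#'   (the full crossing) and the levels.
#' @export
simulation_design <- function(Np_levels = c(20, 60, 100),
                              Nt_levels = c(20, 160, 300),
                              sigma_levels = c(0.10, 0.15, 0.20),
                              pmiss_levels = c(0, 0.1, 0.2),
                              M = 200) {
  stopifnot(all(Np_levels >= 1), all(Nt_levels >= 2),
            all(sigma_levels > 0),
            all(pmiss_levels >= 0), all(pmiss_levels < 1), M >= 1)
  conditions <- expand.grid(n_subjects = Np_levels, n_times = Nt_levels,
                            sigma = sigma_levels, pmiss = pmiss_levels,
                            KEEP.OUT.ATTRS = FALSE)
  structure(list(conditions = conditions, Np_levels = Np_levels,
                 Nt_levels = Nt_levels, sigma_levels = sigma_levels,
                 pmiss_levels = pmiss_levels, M = M),
            class = "sim_design")
}

#' Serialize parameters to JSON
#'
#' The JSON object carries `alpha`, `omega`, `beta`, `sigma2` (nested
#' arrays) and the `spec`; the reference regime's omega row serializes as
#' zeros.
#'
#' @param params an [rhlp_params].
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_params_json <- function(params, path = NULL) {
  validate_params(params)
  s <- params$spec
  obj <- list(
    alpha = params$alpha,
    omega = lapply(seq_len(s$K), function(k)
      lapply(seq_len(s$R), function(r) params$omega[k, r, ])),
    beta = lapply(seq_len(s$K), function(k)
      lapply(seq_len(s$R), function(r) params$beta[k, r, ])),
    sigma2 = lapply(seq_len(s$K), function(k) params$sigma2[k, ]),
    spec = list(K = s$K, R = s$R, d = s$d, variance_structure = s$variance)
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read parameters from JSON
#'
#' @param path file path or a JSON string produced by [write_params_json()].
#' @return an [rhlp_params].
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sp <- obj$spec
  spec <- model_spec(sp$K, sp$R, sp$d, sp$variance_structure)
  to_array <- function(x, p) {
    # fromJSON simplifies regular nested lists to K x R x p arrays; fall
    # back to assembling from list-of-lists otherwise
    if (is.array(x) && length(dim(x)) == 3L) return(x)
    arr <- array(0, c(spec$K, spec$R, p))
    for (k in seq_len(spec$K)) for (r in seq_len(spec$R))
      arr[k, r, ] <- as.numeric(x[[k]][[r]])
    arr
  }
  rhlp_params(
    alpha = obj$alpha,
    omega = to_array(obj$omega, 2L),
    beta = to_array(obj$beta, spec$d + 1L),
    sigma2 = matrix(if (is.list(obj$sigma2)) do.call(rbind, obj$sigma2)
                    else obj$sigma2, spec$K, spec$R),
    spec = spec
  )
}
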