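# Generative sampling from the mixRHLP process, the
# missing-completely-at-random mask, and linear-interpolation imputation --
# the machinery behind the package's Monte Carlo study.

#' Simulate a panel from a mixRHLP model
#'
#' Time points are `n_times` equally spaced values spanning `[0, 1]`
#' inclusive. Each subject draws a cluster from `alpha`; at every time
#' point a regime is drawn independently from the cluster's logistic
#' switching probabilities, and the observation is Gaussian around that
#' regime's polynomial trend.
#'
#' @param params an [rhlp_params] (e.g. [benchmark_params()]).
#' @param n_subjects,n_times panel dimensions.
#' @param seed integer seed; the draw is deterministic given it.
#' @return An object of class `rhlp_sim`: list with `data` (a complete
#'   [panel_data]), `truth` (an [rhlp_labeling] of the generating cluster
#'   and regime draws), `params` and `seed`. After [apply_mcar()] the
#'   masked panel lives in `data` and the pre-masking panel in `complete`.
#' @export
simulate_rhlpmix <- function(params, n_subjects, n_times, seed = 1L) {
  validate_params(params)
  stopifnot(n_subjects >= 1, n_times >= 2)
  s <- params$spec
  set.seed(as.integer(seed))
  times <- seq(0, 1, length.out = n_times)
  X <- design_matrix(times, s$d)
  cluster <- sample.int(s$K, n_subjects, replace = TRUE,
                        prob = params$alpha)
  pis <- lapply(seq_len(s$K), function(k)
    exp(log_regime_probabilities(matrix(params$omega[k, , ], s$R, 2L),
                                 times)))
  mus <- lapply(seq_len(s$K), function(k)
    X %*% t(matrix(params$beta[k, , ], s$R, s$d + 1L)))  # N_t x R
  regime <- matrix(1L, n_subjects, n_times)
  values <- matrix(0, n_subjects, n_times)
  for (i in seq_len(n_subjects)) {
    k <- cluster[i]
    u <- stats::runif(n_times)
    # inverse-cdf draw per time point: h_j = 1 + #{r < R : u_j > cum_jr}
    h <- if (s$R == 1L) rep(1L, n_times) else {
      cum <- pis[[k]]
      for (r in 2:s$R) cum[, r] <- cum[, r - 1L] + cum[, r]
      1L + rowSums(u > cum[, -s$R, drop = FALSE])
    }
    regime[i, ] <- h
    mu <- mus[[k]][cbind(seq_len(n_times), h)]
    sd <- sqrt(params$sigma2[k, ][h])
    values[i, ] <- stats::rnorm(n_times, mu, sd)
  }
  structure(
    list(data = panel_data(values, times), complete = NULL,
         truth = rhlp_labeling(cluster, regime), params = params,
         seed = as.integer(seed)),
    class = "rhlp_sim"
  )
}

#' @export
print.rhlp_sim <- function(x, ...) {
  cat(sprintf("mixRHLP simulation (seed %d): ", x$seed))
  print(x$data)
  invisible(x)
}

#' Mask cells completely at random
#'
#' Each cell is masked independently with probability `pmiss`. By default
#' every subject's first and last grid points are protected so that linear
#' interpolation never has to extrapolate; disable with
#' `protect_ends = FALSE` (boundary gaps are then filled by the nearest
#' observed value at imputation time).
#'
#' @param x an `rhlp_sim` or a [panel_data].
#' @param pmiss masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @param protect_ends keep each subject's first and last cells observed.
#' @return same class as `x`; for an `rhlp_sim` the masked panel replaces
#'   `data` and the original is kept in `complete`.
#' @export
apply_mcar <- function(x, pmiss, seed = 1L, protect_ends = TRUE) {
  stopifnot(pmiss >= 0, pmiss < 1)
  if (inherits(x, "rhlp_sim")) {
    out <- x
    out$complete <- x$data
    out$data <- apply_mcar(x$data, pmiss, seed, protect_ends)
    return(out)
  }
  validate_panel(x)
  if (pmiss == 0) return(x)
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(length(x$values)) < pmiss,
                 nrow(x$values), ncol(x$values))
  if (protect_ends) mask[, c(1L, ncol(mask))] <- FALSE
  obs <- x$observed & !mask
  bad <- rowSums(obs) < 2L   # keep interpolation defined
  if (any(bad)) obs[bad, c(1L, ncol(obs))] <- x$observed[bad, c(1L, ncol(obs))]
  panel_data(x$values, x$times, observed = obs, subject_ids = x$subject_ids)
}

#' Fill missing cells by linear interpolation in time
#'
#' Interior gaps are interpolated linearly between the nearest observed
#' neighbors (via [zoo::na.approx()]); leading and trailing gaps take the
#' nearest observed value. The result is a fully observed panel.
#'
#' @param data a [panel_data]; every subject needs at least two observed
#'   cells.
#' @return a complete [panel_data].
#' @export
impute_linear <- function(data) {
  validate_panel(data)
  if (all(data$observed)) return(data)
  if (any(rowSums(data$observed) < 2L))
    stop("every subject needs at least two observed values to interpolate",
         call. = FALSE)
  vals <- data$values
  vals[!data$observed] <- NA_real_
  filled <- t(apply(vals, 1L, function(y)
    zoo::na.approx(y, x = data$times, na.rm = FALSE, rule = 2)))
  panel_data(filled, data$times, subject_ids = data$subject_ids)
}
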