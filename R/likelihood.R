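# Likelihood machinery of the mixRHLP model. All mixing is done in log
# space with log-sum-exp; at several hundred time points per subject the
# per-subject product of per-time mixtures underflows catastrophically in
# linear space.

#' Polynomial design matrix on a time grid
#'
#' Plain (non-orthogonalized) Vandermonde basis `t^0, t^1, ..., t^d`, so
#' fitted coefficients live on the same raw scale the model is
#' parameterized on.
#'
#' @param times numeric vector of time points.
#' @param d polynomial order (>= 0).
#' @return `length(times) x (d+1)` matrix.
#' @export
design_matrix <- function(times, d) {
  stopifnot(d >= 0)
  outer(as.numeric(times), 0:d, `^`)
}

#' Logistic regime-membership probabilities over time
#'
#' Evaluates the multinomial logistic switching process for one cluster:
#' regime `r`'s log-odds against the reference regime are linear in time,
#' `omega[r, 1] + omega[r, 2] * t`, and the reference (last) regime's row is
#' zero. Rows are computed by a max-subtracted softmax so extreme
#' coefficients cannot overflow.
#'
#' @param omega `R x 2` matrix of (intercept, slope) rows; the last row must
#'   be zero.
#' @param times numeric vector of time points.
#' @return `length(times) x R` matrix; each row a probability vector.
#' @examples
#' om <- rbind(c(-2, 3), c(1, -2.5), c(0, 0))
#' regime_probabilities(om, c(0, 1))
#' @export
regime_probabilities <- function(omega, times) {
  omega <- as.matrix(omega)
  if (!all(is.finite(omega)))
    stop("`omega` must be finite", call. = FALSE)
  R <- nrow(omega)
  if (any(abs(omega[R, ]) > 0))
    stop("the reference (last) row of `omega` must be zero", call. = FALSE)
  exp(log_regime_probabilities(omega, as.numeric(times)))
}

# log softmax over regimes, rows = time points; no validation (hot path)
log_regime_probabilities <- function(omega, times) {
  eta <- cbind(1, times) %*% t(omega)            # N_t x R
  m <- eta[cbind(seq_along(times), max.col(eta, ties.method = "first"))]
  eta - (m + log(rowSums(exp(eta - m))))
}

#' Log-density of one observation under one regime's regression
#'
#' `log N(y; x * beta, sigma2)` where `x` is the polynomial design row of
#' the observation's time point.
#'
#' @param y observed value.
#' @param x design row, `(t^0, ..., t^d)`.
#' @param beta regression coefficients, same length as `x`.
#' @param sigma2 positive residual variance.
#' @return the log-density (vectorized over `y` if `y` is a vector).
#' @export
emission_logdensity <- function(y, x, beta, sigma2) {
  if (!isTRUE(all(sigma2 > 0)) || !all(is.finite(sigma2)))
    stop("`sigma2` must be positive and finite", call. = FALSE)
  stats::dnorm(y, mean = sum(x * beta), sd = sqrt(sigma2), log = TRUE)
}

require_complete <- function(data) {
  validate_panel(data)
  if (!all(data$observed))
    stop("likelihood evaluation needs a complete panel; impute first ",
         "(see impute_linear())", call. = FALSE)
  invisible(data)
}

# E-quantities for a complete panel: per-cluster conditional log-likelihoods,
# cluster posteriors, total log-likelihood and (optionally) the per-cell
# regime responsibilities. The single hot path shared by the public
# accessors and the EM loop.
rhlp_estep <- function(Y, times, params, want_gamma = FALSE) {
  s <- params$spec
  np <- nrow(Y); nt <- ncol(Y)
  X <- design_matrix(times, s$d)
  comp <- matrix(0, np, s$K)
  gamma <- if (want_gamma) vector("list", s$K)
  for (k in seq_len(s$K)) {
    lp <- log_regime_probabilities(
      matrix(params$omega[k, , ], s$R, 2L), times)
    Bk <- matrix(params$beta[k, , ], s$R, s$d + 1L)
    Mu <- X %*% t(Bk)                            # N_t x R means
    slices <- vector("list", s$R)
    mx <- matrix(-Inf, np, nt)
    for (r in seq_len(s$R)) {
      s2 <- params$sigma2[k, r]
      dev <- Y - matrix(Mu[, r], np, nt, byrow = TRUE)
      a <- (-0.5 * log(2 * pi * s2)) - dev * dev / (2 * s2) +
        matrix(lp[, r], np, nt, byrow = TRUE)
      slices[[r]] <- a
      mx <- pmax(mx, a)
    }
    acc <- matrix(0, np, nt)
    for (r in seq_len(s$R)) acc <- acc + exp(slices[[r]] - mx)
    lse <- mx + log(acc)                          # per-cell regime mixture
    comp[, k] <- rowSums(lse)
    if (want_gamma) {
      g <- array(0, c(np, nt, s$R))
      for (r in seq_len(s$R)) g[, , r] <- exp(slices[[r]] - lse)
      gamma[[k]] <- g
    }
  }
  lw <- sweep(comp, 2L, log(params$alpha), `+`)
  m <- apply(lw, 1L, max)
  lnorm <- m + log(rowSums(exp(lw - m)))
  list(comp = comp, tau = exp(lw - lnorm), loglik = sum(lnorm),
       gamma = gamma)
}

#' Conditional log-likelihood of each subject under one cluster
#'
#' For cluster `k`, sums over time points the log of the regime mixture
#' density (switching probabilities times Gaussian emissions), each inner
#' sum by log-sum-exp.
#'
#' @param data a complete [panel_data] (impute missing values first).
#' @param params an [rhlp_params].
#' @param k cluster index.
#' @return numeric vector, one value per subject.
#' @export
component_loglik <- function(data, params, k) {
  require_complete(data)
  validate_params(params)
  stopifnot(k >= 1, k <= params$spec$K)
  rhlp_estep(data$values, data$times, params)$comp[, k]
}

#' Observed-data log-likelihood of a mixRHLP model
#'
#' Sums over subjects the log of the cluster mixture of per-cluster
#' conditional likelihoods, with the outer sum over clusters done by
#' log-sum-exp.
#'
#' @inheritParams component_loglik
#' @return a single number.
#' @export
total_loglik <- function(data, params) {
  require_complete(data)
  validate_params(params)
  rhlp_estep(data$values, data$times, params)$loglik
}

#' Posterior cluster-membership probabilities
#'
#' Row `i` is proportional to `alpha_k * p_k(y_i)` and normalized over
#' clusters.
#'
#' @inheritParams component_loglik
#' @return `N_p x K` matrix with rows summing to 1.
#' @export
posterior_cluster <- function(data, params) {
  require_complete(data)
  validate_params(params)
  rhlp_estep(data$values, data$times, params)$tau
}

#' Posterior regime-membership probabilities within a cluster
#'
#' Conditional on cluster `k`, cell `(j, r)` is proportional to the
#' switching probability of regime `r` at `t_j` times the Gaussian emission
#' density of the subject's observation there.
#'
#' @inheritParams component_loglik
#' @param subject subject index, or `NULL` for all subjects.
#' @return `N_t x R` matrix for a single subject, otherwise an
#'   `N_p x N_t x R` array; probabilities sum to 1 over regimes.
#' @export
posterior_regime <- function(data, params, k, subject = NULL) {
  require_complete(data)
  validate_params(params)
  stopifnot(k >= 1, k <= params$spec$K)
  g <- rhlp_estep(data$values, data$times, params,
                  want_gamma = TRUE)$gamma[[k]]
  if (is.null(subject)) return(g)
  stopifnot(subject >= 1, subject <= nrow(data$values))
  matrix(g[subject, , ], ncol = params$spec$R)
}
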