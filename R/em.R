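# Expectation-Maximization estimation of the mixRHLP model.
#
# E-step: cluster responsibilities tau_ik and, conditional on each cluster,
# per-cell regime responsibilities gamma_ijkr (rhlp_estep). M-step: exact
# weighted updates -- mixing proportions by averaging tau, regression
# coefficients by weighted least squares with weights tau_ik * gamma_ijkr,
# variances as weighted mean squared residuals (pooled when homoskedastic),
# and the logistic switching coefficients by Newton-Raphson (IRLS) on the
# multinomial logistic log-likelihood with fractional targets.

#' Control settings for the EM fit
#'
#' @param max_iter maximum EM iterations per start.
#' @param tol convergence threshold on the relative log-likelihood change
#'   `|l' - l| / (|l| + 1)`.
#' @param n_starts number of independent random initializations; the fit
#'   with the highest final log-likelihood is kept.
#' @param irls_max_iter,irls_tol inner Newton loop controls for the
#'   switching coefficients.
#' @param variance_floor lower bound on fitted variances, guarding against
#'   the degenerate zero-variance spikes finite Gaussian mixtures are prone
#'   to.
#' @param seed integer seed; start `s` uses `seed + s - 1`.
#' @return list of class `fit_controls`.
#' @export
fit_controls <- function(max_iter = 1000L, tol = 1e-8, n_starts = 10L,
                         irls_max_iter = 50L, irls_tol = 1e-8,
                         variance_floor = 1e-6, seed = 1L) {
  stopifnot(max_iter >= 1, tol > 0, n_starts >= 1, irls_max_iter >= 1,
            irls_tol > 0, variance_floor > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts),
                 irls_max_iter = as.integer(irls_max_iter),
                 irls_tol = irls_tol, variance_floor = variance_floor,
                 seed = as.integer(seed)),
            class = "fit_controls")
}

#' Initial parameter values for the EM fit
#'
#' `random_partition` assigns subjects uniformly at random to the K
#' clusters; within each cluster the time axis is cut into R contiguous
#' equal blocks and a separate polynomial regression per block seeds `beta`
#' and `sigma2`. `contiguous_segments` does the same after ordering subjects
#' by their series mean, giving a deterministic, separation-seeking start.
#' Switching coefficients start at zero (uniform regime probabilities).
#'
#' @param data a complete [panel_data].
#' @param spec a [model_spec].
#' @param seed integer seed (used by `random_partition`).
#' @param strategy `"random_partition"` or `"contiguous_segments"`.
#' @return an [rhlp_params].
#' @export
init_rhlp <- function(data, spec, seed = 1L,
                      strategy = c("random_partition",
                                   "contiguous_segments")) {
  strategy <- match.arg(strategy)
  require_complete(data)
  np <- nrow(data$values); nt <- length(data$times)
  if (spec$K > np) stop("more clusters than subjects", call. = FALSE)
  if (strategy == "random_partition") {
    set.seed(seed)
    assign <- c(seq_len(spec$K),
                sample.int(spec$K, np - spec$K, replace = TRUE))
    assign <- assign[sample.int(np)]
  } else {
    ord <- order(rowMeans(data$values))
    assign <- integer(np)
    assign[ord] <- rep(seq_len(spec$K), length.out = np,
                       each = ceiling(np / spec$K))[seq_len(np)]
  }
  X <- design_matrix(data$times, spec$d)
  blocks <- if (spec$R == 1L) list(seq_len(nt)) else
    split(seq_len(nt), cut(seq_len(nt), spec$R, labels = FALSE))
  beta <- array(0, c(spec$K, spec$R, spec$d + 1L))
  sigma2 <- matrix(1, spec$K, spec$R)
  for (k in seq_len(spec$K)) {
    rows <- which(assign == k)
    for (r in seq_len(spec$R)) {
      j <- blocks[[r]]
      xb <- X[rep(j, times = length(rows)), , drop = FALSE]
      yb <- as.vector(t(data$values[rows, j, drop = FALSE]))
      co <- tryCatch(stats::lsfit(xb, yb, intercept = FALSE)$coefficients,
                     error = function(e) rep(0, spec$d + 1L))
      co[!is.finite(co)] <- 0
      beta[k, r, ] <- co
      res <- yb - xb %*% co
      sigma2[k, r] <- max(mean(res^2), 1e-4)
    }
  }
  if (spec$variance == "homoskedastic")
    sigma2[] <- mean(sigma2)
  alpha <- (tabulate(assign, spec$K) + 1) / (np + spec$K)
  alpha <- alpha / sum(alpha)
  rhlp_params(alpha = alpha, omega = array(0, c(spec$K, spec$R, 2L)),
              beta = beta, sigma2 = sigma2, spec = spec)
}

#' Weighted multinomial logistic fit of the switching coefficients
#'
#' Maximizes `sum_{j,r} targets[j, r] * log pi_r(t_j; omega)` over the
#' `(R-1) x 2` free coefficients (reference regime pinned at zero) by
#' Newton-Raphson with step-halving. The targets are fractional regime
#' responsibilities aggregated over subjects, so this is the exact M-step
#' for the switching process.
#'
#' @param targets `N_t x R` matrix of non-negative weights.
#' @param times time grid.
#' @param omega_init `R x 2` starting value, reference row zero.
#' @param max_iter,tol Newton loop controls.
#' @return `R x 2` matrix with objective value attached as attribute
#'   `"objective"`; never worse than at `omega_init`.
#' @export
irls_multinomial <- function(targets, times, omega_init,
                             max_iter = 50L, tol = 1e-8) {
  targets <- as.matrix(targets)
  R <- ncol(targets)
  stopifnot(all(targets >= 0), nrow(targets) == length(times))
  omega <- as.matrix(omega_init)
  objective <- function(om) sum(targets * log_regime_probabilities(om, times))
  if (R == 1L) {
    out <- matrix(0, 1L, 2L)
    attr(out, "objective") <- 0
    return(out)
  }
  Xl <- cbind(1, as.numeric(times))               # N_t x 2
  cj <- rowSums(targets)
  obj <- objective(omega)
  free <- seq_len(R - 1L)
  for (iter in seq_len(max_iter)) {
    P <- exp(log_regime_probabilities(omega, times))
    # gradient: stack of 2-vectors over free regimes
    G <- crossprod(Xl, targets[, free, drop = FALSE] -
                     cj * P[, free, drop = FALSE])  # 2 x (R-1)
    grad <- as.vector(G)
    H <- matrix(0, 2L * (R - 1L), 2L * (R - 1L))
    for (r in free) for (s in free) {
      w <- if (r == s) cj * P[, r] * (1 - P[, r]) else -cj * P[, r] * P[, s]
      H[(2 * r - 1):(2 * r), (2 * s - 1):(2 * s)] <-
        -crossprod(Xl, w * Xl)
    }
    step <- tryCatch(solve(-H, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      step <- grad / max(sum(abs(cj)), 1)          # gradient fallback
    improved <- FALSE
    fac <- 1
    for (h in 0:30) {
      cand <- omega
      cand[free, ] <- omega[free, ] +
        fac * matrix(step, R - 1L, 2L, byrow = TRUE)
      cobj <- objective(cand)
      if (is.finite(cobj) && cobj >= obj) {
        improved <- cobj > obj + tol * (abs(obj) + 1)
        omega <- cand
        delta <- cobj - obj
        obj <- cobj
        break
      }
      fac <- fac / 2
    }
    if (!improved) break
    if (delta < tol * (abs(obj) + 1)) break
  }
  init_obj <- objective(as.matrix(omega_init))
  if (obj < init_obj) {                            # ascent contract
    warning("IRLS failed to improve on its starting value")
    omega <- as.matrix(omega_init)
    obj <- init_obj
  }
  attr(omega, "objective") <- obj
  omega
}

# One EM run from given starting parameters; returns NULL on numerical
# failure (non-finite log-likelihood).
em_run <- function(Y, times, params, controls) {
  s <- params$spec
  np <- nrow(Y); nt <- ncol(Y)
  X <- design_matrix(times, s$d)
  trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  for (iter in seq_len(controls$max_iter)) {
    e <- rhlp_estep(Y, times, params, want_gamma = TRUE)
    if (!is.finite(e$loglik)) return(NULL)
    trace <- c(trace, e$loglik)
    if (iter > 1L &&
        abs(e$loglik - loglik) < controls$tol * (abs(loglik) + 1)) {
      loglik <- e$loglik
      converged <- TRUE
      break
    }
    loglik <- e$loglik
    # ---- M-step ----
    alpha <- colMeans(e$tau)
    alpha <- pmax(alpha, 1e-12); alpha <- alpha / sum(alpha)
    beta <- params$beta
    sigma2 <- params$sigma2
    omega <- params$omega
    pool_num <- 0; pool_den <- 0
    for (k in seq_len(s$K)) {
      g <- e$gamma[[k]]
      tk <- e$tau[, k]
      Gk <- matrix(0, nt, s$R)                    # targets for IRLS
      for (r in seq_len(s$R)) {
        W <- tk * g[, , r]                         # N_p x N_t weights
        wj <- colSums(W)
        Gk[, r] <- wj
        sj <- colSums(W * Y)
        XtWX <- crossprod(X, wj * X)
        co <- tryCatch(solve(XtWX, crossprod(X, sj)),
                       error = function(e2) NULL)
        if (!is.null(co) && all(is.finite(co))) beta[k, r, ] <- co
        mu <- X %*% beta[k, r, ]
        dev <- Y - matrix(mu, np, nt, byrow = TRUE)
        num <- sum(W * dev * dev); den <- sum(wj)
        if (s$variance == "homoskedastic") {
          pool_num <- pool_num + num; pool_den <- pool_den + den
        } else if (den > 0) {
          sigma2[k, r] <- max(num / den, controls$variance_floor)
        }
      }
      om <- irls_multinomial(Gk, times,
                             matrix(omega[k, , ], s$R, 2L),
                             max_iter = controls$irls_max_iter,
                             tol = controls$irls_tol)
      omega[k, , ] <- om
    }
    if (s$variance == "homoskedastic")
      sigma2[] <- max(pool_num / max(pool_den, 1e-300),
                      controls$variance_floor)
    params <- rhlp_params(alpha, omega, beta, sigma2, s)
  }
  e <- rhlp_estep(Y, times, params, want_gamma = FALSE)
  list(params = params, loglik = e$loglik, trace = trace, tau = e$tau,
       converged = converged, n_iter = length(trace))
}

#' Fit a mixRHLP model by multi-start EM
#'
#' Runs `controls$n_starts` independent EM runs from random-partition
#' initializations (or a single run from `init` if supplied) and keeps the
#' one with the highest final log-likelihood. Each run alternates posterior
#' responsibility computation with exact weighted maximum-likelihood
#' updates, so the log-likelihood trace is non-decreasing.
#'
#' @param data a complete [panel_data]; impute missing values first.
#' @param spec a [model_spec].
#' @param controls a [fit_controls].
#' @param init optional [rhlp_params] to start from (overrides multi-start;
#'   used e.g. for truth-initialized recovery studies).
#' @return An object of class `rhlp_fit`: list with `params`, `loglik`,
#'   `loglik_trace`, `cluster_posterior`, `converged`, `n_iter`, `spec`,
#'   `n_params`, `criteria` (BIC/saBIC/AIC/AICc), `start_logliks`.
#' @examples
#' sim <- simulate_rhlpmix(benchmark_params(0.1), 10, 40, seed = 1)
#' fit <- fit_rhlpmix(sim$data, model_spec(2, 3, 1),
#'                    fit_controls(n_starts = 2, max_iter = 100))
#' fit
#' @export
fit_rhlpmix <- function(data, spec, controls = fit_controls(),
                        init = NULL) {
  require_complete(data)
  stopifnot(inherits(spec, "rhlp_spec"), inherits(controls, "fit_controls"))
  Y <- data$values; times <- data$times
  starts <- if (is.null(init)) {
    lapply(seq_len(controls$n_starts), function(s2)
      init_rhlp(data, spec, seed = controls$seed + s2 - 1L,
                strategy = "random_partition"))
  } else {
    validate_params(init)
    if (!identical(unclass(init$spec), unclass(spec)))
      stop("`init` was built for a different spec", call. = FALSE)
    list(init)
  }
  best <- NULL
  start_logliks <- rep(NA_real_, length(starts))
  for (s2 in seq_along(starts)) {
    run <- em_run(Y, times, starts[[s2]], controls)
    if (is.null(run)) next
    start_logliks[s2] <- run$loglik
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best))
    stop("all EM starts failed with non-finite log-likelihood",
         call. = FALSE)
  q <- count_parameters(spec)
  crit <- information_criteria(best$loglik, q, length(times), nrow(Y))
  structure(
    list(params = best$params, loglik = best$loglik,
         loglik_trace = best$trace, cluster_posterior = best$tau,
         converged = best$converged, n_iter = best$n_iter, spec = spec,
         n_params = q, criteria = crit, start_logliks = start_logliks),
    class = "rhlp_fit"
  )
}

#' @export
print.rhlp_fit <- function(x, ...) {
  cat(sprintf(
    "mixRHLP fit: K = %d, R = %d, d = %d (%s)\nlog-likelihood %.4f after %d EM iterations (%sconverged), %d parameters\n",
    x$spec$K, x$spec$R, x$spec$d, x$spec$variance, x$loglik, x$n_iter,
    if (x$converged) "" else "not ", x$n_params))
  cat("criteria:", paste(names(x$criteria),
                         signif(unlist(x$criteria), 6),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.rhlp_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = nrow(object$cluster_posterior), class = "logLik")
}

#' @export
coef.rhlp_fit <- function(object, ...) object$params
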