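# Brute-force linear-space oracles and random-instance generators shared
# across the suite. The oracles enumerate regimes/clusters directly and are
# only usable on tiny instances; they are deliberately independent of the
# package's log-space implementations.

bf_component_loglik <- function(y, times, params, k) {
  s <- params$spec
  X <- design_matrix(times, s$d)
  ll <- 0
  for (j in seq_along(times)) {
    eta <- params$omega[k, , 1] + params$omega[k, , 2] * times[j]
    pi_j <- exp(eta) / sum(exp(eta))
    tot <- 0
    for (r in seq_len(s$R)) {
      tot <- tot + pi_j[r] *
        stats::dnorm(y[j], sum(X[j, ] * params$beta[k, r, ]),
                     sqrt(params$sigma2[k, r]))
    }
    ll <- ll + log(tot)
  }
  ll
}

bf_total_loglik <- function(data, params) {
  s <- params$spec
  tot <- 0
  for (i in seq_len(nrow(data$values))) {
    mix <- 0
    for (k in seq_len(s$K)) {
      mix <- mix + params$alpha[k] *
        exp(bf_component_loglik(data$values[i, ], data$times, params, k))
    }
    tot <- tot + log(mix)
  }
  tot
}

random_params <- function(K, R, d, seed = 1) {
  set.seed(seed)
  g <- stats::rexp(K) + 0.2
  omega <- array(stats::rnorm(K * R * 2), c(K, R, 2))
  omega[, R, ] <- 0
  rhlp_params(
    alpha = g / sum(g),
    omega = omega,
    beta = array(stats::rnorm(K * R * (d + 1)), c(K, R, d + 1)),
    sigma2 = matrix(stats::runif(K * R, 0.3, 1.5), K, R),
    spec = model_spec(K, R, d)
  )
}

random_panel <- function(n_subjects, n_times, seed = 1) {
  set.seed(seed)
  panel_data(matrix(stats::rnorm(n_subjects * n_times), n_subjects, n_times),
             times = seq(0, 1, length.out = n_times))
}
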