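# Likelihood and probability computations of the mixRHLP model.

test_that("regime probabilities follow the multinomial logistic model", {
  om <- rbind(c(-2, 3), c(1, -2.5), c(0, 0))
  p <- regime_probabilities(om, c(0, 1))
  expect_equal(p[1, ], c(0.03512, 0.70539, 0.25949), tolerance = 1e-4)
  expect_equal(p[2, ], c(0.68967, 0.05661, 0.25372), tolerance = 1e-4)

  # zero log-odds give uniform membership at every time point
  u <- regime_probabilities(matrix(0, 4, 2), runif(7))
  expect_equal(u, matrix(0.25, 7, 4))

  # rows are probability vectors on randomized coefficients
  for (s in 1:10) {
    set.seed(s)
    R <- sample(2:4, 1)
    om <- matrix(rnorm(R * 2, sd = 3), R, 2)
    om[R, ] <- 0
    p <- regime_probabilities(om, seq(0, 1, length.out = 11))
    expect_equal(rowSums(p), rep(1, 11), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }

  # log-space evaluation survives coefficients that overflow exp()
  om <- rbind(c(800, -1600), c(0, 0))
  p <- regime_probabilities(om, c(0, 0.5, 1))
  expect_true(all(is.finite(p)))
  expect_equal(p[1, ], c(1, 0), tolerance = 1e-12)

  expect_error(regime_probabilities(rbind(c(NA, 1), c(0, 0)), 0.5), "finite")
  expect_error(regime_probabilities(rbind(c(1, 1), c(1, 0)), 0.5),
               "reference")
})

test_that("Gaussian emission log-density is exact", {
  expect_equal(emission_logdensity(2.5, c(1, 0.5), c(2, 1), 1 / (2 * pi)), 0)
  expect_equal(emission_logdensity(0, 1, 0, 1), -0.918939, tolerance = 1e-6)
  expect_equal(emission_logdensity(1, 1, 0, 1), -1.418939, tolerance = 1e-6)
  expect_error(emission_logdensity(0, 1, 0, 0), "positive")
  expect_error(emission_logdensity(0, 1, 0, -1), "positive")
})

test_that("component and total log-likelihoods match brute-force oracles", {
  for (s in 1:6) {
    K <- sample(1:3, 1); R <- sample(1:3, 1); d <- sample(0:2, 1)
    params <- random_params(K, R, d, seed = 100 + s)
    pd <- random_panel(3, 5, seed = 200 + s)
    for (k in seq_len(K)) {
      bf <- vapply(1:3, function(i)
        bf_component_loglik(pd$values[i, ], pd$times, params, k), numeric(1))
      expect_equal(component_loglik(pd, params, k), bf, tolerance = 1e-8)
    }
    expect_equal(total_loglik(pd, params), bf_total_loglik(pd, params),
                 tolerance = 1e-8)
  }
})

test_that("single-regime component likelihood collapses to a sum of emissions", {
  params <- random_params(2, 1, 1, seed = 4)
  pd <- random_panel(4, 6, seed = 5)
  X <- design_matrix(pd$times, 1)
  direct <- vapply(1:4, function(i)
    sum(vapply(1:6, function(j)
      emission_logdensity(pd$values[i, j], X[j, ], params$beta[1, 1, ],
                          params$sigma2[1, 1]), numeric(1))), numeric(1))
  expect_equal(component_loglik(pd, params, 1), direct, tolerance = 1e-10)
})

test_that("degenerate mixtures collapse as expected", {
  pd <- random_panel(4, 6, seed = 6)
  p1 <- random_params(1, 2, 1, seed = 7)
  expect_equal(total_loglik(pd, p1), sum(component_loglik(pd, p1, 1)))

  # zero-weight component drops out of the mixture
  p2 <- random_params(2, 2, 1, seed = 8)
  p2$alpha <- c(1, 0)
  expect_equal(total_loglik(pd, p2), sum(component_loglik(pd, p2, 1)))

  # growing variance drives the likelihood toward -Inf
  p3 <- random_params(1, 2, 1, seed = 9)
  lls <- vapply(c(1, 1e4, 1e8), function(v) {
    p3$sigma2[] <- v
    total_loglik(pd, p3)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("posterior probabilities are normalized and symmetric when they should be", {
  pd <- random_panel(5, 8, seed = 10)
  params <- random_params(3, 3, 1, seed = 11)
  tau <- posterior_cluster(pd, params)
  expect_equal(rowSums(tau), rep(1, 5), tolerance = 1e-12)

  p1 <- random_params(1, 2, 1, seed = 12)
  expect_equal(posterior_cluster(pd, p1), matrix(1, 5, 1))

  # identical components with equal weights split responsibility evenly
  p2 <- random_params(2, 2, 1, seed = 13)
  p2$alpha <- c(0.5, 0.5)
  p2$omega[2, , ] <- p2$omega[1, , ]
  p2$beta[2, , ] <- p2$beta[1, , ]
  p2$sigma2[2, ] <- p2$sigma2[1, ]
  expect_equal(posterior_cluster(pd, p2), matrix(0.5, 5, 2))

  g <- posterior_regime(pd, params, k = 2, subject = 3)
  expect_equal(rowSums(g), rep(1, 8), tolerance = 1e-12)
  pR1 <- random_params(2, 1, 1, seed = 19)
  expect_equal(posterior_regime(pd, pR1, 1, subject = 1)[, 1], rep(1, 8))

  # equal emissions across regimes pass the switching prior through
  p3 <- random_params(1, 3, 1, seed = 14)
  p3$beta[1, , ] <- rep(p3$beta[1, 1, ], each = 3)
  p3$sigma2[1, ] <- p3$sigma2[1, 1]
  expect_equal(posterior_regime(pd, p3, 1, subject = 2),
               regime_probabilities(matrix(p3$omega[1, , ], 3, 2),
                                    pd$times),
               tolerance = 1e-12)
})

test_that("the likelihood is invariant to cluster label permutations", {
  pd <- random_panel(4, 6, seed = 15)
  params <- random_params(3, 2, 1, seed = 16)
  perm <- c(3, 1, 2)
  permuted <- rhlp_params(params$alpha[perm],
                          params$omega[perm, , , drop = FALSE],
                          params$beta[perm, , , drop = FALSE],
                          params$sigma2[perm, , drop = FALSE],
                          params$spec)
  expect_equal(total_loglik(pd, params), total_loglik(pd, permuted),
               tolerance = 1e-12)
})

test_that("time translation is absorbed by the switching intercepts", {
  om <- rbind(c(-2, 3), c(1, -2.5), c(0, 0))
  delta <- 0.37
  times <- seq(0, 1, length.out = 9)
  shifted <- om
  shifted[, 1] <- om[, 1] - om[, 2] * delta
  expect_equal(regime_probabilities(om, times),
               regime_probabilities(shifted, times + delta),
               tolerance = 1e-12)
})

test_that("likelihood evaluation refuses incomplete panels", {
  pd <- random_panel(3, 5, seed = 17)
  pd$observed[2, 3] <- FALSE
  params <- random_params(2, 2, 1, seed = 18)
  expect_error(total_loglik(pd, params), "impute")
})

test_that("parameters survive a JSON round trip, reference row zeroed", {
  params <- benchmark_params(0.15)
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(params, path)
  back <- read_params_json(path)
  expect_equal(back$alpha, params$alpha)
  expect_equal(back$omega, params$omega)
  expect_equal(back$beta, params$beta)
  expect_equal(back$sigma2, params$sigma2)
  expect_identical(unclass(back$spec), unclass(params$spec))
  expect_true(all(back$omega[, 3, ] == 0))
})

test_that("parameter validation catches the standard violations", {
  s <- model_spec(2, 2, 1)
  ok_om <- array(0, c(2, 2, 2)); ok_b <- array(0, c(2, 2, 2))
  expect_error(rhlp_params(c(0.7, 0.7), ok_om, ok_b, matrix(1, 2, 2), s),
               "summing to 1")
  bad_om <- ok_om; bad_om[1, 2, 1] <- 1
  expect_error(rhlp_params(c(0.5, 0.5), bad_om, ok_b, matrix(1, 2, 2), s),
               "reference")
  expect_error(rhlp_params(c(0.5, 0.5), ok_om, ok_b, matrix(-1, 2, 2), s),
               "positive")
  sh <- model_spec(2, 2, 1, "homoskedastic")
  expect_error(rhlp_params(c(0.5, 0.5), ok_om, ok_b,
                           matrix(c(1, 2, 1, 1), 2, 2), sh),
               "shared variance")
})
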