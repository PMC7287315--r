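# EM estimation: degenerate closed forms, the ascent property, the IRLS
# inner loop, and parameter recovery on simulated data.

test_that("the K=1, R=1 fit equals the closed-form least-squares solution", {
  pd <- random_panel(6, 25, seed = 21)
  for (d in 0:2) {
    fit <- fit_rhlpmix(pd, model_spec(1, 1, d),
                       fit_controls(n_starts = 1, seed = 1))
    X <- design_matrix(rep(pd$times, each = 6), d)
    y <- as.vector(pd$values)
    co <- solve(crossprod(X), crossprod(X, y))
    expect_equal(as.vector(fit$params$beta[1, 1, ]), as.vector(co),
                 tolerance = 1e-8)
    expect_equal(fit$params$sigma2[1, 1],
                 mean((y - X %*% co)^2), tolerance = 1e-8)
    expect_equal(fit$params$alpha, 1)
  }
})

test_that("every EM iteration increases the log-likelihood", {
  for (s in 1:8) {
    K <- sample(1:2, 1); R <- sample(1:3, 1)
    truth <- random_params(K, R, 1, seed = 300 + s)
    sim <- simulate_rhlpmix(truth, 8, 20, seed = 400 + s)
    fit <- fit_rhlpmix(sim$data, truth$spec,
                       fit_controls(n_starts = 2, max_iter = 40,
                                    seed = 500 + s))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 *
                      (abs(fit$loglik_trace[-length(fit$loglik_trace)]) + 1)))
  }
})

test_that("initialization is deterministic and validates its inputs", {
  pd <- random_panel(10, 30, seed = 22)
  spec <- model_spec(3, 2, 1)
  a <- init_rhlp(pd, spec, seed = 7)
  b <- init_rhlp(pd, spec, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, init_rhlp(pd, spec, seed = 8)))
  # zero switching coefficients start from uniform regime probabilities
  expect_true(all(a$omega == 0))
  expect_error(init_rhlp(random_panel(2, 10, seed = 1), model_spec(5, 1, 1)),
               "more clusters than subjects")
  cs <- init_rhlp(pd, spec, strategy = "contiguous_segments")
  expect_identical(cs, init_rhlp(pd, spec, strategy = "contiguous_segments"))
})

test_that("a supplied starting value is honoured and checked", {
  truth <- benchmark_params(0.1)
  sim <- simulate_rhlpmix(truth, 12, 40, seed = 23)
  fit <- fit_rhlpmix(sim$data, truth$spec, fit_controls(max_iter = 50),
                     init = truth)
  expect_equal(sum(!is.na(fit$start_logliks)), 1L)
  expect_error(fit_rhlpmix(sim$data, model_spec(3, 3, 1), init = truth),
               "different spec")
})

test_that("IRLS maximizes the weighted multinomial logistic objective", {
  times <- seq(0, 1, length.out = 300)

  # uniform responsibilities: zero coefficients are the stationary point
  targ <- matrix(1 / 3, 300, 3)
  om <- irls_multinomial(targ, times, matrix(0, 3, 2))
  expect_equal(om[1:2, ], matrix(0, 2, 2), tolerance = 1e-6)
  expect_equal(attr(om, "objective"), sum(targ * log(1 / 3)))

  # recover a known logistic curve from its own probabilities
  true_om <- rbind(c(1, -2), c(0, 0))
  targ2 <- regime_probabilities(true_om, times)
  om2 <- irls_multinomial(targ2, times, matrix(0, 2, 2))
  expect_equal(om2[1, ], c(1, -2), tolerance = 0.05)

  # ascent contract on randomized fractional targets
  for (s in 1:5) {
    set.seed(600 + s)
    R <- sample(2:4, 1)
    raw <- matrix(rexp(50 * R), 50, R)
    targ3 <- raw / rowSums(raw)
    init <- matrix(rnorm(R * 2), R, 2); init[R, ] <- 0
    f0 <- sum(targ3 * log(regime_probabilities(init, times[1:50]) + 0))
    om3 <- irls_multinomial(targ3, times[1:50], init)
    expect_gte(attr(om3, "objective"), f0 - 1e-10)
  }

  # single-regime case is trivially uniform
  om4 <- irls_multinomial(matrix(1, 10, 1), times[1:10], matrix(0, 1, 2))
  expect_equal(unclass(om4)[1, ], c(0, 0), ignore_attr = TRUE)
})

test_that("truth-initialized fits recover the generating parameters", {
  # single-cluster truth built from the benchmark model's first cluster
  b1 <- benchmark_params(0.1)
  spec1 <- model_spec(1, 3, 1)
  p1 <- rhlp_params(1, b1$omega[1, , , drop = FALSE],
                    b1$beta[1, , , drop = FALSE],
                    b1$sigma2[1, , drop = FALSE], spec1)
  sim1 <- simulate_rhlpmix(p1, 60, 300, seed = 24)
  fit1 <- fit_rhlpmix(sim1$data, spec1, fit_controls(), init = p1)
  expect_equal(fit1$params$beta, p1$beta, tolerance = 0.05)
  expect_equal(sqrt(fit1$params$sigma2), sqrt(p1$sigma2), tolerance = 0.02)

  # two-cluster benchmark truth at the large data condition
  truth <- benchmark_params(0.1)
  sim <- simulate_rhlpmix(truth, 100, 300, seed = 25)
  fit <- fit_rhlpmix(sim$data, truth$spec, fit_controls(), init = truth)
  lab <- classify(fit, sim$data)
  m <- match_labels(sim$truth, lab, 2, 3)
  est <- permute_params(fit$params, m)
  expect_equal(est$beta, truth$beta, tolerance = 0.05)
  expect_equal(sqrt(est$sigma2), sqrt(truth$sigma2), tolerance = 0.02)
})

test_that("subject order does not change the estimates", {
  truth <- benchmark_params(0.1)
  sim <- simulate_rhlpmix(truth, 15, 60, seed = 26)
  perm <- sample(15)
  shuffled <- panel_data(sim$data$values[perm, ], sim$data$times)
  f1 <- fit_rhlpmix(sim$data, truth$spec, fit_controls(max_iter = 60),
                    init = truth)
  f2 <- fit_rhlpmix(shuffled, truth$spec, fit_controls(max_iter = 60),
                    init = truth)
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-8)
  expect_equal(f1$params$omega, f2$params$omega, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})
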