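# Generative sampling, MCAR masking, and linear-interpolation imputation.

test_that("simulation is deterministic given the seed", {
  p <- benchmark_params(0.1)
  a <- simulate_rhlpmix(p, 8, 25, seed = 51)
  b <- simulate_rhlpmix(p, 8, 25, seed = 51)
  expect_identical(a, b)
  expect_false(identical(a, simulate_rhlpmix(p, 8, 25, seed = 52)))
  expect_equal(a$data$times, seq(0, 1, length.out = 25))
})

test_that("degenerate generative settings behave as designed", {
  p <- benchmark_params(0.1)
  p$alpha <- c(1, 0)
  sim <- simulate_rhlpmix(p, 30, 10, seed = 53)
  expect_true(all(sim$truth$cluster == 1L))

  # vanishing noise puts every value exactly on its regime's trend line
  q <- benchmark_params(0.1)
  q$sigma2[] <- 1e-20
  simq <- simulate_rhlpmix(q, 5, 12, seed = 54)
  X <- design_matrix(simq$data$times, 1)
  for (i in 1:5) {
    k <- simq$truth$cluster[i]
    mu <- vapply(seq_len(12), function(j)
      sum(X[j, ] * q$beta[k, simq$truth$regime[i, j], ]), numeric(1))
    expect_equal(simq$data$values[i, ], mu, tolerance = 1e-6)
  }
})

test_that("simulated frequencies match the model's probabilities", {
  p <- benchmark_params(0.1)
  n <- 10000
  sim <- simulate_rhlpmix(p, n, 160, seed = 55)
  frac1 <- mean(sim$truth$cluster == 1L)
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac1 - 0.5), 3 * se)

  # regime frequencies at t = 0 in cluster 1 follow the logistic model
  target <- regime_probabilities(matrix(p$omega[1, , ], 3, 2), 0)[1, ]
  h0 <- sim$truth$regime[sim$truth$cluster == 1L, 1]
  emp <- tabulate(h0, 3) / length(h0)
  for (r in 1:3) {
    se_r <- sqrt(target[r] * (1 - target[r]) / length(h0))
    expect_lt(abs(emp[r] - target[r]), 3 * se_r + 1e-6)
  }
})

test_that("MCAR masking hits its rate and keeps values recoverable", {
  p <- benchmark_params(0.1)
  sim <- simulate_rhlpmix(p, 100, 320, seed = 56)
  expect_identical(apply_mcar(sim$data, 0, seed = 1), sim$data)

  masked <- apply_mcar(sim, 0.2, seed = 57, protect_ends = FALSE)
  frac <- 1 - mean(masked$data$observed)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 32000))
  # values survive in both panels; only the mask differs
  expect_identical(masked$data$values, masked$complete$values)
  expect_true(all(masked$complete$observed))

  prot <- apply_mcar(sim$data, 0.3, seed = 58, protect_ends = TRUE)
  expect_true(all(prot$observed[, c(1, 320)]))
  expect_identical(apply_mcar(sim$data, 0.3, seed = 58),
                   apply_mcar(sim$data, 0.3, seed = 58))
})

test_that("linear imputation interpolates interior gaps and pads the ends", {
  pd <- panel_data(rbind(c(0, NA, 2, NA, NA),
                         c(NA, 1, NA, 3, NA)),
                   times = c(0, 0.5, 1, 1.5, 2))
  out <- impute_linear(pd)
  expect_true(all(out$observed))
  expect_equal(out$values[1, ], c(0, 1, 2, 2, 2))    # trailing run padded
  expect_equal(out$values[2, ], c(1, 1, 2, 3, 3))    # leading run padded

  # already-complete panels pass through unchanged
  full <- random_panel(3, 6, seed = 59)
  expect_identical(impute_linear(full), full)

  # interpolated values stay within the flanking observations
  set.seed(60)
  vals <- matrix(rnorm(200), 10, 20)
  mask <- matrix(runif(200) > 0.3, 10, 20)
  mask[, c(1, 20)] <- TRUE
  pd2 <- panel_data(vals, seq(0, 1, length.out = 20), observed = mask)
  imp <- impute_linear(pd2)
  for (i in 1:10) {
    obs_j <- which(mask[i, ])
    for (j in which(!mask[i, ])) {
      lo <- max(obs_j[obs_j < j]); hi <- min(obs_j[obs_j > j])
      expect_gte(imp$values[i, j], min(vals[i, lo], vals[i, hi]) - 1e-12)
      expect_lte(imp$values[i, j], max(vals[i, lo], vals[i, hi]) + 1e-12)
    }
  }

  expect_error(impute_linear(
    panel_data(rbind(c(1, NA, NA), c(1, 2, 3)), 1:3)),
    "at least two observed")
})

test_that("the benchmark generative model carries its published values", {
  p <- benchmark_params(0.15)
  expect_equal(p$alpha[1], 0.5)
  expect_equal(p$beta[1, 1, ], c(0, -1.5))
  expect_equal(p$omega[2, 2, ], c(0.5, -2))
  expect_equal(p$sigma2, matrix(0.15^2, 2, 3))
  expect_silent(validate_params <- rhlp_params(p$alpha, p$omega, p$beta,
                                               p$sigma2, p$spec))
  expect_warning(benchmark_params(0.3), "levels")
})
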