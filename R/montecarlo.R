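# Monte Carlo study harness: replicate the
# simulate -> mask -> impute -> fit pipeline under a data condition,
# score model selection, parameter recovery and classification, and
# aggregate the three measure families.

#' Run Monte Carlo replications under one data condition
#'
#' For each of `M` runs: simulate a panel from [benchmark_params()] at the
#' condition's `sigma`, mask cells completely at random at rate `pmiss`,
#' impute by linear interpolation, fit either the generating specification
#' alone or a full model grid, and record criterion values and ranks of the
#' generating spec, label-matched parameter estimates from its fit, and
#' classification accuracies on the cells observed before imputation. Run
#' seeds derive deterministically from `base_seed`.
#'
#' @param n_subjects,n_times,sigma,pmiss the data condition.
#' @param M number of Monte Carlo runs.
#' @param models `"true"` to fit only the generating spec, or a list with
#'   elements `Ks`, `Rs`, `ds` for a grid.
#' @param controls a [fit_controls].
#' @param base_seed integer; run `r` uses seeds drawn from a stream seeded
#'   with it.
#' @param truth optional generating [rhlp_params] (default
#'   `benchmark_params(sigma)`).
#' @return list of class `mc_runs`: per-run records with `est` (matched
#'   estimates), `cluster_acc`, `regime_acc`, `ranks`, `criteria`, `error`.
#' @export
run_condition <- function(n_subjects, n_times, sigma, pmiss, M = 20L,
                          models = "true", controls = fit_controls(),
                          base_seed = 1L, truth = NULL) {
  stopifnot(M >= 1)
  if (is.null(truth)) truth <- benchmark_params(sigma)
  spec_true <- truth$spec
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * M)
  records <- vector("list", M)
  for (r in seq_len(M)) {
    rec <- list(seed = seeds[r], error = NA_character_)
    sim <- simulate_rhlpmix(truth, n_subjects, n_times, seed = seeds[r])
    observed_pre <- matrix(TRUE, n_subjects, n_times)
    dat <- sim$data
    if (pmiss > 0) {
      sim <- apply_mcar(sim, pmiss, seed = seeds[M + r])
      observed_pre <- sim$data$observed
      dat <- impute_linear(sim$data)
    }
    fit_true <- NULL
    if (identical(models, "true")) {
      fit_true <- tryCatch(fit_rhlpmix(dat, spec_true, controls),
                           error = function(e) NULL)
      rec$ranks <- c(BIC = 1L, saBIC = 1L, AIC = 1L, AICc = 1L)
    } else {
      rep_ <- tryCatch(
        select_models(dat, models$Ks, models$Rs, models$ds,
                      variance = spec_true$variance, controls = controls),
        error = function(e) NULL)
      if (!is.null(rep_)) {
        rec$ranks <- vapply(c("BIC", "saBIC", "AIC", "AICc"), function(cr)
          rank_of(rep_, spec_true$K, spec_true$R, spec_true$d, cr),
          integer(1))
        rec$report_table <- rep_$table
        i <- which(rep_$table$K == spec_true$K &
                     rep_$table$R == spec_true$R &
                     rep_$table$d == spec_true$d)
        fit_true <- rep_$fits[[i]]
      }
    }
    if (is.null(fit_true)) {
      rec$error <- "fit of the generating spec failed"
      records[[r]] <- rec
      next
    }
    rec$criteria <- unlist(fit_true$criteria)
    est_lab <- classify(fit_true, dat)
    m <- match_labels(sim$truth, est_lab, spec_true$K, spec_true$R)
    acc <- label_accuracy(sim$truth, est_lab, observed_pre,
                          K = spec_true$K, R = spec_true$R)
    rec$cluster_acc <- acc$cluster_acc
    rec$regime_acc <- acc$regime_acc
    rec$regime_acc_subject <- acc$regime_acc_subject
    rec$est <- permute_params(fit_true$params, m)
    records[[r]] <- rec
  }
  structure(list(records = records,
                 condition = list(n_subjects = n_subjects,
                                  n_times = n_times, sigma = sigma,
                                  pmiss = pmiss),
                 truth = truth, models = models),
            class = "mc_runs")
}

#' Group-averaged RMSE of matched parameter estimates
#'
#' Parameters are grouped as: `alpha_1` (the single free mixing
#' proportion), `beta_m` for each polynomial order `m` (all clusters and
#' regimes pooled), `sigma` (residual standard deviations, compared on the
#' sigma -- not sigma-squared -- scale), and `omega_0` / `omega_1`
#' (switching intercepts / slopes of the non-reference regimes). For each
#' group the per-parameter RMSE over runs is averaged:
#' `rmse_G = (1/|G|) * sum_g sqrt((1/M) * sum_r (est_rg - true_g)^2)`.
#'
#' @param estimates list of label-matched [rhlp_params], one per run
#'   (failed runs may be `NULL` and are dropped).
#' @param truth the generating [rhlp_params].
#' @return named numeric vector of group RMSEs.
#' @export
rmse_by_group <- function(estimates, truth) {
  estimates <- Filter(Negate(is.null), estimates)
  if (!length(estimates)) stop("no estimates to score", call. = FALSE)
  s <- truth$spec
  groups <- list(alpha_1 = function(p) p$alpha[1L])
  for (m in 0:s$d) {
    groups[[paste0("beta_", m)]] <- local({
      mm <- m
      function(p) as.vector(p$beta[, , mm + 1L])
    })
  }
  groups$sigma <- function(p) as.vector(sqrt(p$sigma2))
  groups$omega_0 <- function(p) as.vector(p$omega[, -s$R, 1L])
  groups$omega_1 <- function(p) as.vector(p$omega[, -s$R, 2L])
  vapply(groups, function(f) {
    tv <- f(truth)
    errs <- sapply(estimates, function(e) f(e) - tv)
    errs <- matrix(errs, nrow = length(tv))
    mean(sqrt(rowMeans(errs^2)))
  }, numeric(1))
}

#' Aggregate Monte Carlo runs into the study's measure families
#'
#' Produces (1) information-criterion measures: per-criterion success
#' proportion (rank 1 of the generating spec) and mean and median ranks;
#' (2) parameter-accuracy measures: group-averaged RMSEs via
#' [rmse_by_group()] (means, plus medians of per-run absolute errors as a
#' robust alternative); (3) classification measures: mean cluster and
#' regime accuracies over runs, regimes scored on pre-imputation cells.
#'
#' @param runs an [run_condition()] result.
#' @return list of class `mc_measures` with elements `success_proportion`,
#'   `mean_rank`, `median_rank`, `rmse`, `cluster_acc`, `regime_acc`,
#'   `regime_acc_subject`, `n_failed`, `condition`, and `long` (a long-form
#'   data frame of all measures, one row per measure).
#' @export
summarize_runs <- function(runs) {
  stopifnot(inherits(runs, "mc_runs"))
  recs <- runs$records
  ok <- vapply(recs, function(r) is.na(r$error), logical(1))
  good <- recs[ok]
  if (!length(good)) stop("all runs failed", call. = FALSE)
  crits <- c("BIC", "saBIC", "AIC", "AICc")
  ranks <- do.call(rbind, lapply(good, function(r) r$ranks[crits]))
  success <- colMeans(ranks == 1L, na.rm = TRUE)
  rmse <- rmse_by_group(lapply(good, `[[`, "est"), runs$truth)
  cl <- vapply(good, `[[`, numeric(1), "cluster_acc")
  rg <- vapply(good, `[[`, numeric(1), "regime_acc")
  rgs <- vapply(good, `[[`, numeric(1), "regime_acc_subject")
  meas <- list(
    success_proportion = stats::setNames(as.numeric(success), crits),
    mean_rank = colMeans(ranks, na.rm = TRUE),
    median_rank = apply(ranks, 2L, stats::median, na.rm = TRUE),
    rmse = rmse,
    cluster_acc = mean(cl), regime_acc = mean(rg),
    regime_acc_subject = mean(rgs),
    n_failed = sum(!ok), condition = runs$condition
  )
  cond <- as.data.frame(runs$condition)
  long <- rbind(
    data.frame(cond, family = "criterion", measure = "success",
               name = crits, value = as.numeric(success)),
    data.frame(cond, family = "criterion", measure = "mean_rank",
               name = crits, value = as.numeric(meas$mean_rank)),
    data.frame(cond, family = "criterion", measure = "median_rank",
               name = crits, value = as.numeric(meas$median_rank)),
    data.frame(cond, family = "rmse", measure = "rmse",
               name = names(rmse), value = as.numeric(rmse)),
    data.frame(cond, family = "classification", measure = "accuracy",
               name = c("cluster", "regime", "regime_by_subject"),
               value = c(meas$cluster_acc, meas$regime_acc,
                         meas$regime_acc_subject))
  )
  meas$long <- long
  structure(meas, class = "mc_measures")
}

#' @export
print.mc_measures <- function(x, ...) {
  c0 <- x$condition
  cat(sprintf("Monte Carlo measures at N_p=%d, N_t=%d, sigma=%.2f, pmiss=%.2f (%d failed runs)\n",
              c0$n_subjects, c0$n_times, c0$sigma, c0$pmiss, x$n_failed))
  cat("  BIC success:", signif(x$success_proportion["BIC"], 3),
      " median rank:", x$median_rank["BIC"], "\n")
  cat("  cluster acc:", signif(x$cluster_acc, 4),
      " regime acc:", signif(x$regime_acc, 4), "\n")
  cat("  rmse:", paste(names(x$rmse), signif(x$rmse, 3), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}
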