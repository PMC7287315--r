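# MAP classification and label-matched accuracy scoring. A mixture
# likelihood is invariant to permutations of cluster labels (and, within a
# cluster, regime labels), so estimated labelings are matched to the truth
# by optimal assignment before any accuracy or parameter-error measure is
# computed.

#' Cluster and regime labeling of a panel
#'
#' @param cluster length-`N_p` integer vector of cluster labels in `1..K`.
#' @param regime `N_p x N_t` integer matrix of regime labels in `1..R`.
#' @return object of class `rhlp_labeling`.
#' @export
rhlp_labeling <- function(cluster, regime) {
  cluster <- as.integer(cluster)
  regime <- as.matrix(regime)
  storage.mode(regime) <- "integer"
  stopifnot(length(cluster) == nrow(regime), all(cluster >= 1L),
            all(regime >= 1L))
  structure(list(cluster = cluster, regime = regime),
            class = "rhlp_labeling")
}

#' MAP cluster and regime classification from a fit
#'
#' Each subject is assigned the cluster with the highest posterior
#' probability; each time point is assigned the regime with the highest
#' posterior probability conditional on the subject's MAP cluster. Argmax
#' ties break toward the smallest index.
#'
#' @param fit an [fit_rhlpmix()] result.
#' @param data the complete [panel_data] the fit was computed on.
#' @return an [rhlp_labeling].
#' @export
classify <- function(fit, data) {
  stopifnot(inherits(fit, "rhlp_fit"))
  require_complete(data)
  e <- rhlp_estep(data$values, data$times, fit$params, want_gamma = TRUE)
  cluster <- max.col(e$tau, ties.method = "first")
  np <- nrow(data$values); nt <- length(data$times)
  regime <- matrix(1L, np, nt)
  for (k in unique(cluster)) {
    rows <- which(cluster == k)
    g <- e$gamma[[k]]
    for (i in rows)
      regime[i, ] <- max.col(matrix(g[i, , ], nt, fit$spec$R),
                             ties.method = "first")
  }
  rhlp_labeling(cluster, regime)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Match estimated labels to true labels
#'
#' Finds the cluster-label permutation maximizing subject-level agreement
#' (optimal assignment on the `K x K` confusion matrix, by exhaustive search
#' over permutations -- `K` is small), then, within each matched cluster,
#' the regime permutation maximizing pointwise regime agreement.
#'
#' The returned permutations map estimated labels to true labels: an
#' estimated cluster `c` corresponds to true cluster `cluster_perm[c]`, and
#' an estimated regime `r` in estimated cluster `c` to true regime
#' `regime_perms[[c]][r]`.
#'
#' @param truth,est [rhlp_labeling] objects of the same dimensions.
#' @param K,R label ranges.
#' @return list with `cluster_perm` (length `K`) and `regime_perms` (list
#'   of length `K`, each length `R`).
#' @export
match_labels <- function(truth, est, K, R) {
  stopifnot(inherits(truth, "rhlp_labeling"), inherits(est, "rhlp_labeling"),
            length(truth$cluster) == length(est$cluster),
            all(dim(truth$regime) == dim(est$regime)))
  conf <- matrix(0, K, K)  # conf[e, t]: subjects with est e, truth t
  for (i in seq_along(truth$cluster))
    conf[est$cluster[i], truth$cluster[i]] <-
      conf[est$cluster[i], truth$cluster[i]] + 1
  best <- NULL; best_agree <- -1
  for (p in all_perms(K)) {
    agree <- sum(conf[cbind(seq_len(K), p)])
    if (agree > best_agree) { best_agree <- agree; best <- p }
  }
  cluster_perm <- as.integer(best)
  regime_perms <- vector("list", K)
  for (ce in seq_len(K)) {
    rows <- which(est$cluster == ce &
                    truth$cluster == cluster_perm[ce])
    if (!length(rows)) { regime_perms[[ce]] <- seq_len(R); next }
    rconf <- matrix(0, R, R)
    te <- est$regime[rows, , drop = FALSE]
    tt <- truth$regime[rows, , drop = FALSE]
    for (e2 in seq_len(R)) for (t2 in seq_len(R))
      rconf[e2, t2] <- sum(te == e2 & tt == t2)
    bestr <- NULL; bestr_agree <- -1
    for (p in all_perms(R)) {
      agree <- sum(rconf[cbind(seq_len(R), p)])
      if (agree > bestr_agree) { bestr_agree <- agree; bestr <- p }
    }
    regime_perms[[ce]] <- as.integer(bestr)
  }
  list(cluster_perm = cluster_perm, regime_perms = regime_perms)
}

# apply a label matching to an estimated labeling
relabel <- function(est, matching) {
  cluster <- matching$cluster_perm[est$cluster]
  regime <- est$regime
  for (ce in seq_along(matching$regime_perms)) {
    rows <- which(est$cluster == ce)
    if (length(rows))
      regime[rows, ] <- matrix(
        matching$regime_perms[[ce]][est$regime[rows, ]],
        nrow = length(rows))
  }
  rhlp_labeling(cluster, regime)
}

#' Label-matched classification accuracy
#'
#' Matches the estimated labeling to the truth (see [match_labels()]), then
#' reports the fraction of subjects whose cluster matches and the fraction
#' of cells whose regime matches. Regime accuracy is computed only over
#' cells where `observed` is `TRUE` -- the cells that were available before
#' imputation -- both pooled over all cells and averaged per subject.
#'
#' @param truth,est [rhlp_labeling] objects.
#' @param observed logical `N_p x N_t` mask of pre-imputation availability;
#'   defaults to all cells.
#' @param K,R label ranges; default to the maxima present in `truth`.
#' @return list with `cluster_acc`, `regime_acc` (pooled over observed
#'   cells) and `regime_acc_subject` (mean of per-subject accuracies).
#' @export
label_accuracy <- function(truth, est, observed = NULL,
                           K = max(truth$cluster),
                           R = max(truth$regime)) {
  if (is.null(observed))
    observed <- matrix(TRUE, nrow(truth$regime), ncol(truth$regime))
  m <- match_labels(truth, est, K, R)
  est2 <- relabel(est, m)
  cluster_acc <- mean(est2$cluster == truth$cluster)
  hit <- (est2$regime == truth$regime) & observed
  regime_acc <- sum(hit) / sum(observed)
  per_subj <- rowSums(hit) / pmax(rowSums(observed), 1L)
  list(cluster_acc = cluster_acc, regime_acc = regime_acc,
       regime_acc_subject = mean(per_subj[rowSums(observed) > 0]))
}

#' Permute parameter labels to align with a matching
#'
#' Reorders `alpha`, `omega`, `beta` and `sigma2` so estimated cluster `c`
#' moves to position `cluster_perm[c]` and estimated regime `r` within it
#' to `regime_perms[[c]][r]`. After a regime permutation the zero reference
#' row generally moves, so each cluster's switching coefficients are
#' re-expressed relative to the new last regime (subtracting its row leaves
#' all switching probabilities unchanged).
#'
#' @param params an [rhlp_params].
#' @param matching a [match_labels()] result.
#' @return an [rhlp_params] with permuted labels.
#' @export
permute_params <- function(params, matching) {
  s <- params$spec
  cp <- matching$cluster_perm
  alpha <- numeric(s$K)
  omega <- array(0, dim(params$omega))
  beta <- array(0, dim(params$beta))
  sigma2 <- params$sigma2
  for (ce in seq_len(s$K)) {
    ct <- cp[ce]
    rp <- matching$regime_perms[[ce]]
    alpha[ct] <- params$alpha[ce]
    for (re in seq_len(s$R)) {
      rt <- rp[re]
      omega[ct, rt, ] <- params$omega[ce, re, ]
      beta[ct, rt, ] <- params$beta[ce, re, ]
      sigma2[ct, rt] <- params$sigma2[ce, re]
    }
    ref <- omega[ct, s$R, ]
    omega[ct, , 1] <- omega[ct, , 1] - ref[1]
    omega[ct, , 2] <- omega[ct, , 2] - ref[2]
  }
  rhlp_params(alpha, omega, beta, sigma2, s)
}
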