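# Preparation of irregularly sampled event streams for model fitting:
# per-subject time rescaling to [0, 1], two-channel ratio computation,
# aggregation into equal time bins on a shared grid, and upper
# winsorization of extreme ratios.

#' Irregular event stream of one subject
#'
#' @param subject_id label.
#' @param times increasing raw timestamps (e.g. seconds).
#' @param values numeric vector (one channel) or two-column matrix / data
#'   frame with columns `left` and `right` (two channels, e.g. hand
#'   positions).
#' @return object of class `event_series`.
#' @export
event_series <- function(subject_id, times, values) {
  times <- as.numeric(times)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.matrix(values)) {
    stopifnot(ncol(values) == 2L, nrow(values) == length(times))
  } else {
    values <- as.numeric(values)
    stopifnot(length(values) == length(times))
  }
  if (any(diff(times) < 0)) stop("`times` must be non-decreasing", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  structure(list(subject_id = subject_id, times = times, values = values),
            class = "event_series")
}

#' Rescale a subject's event times to the unit interval
#'
#' `t' = (t - t_first) / (t_last - t_first)`, so the first event sits at 0
#' and the last at 1; idempotent on already rescaled series.
#'
#' @param series an [event_series] with at least two events.
#' @return the rescaled [event_series].
#' @export
rescale_time <- function(series) {
  stopifnot(inherits(series, "event_series"))
  if (length(series$times) < 2L)
    stop("need at least two events to rescale", call. = FALSE)
  span <- series$times[length(series$times)] - series$times[1L]
  if (span <= 0) stop("zero duration: cannot rescale", call. = FALSE)
  series$times <- (series$times - series$times[1L]) / span
  series
}

#' Right/left ratio channel
#'
#' Collapses a two-channel series to the per-event ratio `right / left`.
#' Events with a non-positive left channel are dropped (the ratio is
#' undefined there); the number dropped is attached as attribute
#' `"n_dropped"`.
#'
#' @param series a two-channel [event_series].
#' @return a one-channel [event_series].
#' @export
ratio_channel <- function(series) {
  stopifnot(inherits(series, "event_series"), is.matrix(series$values))
  left <- series$values[, 1L]; right <- series$values[, 2L]
  cn <- colnames(series$values)
  if (!is.null(cn) && all(c("left", "right") %in% cn)) {
    left <- series$values[, "left"]; right <- series$values[, "right"]
  }
  keep <- left > 0
  out <- event_series(series$subject_id, series$times[keep],
                      right[keep] / left[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Aggregate an event series into equal time bins
#'
#' With `n_bins` bins, bin `b` (0-based) covers `[b/n_bins, (b+1)/n_bins)`
#' and its event mean is assigned to grid point `b/n_bins`; events at
#' exactly `t = 1` average onto the final grid point. The result lives on
#' `n_bins + 1` equally spaced occasions in `[0, 1]`; empty bins yield
#' missing cells.
#'
#' @param series a rescaled one-channel [event_series].
#' @param n_bins number of aggregation intervals (default 200, giving 201
#'   occasions).
#' @return list with `times` (the grid), `values` (length `n_bins + 1`,
#'   `NA` at empty bins) and `subject_id`.
#' @export
aggregate_bins <- function(series, n_bins = 200L) {
  stopifnot(inherits(series, "event_series"), !is.matrix(series$values),
            n_bins >= 1)
  if (min(series$times) < 0 || max(series$times) > 1)
    stop("rescale the series to [0, 1] first", call. = FALSE)
  idx <- pmin(floor(series$times * n_bins), n_bins) + 1L  # t=1 -> last point
  vals <- rep(NA_real_, n_bins + 1L)
  agg <- tapply(series$values, idx, mean)
  vals[as.integer(names(agg))] <- agg
  list(times = seq(0, 1, length.out = n_bins + 1L), values = vals,
       subject_id = series$subject_id)
}

#' Upper winsorization
#'
#' Values above the `q`-quantile (linear-interpolation convention,
#' `stats::quantile` type 7) are replaced by that quantile.
#'
#' @param x numeric vector (NAs passed through).
#' @param q upper quantile in (0, 1), default 0.95.
#' @return winsorized vector.
#' @export
winsorize_upper <- function(x, q = 0.95) {
  stopifnot(q > 0, q < 1)
  cap <- stats::quantile(x, q, na.rm = TRUE, names = FALSE, type = 7)
  x[!is.na(x) & x > cap] <- cap
  x
}

#' Full preprocessing pipeline for two-channel event streams
#'
#' Per subject: rescale times to `[0, 1]`, take the right/left ratio
#' channel, aggregate into `n_bins` equal intervals on the shared
#' `n_bins + 1`-point grid; then winsorize ratios above the `winsor_q`
#' quantile (pooled across the sample by default, or per subject) and
#' impute remaining gaps by linear interpolation.
#'
#' @param events data frame with columns `subject`, `time`, `left`,
#'   `right`.
#' @param n_bins aggregation intervals.
#' @param winsor_q upper winsorization quantile; `NULL` skips winsorization.
#' @param scope `"pooled"` (one quantile for the whole sample) or
#'   `"subject"` (per-subject quantiles).
#' @param impute impute missing cells after winsorization (default `TRUE`).
#' @return a [panel_data]; the per-subject pre-imputation missing fraction
#'   is attached as attribute `"missing_fraction"`.
#' @export
preprocess_events <- function(events, n_bins = 200L, winsor_q = 0.95,
                              scope = c("pooled", "subject"),
                              impute = TRUE) {
  scope <- match.arg(scope)
  stopifnot(all(c("subject", "time", "left", "right") %in% names(events)))
  subs <- unique(events$subject)
  rows <- lapply(subs, function(s) {
    e <- events[events$subject == s, ]
    e <- e[order(e$time), ]
    es <- event_series(s, e$time, cbind(left = e$left, right = e$right))
    aggregate_bins(ratio_channel(rescale_time(es)), n_bins)
  })
  vals <- do.call(rbind, lapply(rows, `[[`, "values"))
  if (!is.null(winsor_q)) {
    if (scope == "pooled") {
      vals[] <- winsorize_upper(as.vector(vals), winsor_q)
    } else {
      vals <- t(apply(vals, 1L, winsorize_upper, q = winsor_q))
    }
  }
  pd <- panel_data(vals, rows[[1L]]$times, subject_ids = subs)
  miss <- 1 - rowMeans(pd$observed)
  if (impute) pd <- impute_linear(pd)
  attr(pd, "missing_fraction") <- stats::setNames(miss, subs)
  pd
}

#' Synthetic two-channel event-stream emulator
#'
#' Generates irregularly sampled left/right position streams that mimic the
#' structure of tablet hand-movement recordings in a proportional-reasoning
#' task: subjects fall into groups that move through same-height
#' (ratio near 1), noisy exploration, and target-ratio (right/left near 2)
#' phases at group-specific paces. Purely synthetic -- a test stand-in for
#' empirical recordings, not a reproduction of any real data set.
#'
#' @param n_subjects number of subjects.
#' @param events_per_subject mean number of events per subject (the actual
#'   count is drawn around it).
#' @param seed integer seed.
#' @param gap_prob probability of a silent (unrecorded) stretch inserted in
#'   a subject's stream, producing empty aggregation bins downstream.
#' @return data frame with columns `subject`, `time`, `left`, `right` plus
#'   attribute `"group"` (the generating group per subject).
#' @export
simulate_events <- function(n_subjects = 12L, events_per_subject = 800L,
                            seed = 1L, gap_prob = 0.6) {
  set.seed(as.integer(seed))
  out <- vector("list", n_subjects)
  group <- sample.int(2L, n_subjects, replace = TRUE)
  # group-specific switching structure on rescaled time
  om <- list(
    rbind(c(1.9, -7.9), c(1.9, -2.6), c(0, 0)),
    rbind(c(1.4, -14.7), c(0.4, -4.0), c(0, 0))
  )
  level <- c(1.0, 1.1, 2.0)    # same-height, exploring, target ratio
  noise <- c(0.05, 0.45, 0.12)
  for (i in seq_len(n_subjects)) {
    dur <- stats::runif(1, 200, 820)              # seconds
    n_ev <- max(50L, stats::rpois(1, events_per_subject))
    tt <- sort(stats::runif(n_ev, 0, dur))
    if (stats::runif(1) < gap_prob) {             # silent stretch
      g0 <- stats::runif(1, 0.1, 0.8) * dur
      keep <- tt < g0 | tt > g0 + 0.04 * dur
      keep[c(1L, length(tt))] <- TRUE
      tt <- tt[keep]
    }
    u <- tt / dur
    pr <- exp(log_regime_probabilities(om[[group[i]]], u))
    cum <- pr; for (r in 2:3) cum[, r] <- cum[, r - 1L] + cum[, r]
    h <- 1L + rowSums(stats::runif(length(u)) > cum[, -3L, drop = FALSE])
    ratio <- pmax(stats::rnorm(length(u), level[h], noise[h]), 0.05)
    left <- stats::runif(length(u), 2, 8)
    out[[i]] <- data.frame(subject = i, time = tt, left = left,
                           right = ratio * left)
  }
  res <- do.call(rbind, out)
  attr(res, "group") <- group
  res
}
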