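# Base-graphics displays for panels and fits.

#' Plot a panel of time series
#'
#' One line per subject over the shared grid; unobserved cells are left as
#' gaps. Lines can be colored by a grouping (e.g. MAP clusters).
#'
#' @param x a [panel_data].
#' @param col line colors, recycled over subjects, or a grouping vector.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.panel_data <- function(x, col = NULL, ...) {
  vals <- t(x$values)
  vals[t(!x$observed)] <- NA_real_
  if (is.null(col)) col <- "#00000055"
  graphics::matplot(x$times, vals, type = "l", lty = 1, col = col,
                    xlab = "time", ylab = "value", ...)
  invisible(x)
}

#' Plot a fitted mixRHLP model
#'
#' Two panels per cluster: the regime trend polynomials over the grid, and
#' the fitted logistic regime-probability curves.
#'
#' @param x an [fit_rhlpmix()] result.
#' @param data optional [panel_data] to draw behind the trends, colored by
#'   MAP cluster.
#' @param times evaluation grid (defaults to `data$times` or a 201-point
#'   grid on `[0, 1]`).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.rhlp_fit <- function(x, data = NULL, times = NULL, ...) {
  s <- x$spec
  if (is.null(times))
    times <- if (!is.null(data)) data$times else seq(0, 1, length.out = 201)
  X <- design_matrix(times, s$d)
  cl <- if (!is.null(data))
    max.col(x$cluster_posterior, ties.method = "first")
  op <- graphics::par(mfrow = c(2, s$K), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (k in seq_len(s$K)) {
    mu <- X %*% t(matrix(x$params$beta[k, , ], s$R, s$d + 1L))
    ylim <- range(mu, if (!is.null(data)) data$values[cl == k, ])
    graphics::matplot(times, mu, type = "n", ylim = ylim, xlab = "time",
                      ylab = "value",
                      main = sprintf("cluster %d trends", k))
    if (!is.null(data) && any(cl == k))
      graphics::matlines(data$times, t(data$values[cl == k, , drop = FALSE]),
                         lty = 1, col = "#00000022")
    graphics::matlines(times, mu, lty = 1, lwd = 2, col = seq_len(s$R) + 1L)
  }
  for (k in seq_len(s$K)) {
    pr <- regime_probabilities(matrix(x$params$omega[k, , ], s$R, 2L), times)
    graphics::matplot(times, pr, type = "l", lty = 1, lwd = 2,
                      col = seq_len(s$R) + 1L, ylim = c(0, 1),
                      xlab = "time", ylab = "P(regime)",
                      main = sprintf("cluster %d switching", k))
  }
  invisible(x)
}
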