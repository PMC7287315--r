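#' Multi-subject time-series panel on a shared time grid
#'
#' Bundles an `N_p x N_t` matrix of measurements with the shared grid of
#' measurement occasions and an observation mask. All subjects are measured
#' (or missing) on the same grid; this is the input container for every
#' fitting, simulation and classification function in the package.
#'
#' @param values numeric matrix, one row per subject, one column per time
#'   point. `NA` entries are taken as unobserved unless `observed` says
#'   otherwise.
#' @param times strictly increasing numeric vector of time points, one per
#'   column of `values`. Typically rescaled to `[0, 1]`.
#' @param observed optional logical matrix of the same shape as `values`;
#'   defaults to `!is.na(values)`.
#' @param subject_ids optional character/numeric labels, one per row.
#'
#' @return An object of class `panel_data`: a list with elements `values`,
#'   `times`, `observed` and `subject_ids`.
#' @examples
#' pd <- panel_data(matrix(rnorm(20), 4, 5), times = seq(0, 1, length.out = 5))
#' pd
#' @export
panel_data <- function(values, times, observed = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- as.numeric(times)
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(values))
  out <- structure(
    list(values = values, times = times, observed = observed,
         subject_ids = subject_ids),
    class = "panel_data"
  )
  validate_panel(out)
  out
}

validate_panel <- function(x) {
  stopifnot(inherits(x, "panel_data"))
  nt <- length(x$times)
  if (nt < 2L) stop("a panel needs at least two time points", call. = FALSE)
  if (!all(is.finite(x$times)) || any(diff(x$times) <= 0))
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  if (ncol(x$values) != nt)
    stop("ncol(values) must equal length(times)", call. = FALSE)
  if (nrow(x$values) < 1L) stop("a panel needs at least one subject", call. = FALSE)
  if (!identical(dim(x$observed), dim(x$values)))
    stop("`observed` must have the same shape as `values`", call. = FALSE)
  if (!is.logical(x$observed) || anyNA(x$observed))
    stop("`observed` must be logical with no NA", call. = FALSE)
  if (any(rowSums(x$observed) == 0L))
    stop("every subject must have at least one observed value", call. = FALSE)
  if (!all(is.finite(x$values[x$observed])))
    stop("observed values must be finite", call. = FALSE)
  if (length(x$subject_ids) != nrow(x$values))
    stop("one subject id per row is required", call. = FALSE)
  invisible(x)
}

#' @export
print.panel_data <- function(x, ...) {
  miss <- 1 - mean(x$observed)
  cat(sprintf(
    "panel_data: %d subjects x %d time points on [%g, %g], %.1f%% missing\n",
    nrow(x$values), length(x$times), min(x$times), max(x$times), 100 * miss))
  invisible(x)
}

#' @export
dim.panel_data <- function(x) dim(x$values)

#' Convert a panel to a long-form data frame
#'
#' @param x a [panel_data] object.
#' @param row.names,optional ignored, present for the generic.
#' @param ... ignored.
#' @return data frame with columns `subject`, `time`, `value`, `observed`;
#'   unobserved cells carry `NA` in `value`.
#' @export
as.data.frame.panel_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  np <- nrow(x$values); nt <- length(x$times)
  vals <- as.vector(t(x$values))
  vals[!as.vector(t(x$observed))] <- NA_real_
  data.frame(
    subject = rep(x$subject_ids, each = nt),
    time = rep(x$times, times = np),
    value = vals,
    observed = as.vector(t(x$observed))
  )
}

#' Read a panel from CSV
#'
#' Accepts wide form (one row per subject, columns are time points, column
#' names parseable as numbers or `t<j>`) or long form (columns `subject`,
#' `time`, `value`). Empty/NA cells are unobserved.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"wide"` or `"long"`.
#' @return a [panel_data].
#' @export
read_panel_csv <- function(path, format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE)
  if (format == "auto") {
    format <- if (all(c("subject", "time", "value") %in% names(df))) "long" else "wide"
  }
  if (format == "long") {
    times <- sort(unique(df$time))
    subs <- unique(df$subject)
    vals <- matrix(NA_real_, length(subs), length(times))
    i <- match(df$subject, subs)
    j <- match(df$time, times)
    vals[cbind(i, j)] <- df$value
    return(panel_data(vals, times, subject_ids = subs))
  }
  id_col <- which(tolower(names(df)) %in% c("subject", "id", "subject_id"))
  ids <- if (length(id_col)) df[[id_col[1]]] else seq_len(nrow(df))
  if (length(id_col)) df <- df[-id_col[1]]
  times <- suppressWarnings(as.numeric(sub("^t", "", names(df))))
  if (anyNA(times)) times <- seq(0, 1, length.out = ncol(df))
  panel_data(as.matrix(df), times, subject_ids = ids)
}

#' Write a panel to wide CSV (missing cells empty)
#'
#' @param x a [panel_data].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(x, path) {
  vals <- x$values
  vals[!x$observed] <- NA_real_
  df <- data.frame(subject = x$subject_ids, vals)
  names(df) <- c("subject", paste0("t", signif(x$times, 10)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
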