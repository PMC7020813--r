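#' Multivariate time-series container
#'
#' An `eco_ts` holds a sampled state trajectory: the phase vector
#' s = (x_1, ..., x_m) observed at n strictly increasing times.  Values are
#' stored as an n x m numeric matrix (rows = time points, columns = state
#' variables).  Missing observations are carried as an explicit logical gap
#' mask (and `NA` in `values`), never as sentinel numbers, so that nothing
#' downstream can mistake a gap for data.
#'
#' @param times numeric vector of observation times, strictly increasing.
#'   Units are arbitrary (months for monthly vegetation-index data); all
#'   downstream formulas depend on time differences only.
#' @param values numeric matrix (n x m) or vector (treated as one variable).
#' @param names character vector of m variable names.
#' @param meta free-form named list of provenance information.
#' @return an object of class `eco_ts` with fields `times`, `values`,
#'   `names`, `meta` and `gaps` (logical n x m mask, `TRUE` where missing).
#' @export
eco_ts <- function(times, values, names = NULL, meta = list()) {
  times <- as.numeric(times)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (length(times) != n) stop("length(times) must equal nrow(values)")
  if (n < 3L) stop("need at least 3 time points")
  if (m < 1L) stop("need at least one variable")
  if (anyNA(times)) stop("times must be finite")
  if (any(diff(times) <= 0)) {
    if (anyDuplicated(times)) stop("duplicate time values")
    stop("times must be strictly increasing")
  }
  if (is.null(names)) names <- colnames(values)
  if (is.null(names)) names <- paste0("x", seq_len(m))
  if (length(names) != m) stop("names must have one entry per variable")
  colnames(values) <- names
  gaps <- !is.finite(values)
  values[gaps] <- NA_real_
  structure(list(times = times, values = values, names = names,
                 meta = meta, gaps = gaps),
            class = "eco_ts")
}

#' @export
print.eco_ts <- function(x, ...) {
  cat(sprintf("<eco_ts> %d points x %d variable(s): %s\n",
              length(x$times), ncol(x$values),
              paste(x$names, collapse = ", ")))
  cat(sprintf("  t in [%g, %g]; %d gap cell(s)\n",
              x$times[1L], x$times[length(x$times)], sum(x$gaps)))
  invisible(x)
}

n_obs <- function(ts) length(ts$times)
has_gaps <- function(ts) any(ts$gaps)

#' Read a multivariate time series from CSV
#'
#' Reads a header CSV (UTF-8, "." decimal separator) into an [eco_ts].  Rows
#' are sorted by time; blank or non-finite cells become flagged gaps rather
#' than being dropped.
#'
#' @param path path to a CSV file with a header row.
#' @param time_col name of the time column (default `"t"`).
#' @param value_cols character vector of value columns to keep, in the
#'   requested order; `NULL` (default) keeps every non-time column.
#' @return an [eco_ts].
#' @export
read_timeseries <- function(path, time_col = "t", value_cols = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!time_col %in% names(df)) stop("unknown column: ", time_col)
  if (is.null(value_cols)) value_cols <- setdiff(names(df), time_col)
  missing_cols <- setdiff(value_cols, names(df))
  if (length(missing_cols)) stop("unknown column: ",
                                 paste(missing_cols, collapse = ", "))
  tm <- suppressWarnings(as.numeric(df[[time_col]]))
  if (anyNA(tm)) stop("time column not parseable as numeric: ", time_col)
  ord <- order(tm)
  tm <- tm[ord]
  if (anyDuplicated(tm)) stop("duplicate time values in column ", time_col)
  vals <- sapply(value_cols, function(cl) {
    suppressWarnings(as.numeric(df[[cl]][ord]))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(value_cols))
  eco_ts(tm, vals, names = value_cols, meta = list(source = path))
}

#' Write a time series to CSV
#'
#' Emits the same CSV dialect [read_timeseries] consumes: header row, "."
#' decimal separator, gaps as empty cells.
#'
#' @param ts an [eco_ts].
#' @param path output path.
#' @param time_col name for the time column.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, time_col = "t") {
  df <- data.frame(t = ts$times, check.names = FALSE)
  names(df) <- time_col
  for (j in seq_along(ts$names)) df[[ts$names[j]]] <- ts$values[, j]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Fill flagged gaps in a time series
#'
#' @param ts an [eco_ts] with zero or more flagged gaps.
#' @param method `"linear"` (interpolate in time between the bracketing
#'   observations) or `"ffill"` (carry the last observation forward).
#' @return a gap-free [eco_ts]; non-gap values are unchanged.
#' @export
interpolate_gaps <- function(ts, method = c("linear", "ffill")) {
  method <- match.arg(method)
  vals <- ts$values
  for (j in seq_len(ncol(vals))) {
    g <- ts$gaps[, j]
    if (!any(g)) next
    if (g[1L]) stop("gap at series start in variable '", ts$names[j],
                    "' cannot be filled with method=", method)
    if (method == "linear" && g[length(g)])
      stop("gap at series end in variable '", ts$names[j],
           "' cannot be filled with method=linear")
    ok <- !g
    if (method == "linear") {
      vals[g, j] <- stats::approx(ts$times[ok], vals[ok, j],
                                  xout = ts$times[g])$y
    } else {
      idx <- cummax(ifelse(ok, seq_along(g), 0L))
      vals[g, j] <- vals[idx[g], j]
    }
  }
  eco_ts(ts$times, vals, names = ts$names, meta = ts$meta)
}

#' Normalize each variable of a time series
#'
#' @param ts an [eco_ts] (gap-free for meaningful results; gaps are ignored
#'   in the statistics and preserved in the output).
#' @param mode `"minmax"` maps each variable affinely onto `[0, 1]`;
#'   `"zscore"` to mean 0, sd 1.
#' @return normalized [eco_ts].
#' @export
normalize_ts <- function(ts, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  vals <- ts$values
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    ok <- is.finite(v)
    if (diff(range(v[ok])) == 0)
      stop("variable '", ts$names[j], "' is constant; cannot normalize")
    if (mode == "minmax") {
      r <- range(v[ok])
      vals[, j] <- (v - r[1L]) / (r[2L] - r[1L])
    } else {
      vals[, j] <- (v - mean(v[ok])) / stats::sd(v[ok])
    }
  }
  out <- eco_ts(ts$times, vals, names = ts$names, meta = ts$meta)
  out$gaps <- ts$gaps
  out
}

#' Autocorrelation characteristic time tau0
#'
#' The memory span of a series, defined as the first lag at which its sample
#' autocorrelation function crosses zero.  Uses the biased (divide-by-n)
#' estimator with the mean removed, which is positive semidefinite; the
#' crossing is located by linear interpolation between the bracketing integer
#' lags and converted to time units via the mean sampling interval.
#'
#' @param ts an [eco_ts], gap-free in the chosen variable.
#' @param var variable name (default: first variable).
#' @param max_lag largest lag (in samples) to scan; must be `< n`.
#' @return the characteristic time in the units of `ts$times`, or `NA` if the
#'   autocorrelation does not cross zero within `max_lag`.
#' @export
autocorr_tau0 <- function(ts, var = ts$names[1L], max_lag = floor(n_obs(ts) / 3)) {
  j <- match(var, ts$names)
  if (is.na(j)) stop("unknown variable: ", var)
  x <- ts$values[, j]
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  if (anyNA(x)) stop("variable '", var, "' has gaps; fill them first")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("variable '", var, "' is constant")
  r <- vapply(seq_len(max_lag), function(k) {
    sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / denom
  }, numeric(1))
  r <- c(1, r)                       # r[1] is lag 0
  cross <- which(r[-length(r)] > 0 & r[-1L] <= 0)
  if (!length(cross)) return(NA_real_)
  k0 <- cross[1L]                    # lag k0-1 positive, lag k0 <= 0
  lag <- (k0 - 1) + r[k0] / (r[k0] - r[k0 + 1L])
  lag * mean(diff(ts$times))
}
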