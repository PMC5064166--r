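#' Potential field container
#'
#' A node x time matrix of potentials (mV) with its sampling rate. Used for
#' epicardial ground truth, body-surface measurements and reconstructions.
#'
#' @param values numeric matrix, nodes (or leads) x time samples, mV
#' @param fs sampling rate, Hz
#' @param t0 time of the first column, s
#' @return an object of class `potential_field`
#' @export
potential_field <- function(values, fs, t0 = 0) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("`values` must be a finite numeric matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be > 0")
  structure(list(values = values, fs = fs, t0 = t0), class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat("<potential_field> ", nrow(x$values), " channels x ", ncol(x$values),
      " samples @ ", x$fs, " Hz (", round(ncol(x$values) / x$fs, 3), " s from t0 = ",
      x$t0, " s)\n", sep = "")
  invisible(x)
}

#' Time axis of a potential field (s)
#' @param field a `potential_field`
#' @export
field_times <- function(field) {
  field$t0 + (seq_len(ncol(field$values)) - 1L) / field$fs
}

#' Extract a time window of a potential field
#' @param field a `potential_field`
#' @param from,to window bounds in seconds (inclusive of `from`, exclusive of
#'   `to`), on the same clock as `t0`
#' @export
field_window <- function(field, from, to) {
  tt <- field_times(field)
  keep <- tt >= from & tt < to
  if (!any(keep)) stop("empty time window [", from, ", ", to, ")")
  potential_field(field$values[, keep, drop = FALSE], field$fs,
                  t0 = tt[which(keep)[1]])
}

wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
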