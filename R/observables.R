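# Conversion curves, DP distributions and replicate statistics.

#' Glucose-weighted DP distribution of a run
#'
#' Rows are the recorded grid times; column d holds the number of glucose
#' monomers residing in cellulose polymers of DP d (in monomers) divided by
#' the total glucose in the system.  DP 1 is free glucose, DP 2 cellobiose;
#' each row sums to 1.  Requires `record_dp = TRUE` in the [run_config()].
#'
#' @param run a `sacch_run`.
#' @return matrix (times x DP).
#' @export
dp_histogram <- function(run) {
  stopifnot(inherits(run, "sacch_run"))
  if (is.null(run$dp)) stop("run was recorded without record_dp = TRUE")
  dp <- run$dp
  rownames(dp) <- run$timecourse$time
  colnames(dp) <- seq_len(ncol(dp))
  dp
}

#' Relative RMSE between two mean conversion curves
#'
#' `100 * ||a - b||_2 / ||b||_2` over the common time grid: the RMS of the
#' pointwise differences, normalized by the RMS magnitude of the reference
#' curve.  This global normalization keeps the statistic meaningful on curves
#' that start at zero conversion, where pointwise relative differences
#' diverge; for curves with a constant relative offset (e.g. `a = 1.01 * b`)
#' it coincides with the pointwise definition.
#'
#' @param a,b numeric vectors on a common time grid (e.g. two replicate-mean
#'   glucose-conversion curves; `b` is the reference).
#' @return relative RMSE in percent.
#' @export
replicate_rmse <- function(a, b) {
  if (length(a) != length(b)) stop("curves must share a common grid")
  nb <- sqrt(mean(b^2))
  if (nb == 0) return(0)
  sqrt(mean((a - b)^2)) / nb * 100
}

#' Mean final glucan conversion of a replicate set
#'
#' @param reps a `replicate_set` (see [simulate_replicates()]).
#' @param t_end evaluation time (defaults to the last grid point).
#' @export
endpoint_conversion <- function(reps, t_end = NULL) {
  stopifnot(inherits(reps, "replicate_set"))
  if (is.null(t_end)) t_end <- max(reps$times)
  idx <- which.min(abs(reps$times - t_end))
  mean(reps$glucan[idx, ])
}

#' Interpolate a replicate-mean curve at arbitrary time points
#'
#' @param reps a `replicate_set`.
#' @param times query times.
#' @param what `"glucan"` or `"xylan"`.
#' @export
interp_mean_curve <- function(reps, times, what = c("glucan", "xylan")) {
  what <- match.arg(what)
  y <- if (what == "glucan") reps$mean_glucan else reps$mean_xylan
  approx(reps$times, y, xout = times, rule = 2)$y
}

#' Write a timecourse (or replicate mean) as TSV
#'
#' @param run a `sacch_run`.
#' @param path output file.
#' @export
write_timecourse_tsv <- function(run, path) {
  write.table(run$timecourse, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
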