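#' Per-cell calcium trace set on a shared time grid
#'
#' @param time strictly increasing sample times, seconds.
#' @param traces numeric matrix, one column per cell, `length(time)` rows;
#'   values are calibrated concentrations (nM) or raw 340/380 ratios.
#' @param treatment_time agonist addition time, seconds, within
#'   `[time[1], time[length(time)])`.
#' @param meta optional metadata list (specimen id, group label, units).
#' @return A `trace_set` object.
#' @export
trace_set <- function(time, traces, treatment_time, meta = list()) {
  traces <- as.matrix(traces)
  if (length(time) != nrow(traces))
    stop("`time` length must match the number of trace rows")
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (treatment_time < time[1] || treatment_time >= time[length(time)])
    stop("`treatment_time` must lie within [time[1], time[end])")
  if (is.null(colnames(traces)))
    colnames(traces) <- sprintf("cell_%03d", seq_len(ncol(traces)))
  structure(list(time = as.numeric(time), traces = traces,
                 treatment_time = treatment_time, meta = meta),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d cell(s), %d samples over %.0f s, treatment at %.0f s\n",
              ncol(x$traces), length(x$time), diff(range(x$time)),
              x$treatment_time))
  invisible(x)
}

#' Ratiometric trace from excitation pair
#'
#' Elementwise 340/380 nm ratio with a floor guarding the denominator:
#' `numerator / pmax(denominator, floor)`. Samples where the denominator
#' fell below the floor are reported in the `"floored"` attribute for QC.
#'
#' @param numerator,denominator numeric vectors or matrices of equal shape
#'   (340 nm and 380 nm series).
#' @param floor positive lower bound applied to the denominator.
#' @return The ratio, same shape as the inputs, with attribute `floored`
#'   (logical, `TRUE` where the floor engaged).
#' @export
compute_ratio <- function(numerator, denominator, floor = 1e-6) {
  stopifnot(length(numerator) == length(denominator), floor > 0)
  out <- numerator / pmax(denominator, floor)
  attr(out, "floored") <- denominator < floor
  out
}

#' Baseline statistics of a trace
#'
#' Mean and sample SD of all samples strictly before the treatment time
#' (the full pre-treatment window).
#'
#' @param trace numeric vector of one cell's series.
#' @param time sample times, seconds.
#' @param treatment_time agonist addition time, seconds.
#' @return List with `mean`, `sd`, and `n` (number of baseline samples).
#' @export
baseline_stats <- function(trace, time, treatment_time) {
  stopifnot(length(trace) == length(time))
  idx <- time < treatment_time
  if (sum(idx) < 3)
    stop(sprintf("need >= 3 pre-treatment samples, found %d", sum(idx)))
  list(mean = mean(trace[idx]), sd = stats::sd(trace[idx]), n = sum(idx))
}

#' Responsive-cell criterion for a single trace
#'
#' A cell is responsive when its maximum in the response window rises at
#' least `k` baseline standard deviations above the baseline mean:
#' `(peak - baseline_mean) >= k * baseline_sd`, boundary inclusive. The
#' response window runs from the treatment time to the end of the trace.
#'
#' @inheritParams baseline_stats
#' @param k criterion multiplier (default 3).
#' @param baseline optional precomputed [baseline_stats()]; computed if
#'   missing.
#' @return List with `responsive` (logical), `peak`, `peak_time`, `delta`
#'   (`peak - baseline_mean`, reported regardless of the flag), and the
#'   baseline used.
#' @export
classify_responsive <- function(trace, time, treatment_time, k = 3,
                                baseline = NULL) {
  stopifnot(length(trace) == length(time), k >= 0)
  if (is.null(baseline)) baseline <- baseline_stats(trace, time, treatment_time)
  win <- time >= treatment_time
  if (!any(win)) stop("empty response window")
  peak_i <- which(win)[which.max(trace[win])]
  peak <- trace[peak_i]
  delta <- peak - baseline$mean
  list(responsive = delta >= k * baseline$sd,
       peak = peak, peak_time = time[peak_i], delta = delta,
       baseline = baseline)
}

#' Analyze a trace set: baselines, responders, evoked delta-calcium
#'
#' Applies [baseline_stats()] and [classify_responsive()] to every cell and
#' summarizes the set: the resting level is the mean baseline over all
#' cells; the evoked response is the mean of (peak - baseline) over
#' responsive cells only, and is reported missing (`NA`) when no cell
#' responds.
#'
#' @param traces a [trace_set()].
#' @param k responsive-cell criterion multiplier (default 3).
#' @return A `responsiveness_result`: `cells` (per-cell data frame:
#'   `baseline_mean`, `baseline_sd`, `peak`, `peak_time`, `responsive`,
#'   `delta` — `NA` for non-responsive cells), `resting_ca` (nM),
#'   `delta_ca` (nM or `NA`), `responder_fraction`, `n_cells`, `k`,
#'   `treatment_time`.
#' @export
analyze_traces <- function(traces, k = 3) {
  stopifnot(inherits(traces, "trace_set"))
  n <- ncol(traces$traces)
  per <- lapply(seq_len(n), function(i) {
    r <- classify_responsive(traces$traces[, i], traces$time,
                             traces$treatment_time, k = k)
    data.frame(cell = colnames(traces$traces)[i],
               baseline_mean = r$baseline$mean, baseline_sd = r$baseline$sd,
               peak = r$peak, peak_time = r$peak_time,
               responsive = r$responsive,
               delta = if (r$responsive) r$delta else NA_real_)
  })
  cells <- do.call(rbind, per)
  summarize_set(cells, k = k, treatment_time = traces$treatment_time)
}

#' Set-level summary from per-cell responsiveness results
#'
#' @param cells per-cell data frame as produced by [analyze_traces()]
#'   (columns `baseline_mean`, `responsive`, `delta`).
#' @param k criterion multiplier used (carried into the result).
#' @param treatment_time treatment time used (carried into the result).
#' @return A `responsiveness_result`; see [analyze_traces()].
#' @export
summarize_set <- function(cells, k = 3, treatment_time = NA_real_) {
  n <- nrow(cells)
  resp <- cells$responsive
  structure(list(cells = cells,
                 resting_ca = if (n) mean(cells$baseline_mean) else NA_real_,
                 delta_ca = if (any(resp)) mean(cells$delta[resp]) else NA_real_,
                 responder_fraction = if (n) mean(resp) else NA_real_,
                 n_cells = n, k = k, treatment_time = treatment_time),
            class = "responsiveness_result")
}

#' @export
print.responsiveness_result <- function(x, ...) {
  cat(sprintf("<responsiveness_result> %d cell(s), %.0f%% responsive (k = %g)\n",
              x$n_cells, 100 * x$responder_fraction, x$k))
  cat(sprintf("  resting [Ca2+]: %.1f nM; evoked delta[Ca2+]: %s nM\n",
              x$resting_ca,
              if (is.na(x$delta_ca)) "undefined (no responsive cells)"
              else sprintf("%.1f", x$delta_ca)))
  invisible(x)
}

#' Write trace analysis results to disk
#'
#' Per-cell CSV plus a set-level JSON summary.
#'
#' @param result a [analyze_traces()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace_results <- function(result, dir) {
  stopifnot(inherits(result, "responsiveness_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(resting_ca_nM = result$resting_ca,
         delta_ca_nM = result$delta_ca,
         responder_fraction = result$responder_fraction,
         n_cells = result$n_cells, k = result$k,
         treatment_time_s = result$treatment_time),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
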