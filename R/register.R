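#' Register pre/post micrographs by integer translation
#'
#' Recovers the integer pixel translation aligning two frames of the same
#' specimen, as needed to compare regions of interest between before- and
#' after-impact micrographs. Specimens re-imaged in a fixed holder move
#' essentially in-plane, so the model is pure translation (no rotation or
#' scale): the translation is located by FFT cross-correlation of the
#' mean-subtracted images, restricted to `|shift| <= max_shift`, and refined
#' to the exact normalized cross-correlation (NCC) maximum over the
#' 8-neighbourhood of the peak.
#'
#' The returned `offset = c(drow, dcol)` satisfies
#' `moving[r, c] ~ reference[r - drow, c - dcol]`.
#'
#' @param reference,moving numeric matrices of identical size (e.g. pre- and
#'   post-impact projections).
#' @param max_shift maximum translation searched, pixels (default 50).
#' @param score_floor NCC below which the alignment is flagged
#'   low-confidence (the offset is still returned).
#' @return A `roi_alignment`: list with `offset`, `score` (NCC in
#'   `[-1, 1]`), `overlap_ref` and `overlap_mov` (`c(row0, row1, col0, col1)`
#'   rectangles valid in each frame), and `low_confidence`.
#' @export
register_roi <- function(reference, moving, max_shift = 50,
                         score_floor = 0.2) {
  stopifnot(is.matrix(reference), is.matrix(moving),
            identical(dim(reference), dim(moving)), max_shift >= 0)
  h <- nrow(reference); w <- ncol(reference)
  if (max_shift >= min(h, w))
    stop("`max_shift` must be smaller than the image size")
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  shifts <- -max_shift:max_shift
  cc_win <- cc[(shifts %% h) + 1, (shifts %% w) + 1, drop = FALSE]
  peak <- arrayInd(which.max(cc_win), dim(cc_win))
  dr0 <- shifts[peak[1]]; dc0 <- shifts[peak[2]]

  best <- list(score = -Inf, dr = dr0, dc = dc0)
  for (dr in (dr0 - 1):(dr0 + 1)) for (dc in (dc0 - 1):(dc0 + 1)) {
    if (abs(dr) > max_shift || abs(dc) > max_shift) next
    s <- ncc_at(reference, moving, dr, dc)
    if (s > best$score) best <- list(score = s, dr = dr, dc = dc)
  }
  dr <- best$dr; dc <- best$dc
  rows <- c(max(1, 1 - dr), min(h, h - dr))
  cols <- c(max(1, 1 - dc), min(w, w - dc))
  if (rows[1] > rows[2] || cols[1] > cols[2])
    stop("empty overlap between frames at the recovered offset")
  structure(list(offset = c(dr, dc), score = best$score,
                 overlap_ref = c(rows, cols),
                 overlap_mov = c(rows + dr, cols + dc),
                 low_confidence = best$score < score_floor,
                 max_shift = max_shift),
            class = "roi_alignment")
}

# Exact NCC of the overlapping region at a given integer shift.
ncc_at <- function(reference, moving, dr, dc) {
  h <- nrow(reference); w <- ncol(reference)
  rows <- max(1, 1 - dr):min(h, h - dr)
  cols <- max(1, 1 - dc):min(w, w - dc)
  if (!length(rows) || !length(cols)) return(-Inf)
  x <- as.numeric(reference[rows, cols])
  y <- as.numeric(moving[rows + dr, cols + dc])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' @export
print.roi_alignment <- function(x, ...) {
  cat(sprintf("<roi_alignment> offset (%+d, %+d) px, NCC %.3f%s\n",
              x$offset[1], x$offset[2], x$score,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}
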