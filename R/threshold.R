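#' Otsu threshold of a grayscale image
#'
#' Returns the intensity cut that maximizes the between-class variance of
#' the image histogram. The histogram uses `n_bins` equal-width bins over
#' the observed min-max range regardless of bit depth; candidate cuts are
#' the interior bin edges and the first maximizer is returned when several
#' cuts tie. Foreground is `image > threshold`.
#'
#' @param image numeric matrix (or array) of intensities with at least two
#'   distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold, a single number strictly inside the intensity
#'   range.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (!length(v)) stop("image has no finite pixels")
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("cannot threshold a constant image (no separable classes)")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- .bincode(v, breaks, right = TRUE, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  # class means from the actual pixel values in each bin (not bin midpoints)
  sums <- numeric(n_bins)
  agg <- tapply(v, bin, sum)
  sums[as.integer(names(agg))] <- agg
  w0 <- cumsum(counts)
  m0 <- cumsum(sums)
  n <- w0[n_bins]; mtot <- m0[n_bins]
  # between-class variance after each interior cut k (classes: bins <= k, > k)
  k <- seq_len(n_bins - 1)
  p0 <- w0[k] / n
  mu0 <- ifelse(w0[k] > 0, m0[k] / w0[k], 0)
  mu1 <- ifelse(n - w0[k] > 0, (mtot - m0[k]) / (n - w0[k]), 0)
  bcv <- p0 * (1 - p0) * (mu0 - mu1)^2
  bcv[p0 == 0 | p0 == 1] <- -Inf
  breaks[which.max(bcv) + 1]
}
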