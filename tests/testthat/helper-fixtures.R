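# Shared fixtures, built in code at test time.

# Small field for fast generator tests.
small_field <- function(seed = 1, ...) {
  args <- list(width = 192, height = 192, n_cells = 40, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(field_spec, args)
}

# Noise- and background-free field (images equal their truth raster).
clean_field <- function(seed = 1, ...) {
  small_field(seed = seed, noise_sd = 0, background_level = 0, ...)
}

# Single-channel image of hard discs on a flat background.
disc_image <- function(centers, radii, height, width, level = 200,
                       background = 0) {
  img <- matrix(background, height, width)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    ii <- max(1, floor(centers[i, 1] - r)):min(height, ceiling(centers[i, 1] + r))
    jj <- max(1, floor(centers[i, 2] - r)):min(width, ceiling(centers[i, 2] + r))
    mask <- outer((ii - centers[i, 1])^2, (jj - centers[i, 2])^2, "+") <= r^2
    blk <- img[ii, jj]
    blk[mask] <- level
    img[ii, jj] <- blk
  }
  img
}

# Exhaustive-scan Otsu oracle for integer-valued images: tries every
# integer cut t, classes = {v <= t}, {v > t}, maximizes between-class
# variance computed directly from the raw pixel values.
otsu_bruteforce <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  cand <- min(v):(max(v) - 1)
  bcv <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# Greedy one-to-one matching of segmented centroids to true centres within
# a tolerance radius; returns counts for precision/recall.
match_centroids <- function(seg_cells, truth, tol) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(seg_cells))) {
    d <- sqrt((truth$row - seg_cells$centroid_row[i])^2 +
              (truth$col - seg_cells$centroid_col[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { used[j] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(seg_cells) - tp, fn = nrow(truth) - tp)
}
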