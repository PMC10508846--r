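#' Segment cells by distance-transform watershed
#'
#' Segments a binary foreground into individual cells: the Euclidean
#' distance transform of the foreground seeds a watershed that splits
#' touching cells, regions smaller than `min_cell_area` are discarded as
#' debris, and surviving regions are relabelled `1..k` in original label
#' order. Per-cell centroids, areas and (optionally) mean channel
#' intensities are tabulated.
#'
#' @param binary logical (or 0/1 numeric) foreground matrix, e.g.
#'   `image > otsu_threshold(image)`.
#' @param intensity optional named list of intensity images (matrices of the
#'   same size); a `mean_<name>` column is added per image.
#' @param pixel_size micrometres per pixel.
#' @param min_cell_area minimum cell area in square micrometres (default 20,
#'   excluding debris).
#' @param min_separation minimum separation of watershed seed maxima, in
#'   micrometres; roughly the expected cell radius (default 5).
#' @return A `cell_segmentation`: list with `labels` (integer matrix,
#'   0 = background), `cells` (data frame: `label`, `centroid_row`,
#'   `centroid_col`, `area_px`, `area_um2`, mean intensities), and
#'   `pixel_size`. An empty foreground yields zero labels, not an error.
#' @export
segment_cells <- function(binary, intensity = NULL, pixel_size = 1,
                          min_cell_area = 20, min_separation = 5) {
  stopifnot(pixel_size > 0, min_cell_area >= 0, min_separation > 0)
  bw <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  empty <- function() {
    cells <- data.frame(label = integer(0), centroid_row = numeric(0),
                        centroid_col = numeric(0), area_px = numeric(0),
                        area_um2 = numeric(0))
    for (nm in names(intensity)) cells[[paste0("mean_", nm)]] <- numeric(0)
    structure(list(labels = matrix(0L, nrow(bw), ncol(bw)), cells = cells,
                   pixel_size = pixel_size), class = "cell_segmentation")
  }
  if (!any(bw > 0)) return(empty())
  dm <- EBImage::distmap(bw)
  ext <- max(1L, as.integer(ceiling(min_separation / pixel_size)))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  labs <- matrix(as.integer(ws), nrow(bw), ncol(bw))

  area_px <- tabulate(labs[labs > 0L])
  keep <- which(area_px * pixel_size^2 >= min_cell_area & area_px > 0)
  if (!length(keep)) return(empty())
  remap <- integer(max(labs))
  remap[keep] <- seq_along(keep)
  labs[labs > 0L] <- remap[labs[labs > 0L]]

  k <- length(keep)
  idx <- which(labs > 0L)
  lab_v <- labs[idx]
  rows <- (idx - 1L) %% nrow(labs) + 1L
  cols <- (idx - 1L) %/% nrow(labs) + 1L
  area <- tabulate(lab_v, nbins = k)
  cells <- data.frame(
    label = seq_len(k),
    centroid_row = as.numeric(tapply(rows, lab_v, mean)),
    centroid_col = as.numeric(tapply(cols, lab_v, mean)),
    area_px = area,
    area_um2 = area * pixel_size^2)
  for (nm in names(intensity)) {
    img <- intensity[[nm]]
    stopifnot(identical(dim(img), dim(labs)))
    cells[[paste0("mean_", nm)]] <- as.numeric(tapply(img[idx], lab_v, mean))
  }
  structure(list(labels = labs, cells = cells, pixel_size = pixel_size),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d cell(s), %.0f um^2 total foreground\n",
              nrow(x$cells), sum(x$cells$area_um2)))
  if ("class" %in% names(x$cells))
    print(table(x$cells$class))
  invisible(x)
}

#' Classify segmented cells as live or dead
#'
#' Each cell's mean intensity in the live (calcein) and dead (ethidium
#' homodimer) channels is scaled by the channel's own Otsu threshold, which
#' removes the arbitrary gain difference between fluorophores; a cell is
#' classed `dead` when its scaled dead-channel mean is at least (under the
#' default, conservative tie-break) its scaled live-channel mean. If a
#' channel is constant (no Otsu threshold exists) its mean intensity is
#' used as the scale instead.
#'
#' @param seg a [segment_cells()] result.
#' @param live,dead live- and dead-channel intensity images aligned with
#'   `seg$labels`.
#' @param tie_break `"dead"` (default; ties are classed dead, conservative
#'   for an injury assay) or `"live"`.
#' @return `seg` with a `class` column (`"live"`/`"dead"`) added to
#'   `seg$cells`.
#' @export
classify_viability <- function(seg, live, dead, tie_break = c("dead", "live")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(seg, "cell_segmentation"),
            identical(dim(live), dim(seg$labels)),
            identical(dim(dead), dim(seg$labels)))
  channel_scale <- function(img) {
    tryCatch(otsu_threshold(img),
             error = function(e) max(mean(img), 1e-12))
  }
  s_live <- channel_scale(live)
  s_dead <- channel_scale(dead)
  idx <- which(seg$labels > 0L)
  if (nrow(seg$cells)) {
    lab_v <- seg$labels[idx]
    m_live <- as.numeric(tapply(live[idx], lab_v, mean)) / s_live
    m_dead <- as.numeric(tapply(dead[idx], lab_v, mean)) / s_dead
    seg$cells$class <- if (tie_break == "dead")
      ifelse(m_dead >= m_live, "dead", "live")
    else
      ifelse(m_dead > m_live, "dead", "live")
  } else {
    seg$cells$class <- character(0)
  }
  seg
}
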