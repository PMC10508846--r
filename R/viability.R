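#' Quantify impact-induced cell death between registered frames
#'
#' Accounts live/dead cell counts and areas inside the overlap region of
#' interest shared by a registered pre/post pair, and derives the headline
#' impact-induced death area: the post-impact dead area minus the
#' pre-impact dead area within the ROI. The raw signed difference is
#' retained alongside the value clamped at zero; the death-area fraction
#' normalizes the clamped value by the pre-impact live area in the ROI.
#' Accounting is area-based (no tracking of individual cells across
#' frames).
#'
#' @param pre_seg,post_seg classified segmentations
#'   ([classify_viability()]) of the pre and post frames.
#' @param alignment a [register_roi()] result with the pre frame as
#'   reference.
#' @return A `viability_result`: per-frame live/dead counts and areas
#'   (um^2) inside the ROI, `death_area_um2` (clamped at 0),
#'   `death_area_raw_um2`, `death_area_fraction` in `[0, 1]` (NA when no
#'   pre-impact live area), and the ROI rectangles.
#' @export
quantify_viability <- function(pre_seg, post_seg, alignment) {
  stopifnot(inherits(pre_seg, "cell_segmentation"),
            inherits(post_seg, "cell_segmentation"),
            inherits(alignment, "roi_alignment"),
            "class" %in% names(pre_seg$cells),
            "class" %in% names(post_seg$cells))
  if (pre_seg$pixel_size != post_seg$pixel_size)
    stop("pre and post segmentations have different pixel sizes")
  frame_stats <- function(seg, roi) {
    if (roi[1] > roi[2] || roi[3] > roi[4])
      stop("empty overlap ROI")
    sub <- seg$labels[roi[1]:roi[2], roi[3]:roi[4]]
    px <- tabulate(sub[sub > 0L], nbins = max(nrow(seg$cells), 1L))
    cls <- seg$cells$class
    in_roi <- seg$cells$centroid_row >= roi[1] &
      seg$cells$centroid_row <= roi[2] &
      seg$cells$centroid_col >= roi[3] &
      seg$cells$centroid_col <= roi[4]
    list(live_count = sum(in_roi & cls == "live"),
         dead_count = sum(in_roi & cls == "dead"),
         live_area_um2 = sum(px[cls == "live"]) * seg$pixel_size^2,
         dead_area_um2 = sum(px[cls == "dead"]) * seg$pixel_size^2)
  }
  pre <- frame_stats(pre_seg, alignment$overlap_ref)
  post <- frame_stats(post_seg, alignment$overlap_mov)
  raw <- post$dead_area_um2 - pre$dead_area_um2
  death <- max(0, raw)
  frac <- if (pre$live_area_um2 > 0) min(1, death / pre$live_area_um2) else NA_real_
  structure(list(pre = pre, post = post,
                 death_area_um2 = death, death_area_raw_um2 = raw,
                 death_area_fraction = frac,
                 roi_pre = alignment$overlap_ref,
                 roi_post = alignment$overlap_mov,
                 offset = alignment$offset,
                 alignment_score = alignment$score),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat("<viability_result>\n")
  cat(sprintf("  pre : %d live / %d dead, %.0f / %.0f um^2\n",
              x$pre$live_count, x$pre$dead_count,
              x$pre$live_area_um2, x$pre$dead_area_um2))
  cat(sprintf("  post: %d live / %d dead, %.0f / %.0f um^2\n",
              x$post$live_count, x$post$dead_count,
              x$post$live_area_um2, x$post$dead_area_um2))
  cat(sprintf("  impact-induced death area: %.0f um^2 (raw %+.0f), fraction %.3f\n",
              x$death_area_um2, x$death_area_raw_um2, x$death_area_fraction))
  invisible(x)
}

#' Full viability pipeline on a pre/post stack pair
#'
#' Runs the complete impact-viability analysis: maximum-intensity
#' projection of both channels in both frames, registration of the frames
#' (on the pixelwise maximum of the two channel projections), Otsu
#' thresholding of that combined image, distance-transform watershed
#' segmentation, per-cell live/dead classification, and death-area
#' quantification inside the registered overlap ROI.
#'
#' @param pre,post [micrograph_stack()]s with channels `live` and `dead`.
#' @param min_cell_area,min_separation segmentation parameters, um^2 and um
#'   (see [segment_cells()]).
#' @param max_shift registration search bound, pixels.
#' @param tie_break live/dead tie-break (see [classify_viability()]).
#' @return A `viability_analysis`: list with `result` (the
#'   [quantify_viability()] output), `pre_seg`, `post_seg`, `alignment`.
#' @export
analyze_viability_pair <- function(pre, post, min_cell_area = 20,
                                   min_separation = 5, max_shift = 50,
                                   tie_break = "dead") {
  stopifnot(inherits(pre, "micrograph_stack"),
            inherits(post, "micrograph_stack"))
  if (pre$pixel_size != post$pixel_size)
    stop("pre and post stacks have different pixel sizes")
  proj <- function(stk) {
    live <- max_intensity_projection(stk, "live")
    dead <- max_intensity_projection(stk, "dead")
    list(live = live, dead = dead, all = pmax(live, dead))
  }
  p1 <- proj(pre); p2 <- proj(post)
  alignment <- register_roi(p1$all, p2$all, max_shift = max_shift)
  seg_frame <- function(p) {
    binary <- p$all > otsu_threshold(p$all)
    seg <- segment_cells(binary, intensity = list(live = p$live, dead = p$dead),
                         pixel_size = pre$pixel_size,
                         min_cell_area = min_cell_area,
                         min_separation = min_separation)
    classify_viability(seg, p$live, p$dead, tie_break = tie_break)
  }
  pre_seg <- seg_frame(p1)
  post_seg <- seg_frame(p2)
  structure(list(result = quantify_viability(pre_seg, post_seg, alignment),
                 pre_seg = pre_seg, post_seg = post_seg,
                 alignment = alignment),
            class = "viability_analysis")
}

#' @export
print.viability_analysis <- function(x, ...) {
  print(x$alignment)
  print(x$result)
  invisible(x)
}

#' Write a viability analysis to disk
#'
#' Writes the headline result as JSON, the per-cell tables as CSV
#' (`label, centroid_row, centroid_col, area_um2, class` for each frame),
#' and the label images as 16-bit TIFF.
#'
#' @param analysis a [analyze_viability_pair()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_viability_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "viability_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- analysis$result
  jsonlite::write_json(
    list(pre = res$pre, post = res$post,
         death_area_um2 = res$death_area_um2,
         death_area_raw_um2 = res$death_area_raw_um2,
         death_area_fraction = res$death_area_fraction,
         offset = res$offset, alignment_score = res$alignment_score,
         roi_pre = res$roi_pre, roi_post = res$roi_post),
    file.path(dir, "viability.json"), auto_unbox = TRUE, digits = NA)
  keep <- c("label", "centroid_row", "centroid_col", "area_um2", "class")
  utils::write.csv(analysis$pre_seg$cells[, keep],
                   file.path(dir, "cells_pre.csv"), row.names = FALSE)
  utils::write.csv(analysis$post_seg$cells[, keep],
                   file.path(dir, "cells_post.csv"), row.names = FALSE)
  for (nm in c("pre_seg", "post_seg")) {
    labs <- analysis[[nm]]$labels
    tiff::writeTIFF(labs / max(1L, max(labs)),
                    file.path(dir, paste0(sub("_seg", "", nm), "_labels.tif")),
                    bits.per.sample = 16L)
  }
  invisible(dir)
}
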