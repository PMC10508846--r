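#' Integrated density over a cell mask
#'
#' Sum of pixel intensities over the mask (equivalently mean intensity
#' times pixel area). Optional constant background subtraction is off by
#' default.
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix of the same size, or integer indices into
#'   `image`; must select at least one pixel.
#' @param background constant background level subtracted per pixel
#'   (default 0).
#' @return A single number, intensity times pixels.
#' @export
integrated_density <- function(image, mask, background = 0) {
  if (is.logical(mask)) {
    stopifnot(identical(dim(mask), dim(image)))
    mask <- which(mask)
  }
  if (!length(mask)) stop("empty cell mask")
  if (any(mask < 1 | mask > length(image)))
    stop("mask indices outside image bounds")
  sum(image[mask] - background)
}

#' Circularity of a cell mask
#'
#' `4 * pi * area / perimeter^2`, clipped to `[0, 1]`; 1 for a perfect
#' circle. The perimeter is the length of the closed 8-connected boundary
#' chain (unit steps for lateral moves, `sqrt(2)` for diagonal moves),
#' obtained from the object contour. Masks too small to carry a contour
#' (single pixels) are assigned circularity 1.
#'
#' @param mask logical matrix containing a single connected cell mask.
#' @return Circularity in `[0, 1]`.
#' @export
circularity <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  area <- sum(m)
  if (area == 0) stop("empty cell mask")
  oc <- EBImage::ocontour(m)[[1]]
  if (is.null(oc) || nrow(oc) < 3) return(1)
  steps <- oc - oc[c(2:nrow(oc), 1), ]
  perim <- sum(sqrt(rowSums(steps^2)))
  if (perim == 0) return(1)
  min(1, 4 * pi * area / perim^2)
}

#' Select circular-cell ROIs per compartment
#'
#' Keeps cells whose circularity meets `circularity_min` and selects up to
#' `n_target` per compartment, ranked by descending circularity with ties
#' broken by descending area and then ascending label (deterministic). When
#' fewer cells qualify than the target, all are kept and the compartment is
#' flagged under-target.
#'
#' @param cells per-cell data frame with columns `label`, `compartment`,
#'   `circularity`, `area_um2` (as built by [analyze_if_field()]).
#' @param circularity_min minimum circularity (default 0.8).
#' @param n_target cells to select per compartment (default 20).
#' @return List with `selected` (subset of `cells`, with selection order)
#'   and `under_target` (named logical per compartment).
#' @export
select_rois <- function(cells, circularity_min = 0.8, n_target = 20) {
  stopifnot(all(c("label", "compartment", "circularity", "area_um2") %in%
                  names(cells)), n_target >= 1)
  comps <- unique(cells$compartment)
  picked <- list(); under <- logical(0)
  for (cn in comps) {
    sub <- cells[cells$compartment == cn &
                   cells$circularity >= circularity_min, , drop = FALSE]
    ord <- order(-sub$circularity, -sub$area_um2, sub$label)
    sub <- sub[ord, , drop = FALSE]
    keep <- sub[seq_len(min(n_target, nrow(sub))), , drop = FALSE]
    under[cn] <- nrow(keep) < n_target
    picked[[cn]] <- keep
  }
  list(selected = do.call(rbind, picked), under_target = under)
}

#' Joint-level expression score
#'
#' Sums the per-compartment mean integrated densities into a single
#' glenohumeral joint score, optionally normalized to a control joint
#' score. Compartments with no qualifying cells contribute nothing (their
#' means are missing).
#'
#' @param compartment_means named numeric vector of per-compartment mean
#'   integrated densities (may contain `NA`).
#' @param control_joint optional control joint score (> 0) to normalize by.
#' @return List with `joint` and `normalized` (`NULL` when no control is
#'   given).
#' @export
joint_score <- function(compartment_means, control_joint = NULL) {
  if (all(is.na(compartment_means)))
    stop("no compartment mean is defined")
  joint <- sum(compartment_means, na.rm = TRUE)
  normalized <- NULL
  if (!is.null(control_joint)) {
    if (!is.numeric(control_joint) || control_joint <= 0)
      stop("`control_joint` must be a positive number")
    normalized <- joint / control_joint
  }
  list(joint = joint, normalized = normalized)
}

#' Per-cell immunofluorescence quantification of an expression field
#'
#' Thresholds the expression channel (Otsu by default, or a supplied
#' manual threshold), segments cells by distance-transform watershed,
#' measures each cell's integrated density and circularity, assigns cells
#' to anatomical compartments by centroid membership in user-supplied
#' masks, selects up to `n_target` circular cells per compartment, and
#' forms compartment means and the joint score.
#'
#' @param stack a [micrograph_stack()] with an `expression` channel (a
#'   `nuclei` channel, if present, is ignored beyond QC).
#' @param compartment_masks named list of logical masks (e.g. `humeral`,
#'   `glenoid`) defining the anatomical compartments; cells outside every
#'   mask are dropped.
#' @param circularity_min,n_target ROI selection parameters (see
#'   [select_rois()]).
#' @param min_cell_area,min_separation segmentation parameters (see
#'   [segment_cells()]).
#' @param threshold optional manual threshold for the expression channel;
#'   Otsu's method is used when `NULL`.
#' @param background constant background subtracted in the integrated
#'   density (default 0, i.e. off).
#' @param control_joint optional control joint score for normalization.
#' @return An `if_quant_result`: `cells` (all segmented cells with
#'   `integrated_density`, `area_um2`, `circularity`, `compartment`),
#'   `selected`, `under_target`, `compartment_means`, `n_selected`,
#'   `joint_score`, `normalized_score` (`NULL` without a control).
#' @export
analyze_if_field <- function(stack, compartment_masks, circularity_min = 0.8,
                             n_target = 20, min_cell_area = 20,
                             min_separation = 5, threshold = NULL,
                             background = 0, control_joint = NULL) {
  stopifnot(inherits(stack, "micrograph_stack"),
            is.list(compartment_masks), length(compartment_masks) >= 1,
            !is.null(names(compartment_masks)))
  img <- max_intensity_projection(stack, "expression")
  if (is.null(threshold)) threshold <- otsu_threshold(img)
  seg <- segment_cells(img > threshold, intensity = list(expression = img),
                       pixel_size = stack$pixel_size,
                       min_cell_area = min_cell_area,
                       min_separation = min_separation)
  cells <- seg$cells
  k <- nrow(cells)
  cells$integrated_density <- numeric(k)
  cells$circularity <- numeric(k)
  cells$compartment <- NA_character_
  for (i in seq_len(k)) {
    mask_i <- seg$labels == cells$label[i]
    cells$integrated_density[i] <- integrated_density(img, mask_i,
                                                      background = background)
    cells$circularity[i] <- circularity(mask_i)
    r <- round(cells$centroid_row[i]); c <- round(cells$centroid_col[i])
    for (cn in names(compartment_masks)) {
      if (compartment_masks[[cn]][r, c]) { cells$compartment[i] <- cn; break }
    }
  }
  cells <- cells[!is.na(cells$compartment), , drop = FALSE]
  # report every compartment, qualified or not
  sel <- select_rois(cells, circularity_min = circularity_min,
                     n_target = n_target)
  comp_names <- names(compartment_masks)
  means <- stats::setNames(rep(NA_real_, length(comp_names)), comp_names)
  n_sel <- stats::setNames(integer(length(comp_names)), comp_names)
  for (cn in comp_names) {
    sub <- sel$selected[sel$selected$compartment == cn, , drop = FALSE]
    n_sel[cn] <- nrow(sub)
    if (nrow(sub)) means[cn] <- mean(sub$integrated_density)
  }
  under <- stats::setNames(rep(TRUE, length(comp_names)), comp_names)
  under[names(sel$under_target)] <- sel$under_target
  js <- joint_score(means, control_joint = control_joint)
  structure(list(cells = cells, selected = sel$selected,
                 under_target = under, compartment_means = means,
                 n_selected = n_sel, joint_score = js$joint,
                 normalized_score = js$normalized,
                 threshold = threshold, circularity_min = circularity_min,
                 n_target = n_target),
            class = "if_quant_result")
}

#' @export
print.if_quant_result <- function(x, ...) {
  cat(sprintf("<if_quant_result> %d cell(s) in %d compartment(s)\n",
              nrow(x$cells), length(x$compartment_means)))
  for (cn in names(x$compartment_means))
    cat(sprintf("  %s: mean integrated density %s over %d selected cell(s)%s\n",
                cn,
                if (is.na(x$compartment_means[cn])) "undefined"
                else sprintf("%.0f", x$compartment_means[cn]),
                x$n_selected[cn],
                if (x$under_target[cn]) " [under target]" else ""))
  cat(sprintf("  joint score %.0f%s\n", x$joint_score,
              if (!is.null(x$normalized_score))
                sprintf(", normalized %.3f", x$normalized_score) else ""))
  invisible(x)
}

#' Write an immunofluorescence quantification to disk
#'
#' Per-cell CSV plus a per-sample JSON (compartment means, joint score,
#' normalized score).
#'
#' @param result an [analyze_if_field()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_if_result <- function(result, dir) {
  stopifnot(inherits(result, "if_quant_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(compartment_means = as.list(result$compartment_means),
         n_selected = as.list(result$n_selected),
         under_target = as.list(result$under_target),
         joint_score = result$joint_score,
         normalized_score = result$normalized_score,
         threshold = result$threshold),
    file.path(dir, "if_quant.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
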