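#' @importFrom stats runif rnorm sd uniroot
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic chondrocyte field
#'
#' Describes one simulated confocal field: disc-shaped cells (chondrocytes
#' seen en face are near-circular) scattered without overlap, optionally
#' restricted to a cap-shaped mask emulating the spherical articular surface
#' of the humeral head, rendered over a small number of Z-planes with
#' per-plane Gaussian defocus so that maximum-intensity projection is
#' exercised nontrivially.
#'
#' Acquisition metadata (pixel size, intensity levels, noise) are not
#' reported for the source assay, so the defaults are plausible but
#' uncalibrated; they are stated here and in the methods vignette.
#'
#' @param width,height field size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param n_cells number of cells to place (>= 0).
#' @param cell_radius_range c(min, max) cell radius in micrometres.
#' @param cap_mask optional logical `height x width` matrix restricting cell
#'   centres (e.g. from [make_cap_mask()]); `NULL` allows the whole field.
#' @param background_level,cell_level background and in-focus cell intensity
#'   (arbitrary units).
#' @param noise_sd SD of additive Gaussian noise (clipped at 0).
#' @param n_planes number of Z-planes.
#' @param defocus_sigma Gaussian defocus width, in planes: a cell whose focal
#'   plane is `z0` contributes `cell_level * exp(-((z - z0)^2) / (2 * defocus_sigma^2))`
#'   on plane `z`.
#' @param min_gap minimum rasterized gap between cell rims, in pixels, on top
#'   of the non-overlap requirement (keeps non-touching cells separable).
#' @param seed integer seed; placement uses `seed`, downstream state draws
#'   use `seed + 1`, rendering noise uses `seed + 2` (and `seed + 3` for a
#'   second frame).
#' @return A `field_spec` object.
#' @export
field_spec <- function(width = 384, height = 384, pixel_size = 1,
                       n_cells = 150, cell_radius_range = c(4, 7),
                       cap_mask = NULL, background_level = 20,
                       cell_level = 200, noise_sd = 10, n_planes = 5,
                       defocus_sigma = 1, min_gap = 2, seed = 1) {
  stopifnot(width >= 8, height >= 8, pixel_size > 0, n_cells >= 0,
            length(cell_radius_range) == 2, all(cell_radius_range > 0),
            cell_radius_range[1] <= cell_radius_range[2],
            background_level >= 0, cell_level > 0, noise_sd >= 0,
            n_planes >= 1, defocus_sigma > 0, min_gap >= 0)
  if (!is.null(cap_mask)) {
    if (!is.logical(cap_mask) || !identical(dim(cap_mask), c(as.integer(height), as.integer(width))))
      stop("`cap_mask` must be a logical height x width matrix")
    if (!any(cap_mask)) stop("`cap_mask` is empty")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range, cap_mask = cap_mask,
                 background_level = background_level, cell_level = cell_level,
                 noise_sd = noise_sd, n_planes = as.integer(n_planes),
                 defocus_sigma = defocus_sigma, min_gap = min_gap,
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' Disc-shaped cap mask
#'
#' Convenience mask emulating the curved articular cap in view: a centred
#' disc covering `radius_frac` of the smaller field dimension. Cells outside
#' it (capsule / tendon stump territory in the real assay) are excluded from
#' placement.
#'
#' @param width,height field size in pixels.
#' @param radius_frac cap radius as a fraction of `min(width, height)`.
#' @return Logical `height x width` matrix.
#' @export
make_cap_mask <- function(width, height, radius_frac = 0.45) {
  r <- radius_frac * min(width, height)
  ctr <- c((height + 1) / 2, (width + 1) / 2)
  row <- matrix(seq_len(height), height, width)
  col <- matrix(seq_len(width), height, width, byrow = TRUE)
  (row - ctr[1])^2 + (col - ctr[2])^2 <= r^2
}

# Rejection-sampled non-overlapping placement. Draws from the current RNG
# stream; caller is responsible for seeding. Fails loudly when the field
# cannot hold n_cells under the non-overlap constraint.
place_cells <- function(spec, max_attempts_per_cell = 2000L) {
  n <- spec$n_cells
  if (n == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      radius_px = numeric(0), focal_plane = integer(0)))
  rpx <- runif(n, spec$cell_radius_range[1], spec$cell_radius_range[2]) /
    spec$pixel_size
  rows <- cols <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts_per_cell)) {
      m <- rpx[i] + 2
      r0 <- runif(1, 1 + m, spec$height - m)
      c0 <- runif(1, 1 + m, spec$width - m)
      if (!is.null(spec$cap_mask) &&
          !spec$cap_mask[round(r0), round(c0)]) next
      if (i > 1L) {
        j <- seq_len(i - 1L)
        if (any(sqrt((rows[j] - r0)^2 + (cols[j] - c0)^2) <=
                rpx[j] + rpx[i] + spec$min_gap)) next
      }
      rows[i] <- r0; cols[i] <- c0; ok <- TRUE; break
    }
    if (!ok)
      stop(sprintf(paste0("could not place cell %d of %d without violating the ",
                          "non-overlap constraint; reduce n_cells, shrink ",
                          "cell_radius_range, or enlarge the field"), i, n))
  }
  data.frame(row = rows, col = cols, radius_px = rpx,
             focal_plane = sample.int(spec$n_planes, n, replace = TRUE))
}

# Rasterized pixel count of each cell's disc footprint.
disc_areas_px <- function(cells) {
  vapply(seq_len(nrow(cells)), function(i) {
    r <- cells$radius_px[i]
    ii <- floor(cells$row[i] - r):ceiling(cells$row[i] + r)
    jj <- floor(cells$col[i] - r):ceiling(cells$col[i] + r)
    d2 <- outer((ii - cells$row[i])^2, (jj - cells$col[i])^2, "+")
    sum(d2 <= r^2)
  }, numeric(1))
}

# Render one channel (height x width x n_planes) from per-cell levels.
# Cells are non-overlapping by construction, so plain addition is exact.
render_channel <- function(cells, levels, spec) {
  arr <- array(0, c(spec$height, spec$width, spec$n_planes))
  if (nrow(cells) == 0L) return(arr)
  for (i in seq_len(nrow(cells))) {
    if (levels[i] <= 0) next
    r <- cells$radius_px[i]
    i0 <- max(1L, floor(cells$row[i] - r)); i1 <- min(spec$height, ceiling(cells$row[i] + r))
    j0 <- max(1L, floor(cells$col[i] - r)); j1 <- min(spec$width, ceiling(cells$col[i] + r))
    if (i0 > i1 || j0 > j1) next           # cell entirely off-field
    ii <- i0:i1; jj <- j0:j1
    mask <- outer((ii - cells$row[i])^2, (jj - cells$col[i])^2, "+") <= r^2
    for (z in seq_len(spec$n_planes)) {
      w <- exp(-0.5 * ((z - cells$focal_plane[i]) / spec$defocus_sigma)^2)
      if (w < 1e-6) next
      blk <- arr[ii, jj, z]
      blk[mask] <- blk[mask] + levels[i] * w
      arr[ii, jj, z] <- blk
    }
  }
  arr
}

add_image_noise <- function(arr, background, noise_sd) {
  arr <- arr + background
  if (noise_sd > 0)
    arr <- pmax(arr + rnorm(length(arr), 0, noise_sd), 0)
  arr
}

#' Specification of a simulated impact experiment
#'
#' Models the observable consequence of an injurious impact load delivered
#' to the articular surface: a focal region in which cells die with elevated
#' probability, imaged before and after with live (calcein-AM) and dead
#' (ethidium homodimer-1) channels. The post frame is translated by
#' `post_shift` to emulate specimen repositioning between acquisitions.
#'
#' @param field a [field_spec()].
#' @param impact_center c(row, col) pixel coordinates of the impact site;
#'   default is the field centre.
#' @param impact_radius impact radius in micrometres.
#' @param death_probability_inside,death_probability_outside per-cell death
#'   probabilities inside/outside the impact radius, each in `[0, 1]`.
#' @param post_shift c(drow, dcol) integer pixel translation applied to the
#'   post frame.
#' @return An `impact_spec` object.
#' @export
impact_spec <- function(field = field_spec(), impact_center = NULL,
                        impact_radius = 60,
                        death_probability_inside = 0.85,
                        death_probability_outside = 0.05,
                        post_shift = c(3, -2)) {
  stopifnot(inherits(field, "field_spec"), impact_radius > 0,
            death_probability_inside >= 0, death_probability_inside <= 1,
            death_probability_outside >= 0, death_probability_outside <= 1,
            length(post_shift) == 2)
  if (is.null(impact_center))
    impact_center <- c((field$height + 1) / 2, (field$width + 1) / 2)
  stopifnot(length(impact_center) == 2,
            impact_center[1] >= 1, impact_center[1] <= field$height,
            impact_center[2] >= 1, impact_center[2] <= field$width)
  if (!is.null(field$cap_mask)) {
    rpx <- impact_radius / field$pixel_size
    row <- matrix(seq_len(field$height), field$height, field$width)
    col <- matrix(seq_len(field$width), field$height, field$width, byrow = TRUE)
    hit <- (row - impact_center[1])^2 + (col - impact_center[2])^2 <= rpx^2
    if (!any(hit & field$cap_mask))
      stop("impact region does not intersect the cap mask")
  }
  structure(list(field = field, impact_center = impact_center,
                 impact_radius = impact_radius,
                 death_probability_inside = death_probability_inside,
                 death_probability_outside = death_probability_outside,
                 post_shift = as.integer(round(post_shift))),
            class = "impact_spec")
}

#' Generate a paired pre/post-impact live-dead image pair with ground truth
#'
#' Places cells, draws per-cell death states (Bernoulli, probability set by
#' position relative to the impact site), and renders pre- and post-impact
#' two-channel Z-stacks. Pre-impact, every cell is live (bright in the live
#' channel only); post-impact, dead cells switch entirely to the dead
#' channel. RNG substreams: placement uses `seed`, death states use
#' `seed + 1` (a single `runif(n_cells)` compared against the per-cell
#' probability, in placement order), pre-frame noise `seed + 2`, post-frame
#' noise `seed + 3`.
#'
#' @param spec an [impact_spec()].
#' @return A list with elements `pre` and `post` ([micrograph_stack()]s with
#'   channels `live`, `dead`) and `truth`, a data frame with one row per cell
#'   (centre, radius, focal plane, rasterized area, inside-impact flag,
#'   pre/post state); `post_shift`, impact centre and radius are attached as
#'   attributes of `truth`.
#' @export
generate_impact_pair <- function(spec) {
  stopifnot(inherits(spec, "impact_spec"))
  fs <- spec$field
  cells <- with_seed(fs$seed, place_cells(fs))
  n <- nrow(cells)
  rpx <- spec$impact_radius / fs$pixel_size
  inside <- sqrt((cells$row - spec$impact_center[1])^2 +
                 (cells$col - spec$impact_center[2])^2) <= rpx
  p <- ifelse(inside, spec$death_probability_inside,
              spec$death_probability_outside)
  dead <- with_seed(fs$seed + 1L, runif(n) < p)

  truth <- data.frame(cell = seq_len(n), row = cells$row, col = cells$col,
                      radius_px = cells$radius_px,
                      radius_um = cells$radius_px * fs$pixel_size,
                      focal_plane = cells$focal_plane,
                      area_px = disc_areas_px(cells),
                      inside_impact = inside,
                      pre_state = rep("live", n),
                      post_state = ifelse(dead, "dead", "live"))
  truth$area_um2 <- truth$area_px * fs$pixel_size^2
  attr(truth, "impact_center") <- spec$impact_center
  attr(truth, "impact_radius_um") <- spec$impact_radius
  attr(truth, "post_shift") <- spec$post_shift

  pre <- rasterize_truth(truth, fs, frame = "pre")
  post <- rasterize_truth(truth, fs, frame = "post")
  pre$data[, , "live", ] <- with_seed(fs$seed + 2L,
    add_image_noise(pre$data[, , "live", , drop = FALSE],
                    fs$background_level, fs$noise_sd))
  pre$data[, , "dead", ] <- with_seed(fs$seed + 2L + 10L,
    add_image_noise(pre$data[, , "dead", , drop = FALSE],
                    fs$background_level, fs$noise_sd))
  post$data[, , "live", ] <- with_seed(fs$seed + 3L,
    add_image_noise(post$data[, , "live", , drop = FALSE],
                    fs$background_level, fs$noise_sd))
  post$data[, , "dead", ] <- with_seed(fs$seed + 3L + 10L,
    add_image_noise(post$data[, , "dead", , drop = FALSE],
                    fs$background_level, fs$noise_sd))
  list(pre = pre, post = post, truth = truth)
}

#' Re-render the noise-free image implied by a ground-truth record
#'
#' Rasterizes the truth table of [generate_impact_pair()] back into a
#' noise-free, background-free two-channel stack. With `noise_sd = 0` and
#' `background_level = 0` in the field spec, the generator's output equals
#' this rasterization exactly, which is the consistency contract between
#' images and their truth records.
#'
#' @param truth truth data frame from [generate_impact_pair()].
#' @param field the [field_spec()] used to generate it.
#' @param frame `"pre"` or `"post"`; the post frame applies the recorded
#'   `post_shift` and the post-impact states.
#' @return A [micrograph_stack()] with channels `live`, `dead`.
#' @export
rasterize_truth <- function(truth, field, frame = c("pre", "post")) {
  frame <- match.arg(frame)
  cells <- data.frame(row = truth$row, col = truth$col,
                      radius_px = truth$radius_px,
                      focal_plane = truth$focal_plane)
  state <- if (frame == "pre") truth$pre_state else truth$post_state
  if (frame == "post") {
    shift <- attr(truth, "post_shift")
    cells$row <- cells$row + shift[1]
    cells$col <- cells$col + shift[2]
  }
  live <- render_channel(cells, ifelse(state == "live", field$cell_level, 0), field)
  dead <- render_channel(cells, ifelse(state == "dead", field$cell_level, 0), field)
  data <- array(0, c(field$height, field$width, 2, field$n_planes))
  data[, , 1, ] <- live
  data[, , 2, ] <- dead
  micrograph_stack(data, c("live", "dead"), field$pixel_size)
}

#' Specification of simulated ratiometric calcium traces
#'
#' Emulates per-cell cytosolic calcium time series from ratiometric imaging
#' of a field of chondrocytes: a resting baseline with small bounded
#' fluctuations, and, in responding cells, an agonist-evoked transient that
#' starts at the treatment time. Defaults mirror a 6-minute acquisition with
#' treatment at 1 minute.
#'
#' Baseline fluctuation is drawn as bounded uniform white noise with the
#' requested SD (`noise_dist = "uniform"`); a Gaussian option exists. The
#' bounded default reflects resting Fura-2 baselines, whose fluctuations do
#' not produce spontaneous many-sigma excursions; see the methods vignette.
#'
#' @param n_cells number of cells.
#' @param duration acquisition length, seconds.
#' @param sample_interval sampling interval, seconds (> 0).
#' @param baseline_mean,baseline_sd resting calcium mean and fluctuation SD, nM.
#' @param treatment_time agonist addition time, seconds (< `duration`).
#' @param responder_fraction probability that a cell responds, in `[0, 1]`.
#' @param response_amplitude_in_sd noise-free peak amplitude of the evoked
#'   transient, as a multiple of `max(baseline_sd, sd_floor)`.
#' @param response_shape c(rise, decay) time constants of the transient,
#'   seconds.
#' @param sd_floor floor (nM) applied to `baseline_sd` when scaling the
#'   response amplitude, so a vanishing baseline SD still yields a
#'   well-defined transient.
#' @param noise_dist `"uniform"` (bounded, default) or `"gaussian"`.
#' @param seed integer seed; responder labels use `seed + 1` (a single
#'   `runif(n_cells) < responder_fraction` draw), noise uses `seed + 2`.
#' @return A `trace_sim_spec` object.
#' @export
trace_sim_spec <- function(n_cells = 100, duration = 360, sample_interval = 3,
                           baseline_mean = 100, baseline_sd = 5,
                           treatment_time = 60, responder_fraction = 0.7,
                           response_amplitude_in_sd = 8,
                           response_shape = c(rise = 4, decay = 45),
                           sd_floor = 0.5,
                           noise_dist = c("uniform", "gaussian"), seed = 1) {
  noise_dist <- match.arg(noise_dist)
  if (sample_interval <= 0) stop("`sample_interval` must be > 0")
  stopifnot(n_cells >= 0, duration > 0, treatment_time > 0,
            treatment_time < duration, baseline_mean >= 0, baseline_sd >= 0,
            responder_fraction >= 0, responder_fraction <= 1,
            response_amplitude_in_sd >= 0, length(response_shape) == 2,
            all(response_shape > 0), sd_floor > 0)
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 sample_interval = sample_interval,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 treatment_time = treatment_time,
                 responder_fraction = responder_fraction,
                 response_amplitude_in_sd = response_amplitude_in_sd,
                 response_shape = response_shape, sd_floor = sd_floor,
                 noise_dist = noise_dist, seed = as.integer(seed)),
            class = "trace_sim_spec")
}

#' Generate simulated calcium traces with responder ground truth
#'
#' Non-responders fluctuate around `baseline_mean`; responders additionally
#' receive a rise-and-decay transient starting at `treatment_time` whose
#' noise-free peak, on the sampled grid, equals
#' `response_amplitude_in_sd * max(baseline_sd, sd_floor)` above baseline.
#'
#' @param spec a [trace_sim_spec()].
#' @return A list with `traces` (a [trace_set()]) and `truth`, a data frame
#'   with per-cell responder labels and noise-free amplitudes (nM).
#' @export
generate_traces <- function(spec) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  time <- seq(0, spec$duration, by = spec$sample_interval)
  n <- spec$n_cells
  responder <- with_seed(spec$seed + 1L, runif(n) < spec$responder_fraction)
  amp <- spec$response_amplitude_in_sd * max(spec$baseline_sd, spec$sd_floor)
  s <- pmax(time - spec$treatment_time, 0)
  shape <- (1 - exp(-s / spec$response_shape[[1]])) * exp(-s / spec$response_shape[[2]])
  shape[time < spec$treatment_time] <- 0
  if (max(shape) > 0) shape <- shape / max(shape)
  noise <- with_seed(spec$seed + 2L, {
    if (spec$noise_dist == "uniform") {
      a <- spec$baseline_sd * sqrt(3)
      matrix(runif(length(time) * n, -a, a), length(time), n)
    } else {
      matrix(rnorm(length(time) * n, 0, spec$baseline_sd), length(time), n)
    }
  })
  traces <- spec$baseline_mean + noise +
    outer(shape, ifelse(responder, amp, 0))
  colnames(traces) <- sprintf("cell_%03d", seq_len(n))
  list(traces = trace_set(time, traces, spec$treatment_time),
       truth = data.frame(cell = colnames(traces), responsive = responder,
                          amplitude_nM = ifelse(responder, amp, 0)))
}

# Circularity of an ellipse with aspect ratio q >= 1 (area held fixed),
# using Ramanujan's perimeter approximation.
ellipse_circularity <- function(q) {
  a <- sqrt(q); b <- 1 / sqrt(q)
  p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * pi * pi / p^2
}

ellipse_aspect_from_circularity <- function(circ) {
  if (circ >= ellipse_circularity(1)) return(1)
  uniroot(function(q) ellipse_circularity(q) - circ,
          c(1, 200), tol = 1e-8)$root
}

#' Specification of a synthetic immunofluorescence field
#'
#' Two anatomical compartments (humeral, left half; glenoid, right half)
#' of elliptical cells with per-cell expression intensity drawn from
#' compartment-specific normal distributions (truncated at zero), rendered
#' as a single-plane expression channel plus a nuclei channel. Each cell's
#' noise-free integrated density (intensity times rasterized area) is
#' recorded as ground truth.
#'
#' @param n_cells named vector `c(humeral =, glenoid =)` of cell counts.
#' @param intensity_mean,intensity_sd named vectors of per-compartment
#'   intensity distributions (arbitrary units).
#' @param width,height field size in pixels; compartments split at
#'   `width / 2`.
#' @param pixel_size micrometres per pixel.
#' @param cell_radius_range c(min, max) area-equivalent cell radius, um.
#' @param circularity_range c(min, max) target cell circularity in `[0, 1]`;
#'   sampled per cell and converted to an ellipse aspect ratio.
#' @param background_level,noise_sd background intensity and Gaussian noise SD.
#' @param nuclei_level intensity of the rendered nuclei.
#' @param min_gap minimum gap between cells, pixels.
#' @param seed integer seed; placement/shape uses `seed`, intensities
#'   `seed + 1`, noise `seed + 2`.
#' @return An `if_field_spec` object.
#' @export
if_field_spec <- function(n_cells = c(humeral = 25, glenoid = 25),
                          intensity_mean = c(humeral = 100, glenoid = 100),
                          intensity_sd = c(humeral = 15, glenoid = 15),
                          width = 480, height = 240, pixel_size = 1,
                          cell_radius_range = c(4, 7),
                          circularity_range = c(0.75, 1),
                          background_level = 10, noise_sd = 5,
                          nuclei_level = 150, min_gap = 2, seed = 1) {
  comp <- c("humeral", "glenoid")
  stopifnot(all(comp %in% names(n_cells)), all(n_cells[comp] >= 0),
            all(comp %in% names(intensity_mean)),
            all(comp %in% names(intensity_sd)), all(intensity_sd[comp] >= 0),
            width >= 16, height >= 8, pixel_size > 0,
            length(cell_radius_range) == 2, all(cell_radius_range > 0),
            length(circularity_range) == 2, circularity_range[1] > 0,
            circularity_range[2] <= 1,
            circularity_range[1] <= circularity_range[2],
            background_level >= 0, noise_sd >= 0, min_gap >= 0)
  structure(list(n_cells = n_cells[comp], intensity_mean = intensity_mean[comp],
                 intensity_sd = intensity_sd[comp],
                 width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, cell_radius_range = cell_radius_range,
                 circularity_range = circularity_range,
                 background_level = background_level, noise_sd = noise_sd,
                 nuclei_level = nuclei_level, min_gap = min_gap,
                 seed = as.integer(seed)),
            class = "if_field_spec")
}

#' Compartment masks of a synthetic immunofluorescence field
#'
#' @param spec an [if_field_spec()].
#' @return Named list of logical `height x width` matrices (`humeral`,
#'   `glenoid`).
#' @export
if_compartment_masks <- function(spec) {
  stopifnot(inherits(spec, "if_field_spec"))
  half <- floor(spec$width / 2)
  col <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  list(humeral = col <= half, glenoid = col > half)
}

# Rasterize an ellipse: centre (r0, c0), semi-axes (a, b), orientation theta.
ellipse_mask_indices <- function(r0, c0, a, b, theta, height, width) {
  ii <- max(1L, floor(r0 - a)):min(height, ceiling(r0 + a))
  jj <- max(1L, floor(c0 - a)):min(width, ceiling(c0 + a))
  u <- matrix(ii - r0, length(ii), length(jj))
  v <- matrix(jj - c0, length(ii), length(jj), byrow = TRUE)
  x <- u * cos(theta) + v * sin(theta)
  y <- -u * sin(theta) + v * cos(theta)
  list(ii = ii, jj = jj, mask = (x / a)^2 + (y / b)^2 <= 1)
}

#' Generate a synthetic immunofluorescence field with ground truth
#'
#' @param spec an [if_field_spec()].
#' @return A list with `image` (a single-plane [micrograph_stack()] with
#'   channels `expression`, `nuclei`), `truth` (per-cell data frame:
#'   compartment, centre, shape, rasterized area, drawn intensity, and exact
#'   noise-free `integrated_density = intensity * area_px`), and
#'   `compartment_masks` (as [if_compartment_masks()]).
#' @export
generate_if_field <- function(spec) {
  stopifnot(inherits(spec, "if_field_spec"))
  comp_names <- names(spec$n_cells)
  half <- floor(spec$width / 2)
  col_range <- list(humeral = c(1, half), glenoid = c(half + 1, spec$width))

  cells <- with_seed(spec$seed, {
    out <- list()
    for (cn in comp_names) {
      n <- spec$n_cells[[cn]]
      if (n == 0) next
      r <- runif(n, spec$cell_radius_range[1], spec$cell_radius_range[2]) /
        spec$pixel_size
      circ <- runif(n, spec$circularity_range[1], spec$circularity_range[2])
      q <- vapply(circ, ellipse_aspect_from_circularity, numeric(1))
      a <- r * sqrt(q); b <- r / sqrt(q)
      theta <- runif(n, 0, pi)
      rows <- cols <- numeric(n)
      placed <- data.frame()
      all_prev <- do.call(rbind, out)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (att in 1:2000) {
          m <- a[i] + 2
          lo <- max(col_range[[cn]][1] + m, 1 + m)
          hi <- min(col_range[[cn]][2] - m, spec$width - m)
          if (lo >= hi) break
          r0 <- runif(1, 1 + m, spec$height - m)
          c0 <- runif(1, lo, hi)
          prev_parts <- list()
          if (!is.null(all_prev) && nrow(all_prev))
            prev_parts$done <- all_prev[, c("row", "col", "a")]
          if (i > 1)
            prev_parts$here <- data.frame(row = rows[1:(i - 1)],
                                          col = cols[1:(i - 1)],
                                          a = a[1:(i - 1)])
          prev <- do.call(rbind, prev_parts)
          if (!is.null(prev) && nrow(prev) &&
              any(sqrt((prev$row - r0)^2 + (prev$col - c0)^2) <=
                  prev$a + a[i] + spec$min_gap)) next
          rows[i] <- r0; cols[i] <- c0; ok <- TRUE; break
        }
        if (!ok)
          stop(sprintf(paste0("could not place cell %d in compartment '%s' ",
                              "without violating the non-overlap constraint"),
                       i, cn))
      }
      out[[cn]] <- data.frame(compartment = cn, row = rows, col = cols,
                              radius_px = r, a = a, b = b, theta = theta,
                              target_circularity = circ)
    }
    do.call(rbind, out)
  })
  if (is.null(cells))
    cells <- data.frame(compartment = character(0), row = numeric(0),
                        col = numeric(0), radius_px = numeric(0),
                        a = numeric(0), b = numeric(0), theta = numeric(0),
                        target_circularity = numeric(0))
  n_tot <- nrow(cells)

  intensity <- with_seed(spec$seed + 1L, {
    v <- numeric(n_tot)
    for (cn in comp_names) {
      idx <- which(cells$compartment == cn)
      if (!length(idx)) next
      draw <- rnorm(length(idx), spec$intensity_mean[[cn]],
                    spec$intensity_sd[[cn]])
      while (any(draw <= 0))                 # truncate at zero
        draw[draw <= 0] <- rnorm(sum(draw <= 0), spec$intensity_mean[[cn]],
                                 spec$intensity_sd[[cn]])
      v[idx] <- draw
    }
    v
  })

  expr <- matrix(0, spec$height, spec$width)
  nuc <- matrix(0, spec$height, spec$width)
  area_px <- integer(n_tot)
  for (i in seq_len(n_tot)) {
    em <- ellipse_mask_indices(cells$row[i], cells$col[i], cells$a[i],
                               cells$b[i], cells$theta[i],
                               spec$height, spec$width)
    blk <- expr[em$ii, em$jj]
    blk[em$mask] <- blk[em$mask] + intensity[i]
    expr[em$ii, em$jj] <- blk
    area_px[i] <- sum(em$mask)
    nm <- ellipse_mask_indices(cells$row[i], cells$col[i], 2.5, 2.5, 0,
                               spec$height, spec$width)
    nblk <- nuc[nm$ii, nm$jj]
    nblk[nm$mask] <- pmax(nblk[nm$mask], spec$nuclei_level)
    nuc[nm$ii, nm$jj] <- nblk
  }

  noisy <- with_seed(spec$seed + 2L, {
    list(expr = add_image_noise(expr, spec$background_level, spec$noise_sd),
         nuc = add_image_noise(nuc, spec$background_level, spec$noise_sd))
  })
  data <- array(0, c(spec$height, spec$width, 2, 1))
  data[, , 1, 1] <- noisy$expr
  data[, , 2, 1] <- noisy$nuc
  truth <- data.frame(cell = seq_len(n_tot), compartment = cells$compartment,
                      row = cells$row, col = cells$col,
                      semi_major_px = cells$a, semi_minor_px = cells$b,
                      theta = cells$theta,
                      target_circularity = cells$target_circularity,
                      area_px = area_px,
                      area_um2 = area_px * spec$pixel_size^2,
                      intensity = intensity,
                      integrated_density = intensity * area_px)
  list(image = micrograph_stack(data, c("expression", "nuclei"),
                                spec$pixel_size),
       truth = truth, compartment_masks = if_compartment_masks(spec))
}

#' Write a trace set as CSV
#'
#' Column 1 is `time_s`; remaining columns are one per cell.
#'
#' @param traces a [trace_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  df <- data.frame(time_s = traces$time, traces$traces, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace-set CSV written by [write_traces_csv()]
#'
#' @param path CSV path (`time_s` column plus one column per cell).
#' @param treatment_time agonist addition time, seconds.
#' @param meta optional metadata list.
#' @return A [trace_set()].
#' @export
read_traces_csv <- function(path, treatment_time, meta = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("CSV must contain a `time_s` column")
  m <- as.matrix(df[setdiff(names(df), "time_s")])
  trace_set(df$time_s, m, treatment_time, meta)
}
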