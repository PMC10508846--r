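#' Multi-channel micrograph Z-stack
#'
#' Container for confocal Z-stacks with channel semantics and a physical
#' pixel size. Data are stored as a 4-d numeric array indexed
#' `[row, col, channel, plane]`; intensities are in arbitrary units.
#' Single-plane or single-channel inputs are promoted to 4-d.
#'
#' @param data numeric array: `height x width` matrix,
#'   `height x width x channels`, or `height x width x channels x planes`.
#' @param channel_names character vector naming the channels, e.g.
#'   `c("live", "dead")` for a calcein-AM / ethidium-homodimer viability
#'   stack or `c("expression", "nuclei")` for immunofluorescence.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#'
#' @return An object of class `micrograph_stack`.
#' @export
micrograph_stack <- function(data, channel_names, pixel_size) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("`data` must have 2, 3 or 4 dimensions (row, col, channel, plane)")
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (length(channel_names) != dim(data)[3L])
    stop(sprintf("%d channel name(s) for %d channel(s)",
                 length(channel_names), dim(data)[3L]))
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)")
  dimnames(data) <- list(NULL, NULL, channel_names, NULL)
  structure(list(data = data,
                 channel_names = as.character(channel_names),
                 pixel_size = as.numeric(pixel_size)),
            class = "micrograph_stack")
}

#' @export
print.micrograph_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<micrograph_stack> %d x %d px, %d channel(s) [%s], %d plane(s), %.3g um/px\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              d[4], x$pixel_size))
  invisible(x)
}

#' @export
dim.micrograph_stack <- function(x) dim(x$data)

#' Extract one channel of a stack
#'
#' @param stack a [micrograph_stack()].
#' @param channel channel name.
#' @return A `height x width x planes` array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "micrograph_stack"))
  if (!channel %in% stack$channel_names)
    stop(sprintf("unknown channel '%s'; available: %s", channel,
                 paste(stack$channel_names, collapse = ", ")))
  stack$data[, , channel, , drop = FALSE][, , 1L, , drop = TRUE] ->
    out
  if (is.matrix(out)) dim(out) <- c(dim(out), 1L)
  out
}

#' Maximum intensity projection of a channel
#'
#' Collapses a Z-stack to 2-d by taking, at every pixel, the maximum
#' intensity across planes.
#'
#' @inheritParams get_channel
#' @return A `height x width` numeric matrix.
#' @export
max_intensity_projection <- function(stack, channel) {
  arr <- get_channel(stack, channel)
  out <- arr[, , 1L]
  nz <- dim(arr)[3L]
  if (nz > 1L) for (z in 2L:nz) out <- pmax(out, arr[, , z])
  out
}

# -- TIFF + sidecar I/O -------------------------------------------------------
# Pages are written plane-major with channel fastest:
# page = (plane - 1) * n_channels + channel. Intensities are stored as
# 16-bit fractions of `intensity_scale` (the stack maximum), recorded in the
# sidecar so reading restores the original scale to ~1/65535 relative
# precision.

#' Write a micrograph stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack a [micrograph_stack()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(stack, path) {
  stopifnot(inherits(stack, "micrograph_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[3] * d[4])
  for (z in seq_len(d[4])) for (ch in seq_len(d[3]))
    pages[[(z - 1L) * d[3] + ch]] <-
      pmin(pmax(stack$data[, , ch, z] / scale, 0), 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(channel_names = stack$channel_names,
                  pixel_size_um = stack$pixel_size,
                  n_channels = d[3], n_planes = d[4],
                  intensity_scale = scale,
                  page_order = "plane-major, channel fastest")
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a micrograph stack written by [write_micrograph()]
#'
#' @param path TIFF path with accompanying `<path>.json` sidecar.
#' @return A [micrograph_stack()].
#' @export
read_micrograph <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- side$n_channels; nz <- side$n_planes
  if (length(pages) != nc * nz)
    stop(sprintf("expected %d pages, found %d", nc * nz, length(pages)))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0, c(h, w, nc, nz))
  for (z in seq_len(nz)) for (ch in seq_len(nc))
    data[, , ch, z] <- pages[[(z - 1L) * nc + ch]] * side$intensity_scale
  micrograph_stack(data, side$channel_names, side$pixel_size_um)
}
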