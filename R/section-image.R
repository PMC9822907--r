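#' Multi-channel section image
#'
#' A `section_image` bundles named 2D intensity channels of equal shape with
#' the physical pixel size. Channels are numeric matrices indexed
#' `[row, col]` with row 1 at the top of the section (the epidermal surface)
#' and depth increasing downwards; the pixel at `[r, c]` has its centre at
#' `x = (c - 0.5) * pixel_size_um`, `y = (r - 0.5) * pixel_size_um`.
#' Orientation angles are measured from the x axis (0 degrees = parallel to
#' the epidermis) in `[0, 180)`.
#'
#' @param channels named list of numeric matrices, all the same dimension.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param roi optional ROI rectangle `c(x0, y0, x1, y1)` in micrometres.
#'
#' @return An object of class `section_image`.
#' @export
section_image <- function(channels, pixel_size_um, roi = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    stop("all channels must share the same dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop("channel '", nm, "' is not a numeric matrix")
    if (any(!is.finite(ch)) || any(ch < 0))
      stop("channel '", nm, "' has non-finite or negative intensities")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um, roi = roi),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "section_image: %d x %d px (%.1f x %.1f um), %.3g um/px\nchannels: %s\n",
    d[2], d[1], d[2] * x$pixel_size_um, d[1] * x$pixel_size_um,
    x$pixel_size_um, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$channels[[1]])

#' Write a section image as a multi-page TIFF
#'
#' One 16-bit greyscale page per channel, in channel order. Pixel size and
#' channel names are recorded in a JSON sidecar (`<path>.json`) because the
#' baseline TIFF writer exposes no resolution tags; [read_section_tiff()]
#' reads the sidecar back, or accepts an explicit pixel size.
#'
#' @param img a [section_image()].
#' @param path output TIFF path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(img, path, bits = 16L) {
  stopifnot(inherits(img, "section_image"))
  hi <- max(1, vapply(img$channels, max, numeric(1)))
  pages <- lapply(img$channels, function(ch) ch / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  meta <- list(
    pixel_size_um = img$pixel_size_um,
    channels = as.list(names(img$channels)),
    intensity_scale = hi
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a section image from a multi-page TIFF
#'
#' @param path TIFF path; the JSON sidecar written by [write_section_tiff()]
#'   is consulted when present.
#' @param pixel_size_um pixel size override in micrometres; required when no
#'   sidecar exists.
#' @param channel_names channel name override, one per TIFF page.
#' @return A [section_image()].
#' @export
read_section_tiff <- function(path, pixel_size_um = NULL,
                              channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (is.null(channel_names)) channel_names <- meta$channels
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(pixel_size_um))
    stop("no sidecar metadata found; supply `pixel_size_um`")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(pages))
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale
  })
  names(pages) <- channel_names
  section_image(pages, pixel_size_um)
}

# pixel-centre coordinate helpers (um)
px_x <- function(col, pixel_size_um) (col - 0.5) * pixel_size_um
px_y <- function(row, pixel_size_um) (row - 0.5) * pixel_size_um
um_to_col <- function(x, pixel_size_um) x / pixel_size_um + 0.5
um_to_row <- function(y, pixel_size_um) y / pixel_size_um + 0.5
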