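#' Dermal cell density
#'
#' Number of nucleus centres inside an ROI divided by the ROI area in
#' square millimetres (the standard ROI is 300 x 300 um).
#'
#' @param nuclei data.frame of centres `x`, `y` in um.
#' @param roi rectangle `c(x0, y0, x1, y1)` in um.
#' @return Cells per mm^2.
#' @export
cell_density <- function(nuclei, roi) {
  stopifnot(length(roi) == 4, roi[3] > roi[1], roi[4] > roi[2])
  inside <- nuclei$x >= roi[1] & nuclei$x < roi[3] &
    nuclei$y >= roi[2] & nuclei$y < roi[4]
  area_mm2 <- (roi[3] - roi[1]) * (roi[4] - roi[2]) / 1e6
  sum(inside) / area_mm2
}

#' Percentage vessel density
#'
#' 100 times the fraction of ROI pixels covered by the vessel mask.
#'
#' @param vmask a [vessel_mask()] result or a logical matrix.
#' @param roi rectangle `c(x0, y0, x1, y1)` in um, or `NULL` to use the
#'   mask's own region.
#' @param pixel_size_um required when `roi` is given.
#' @return Percentage in `[0, 100]`.
#' @export
vessel_density <- function(vmask, roi = NULL, pixel_size_um = NULL) {
  if (inherits(vmask, "vessel_mask")) {
    m <- vmask$mask
    if (is.null(roi)) {
      reg <- region_to_mask(vmask$region, dim(m),
                            vmask_psz(vmask, pixel_size_um))
      return(100 * sum(m & reg) / sum(reg))
    }
  } else m <- vmask
  stopifnot(!is.null(roi), !is.null(pixel_size_um))
  reg <- region_to_mask(roi, dim(m), pixel_size_um)
  100 * sum(m & reg) / sum(reg)
}

vmask_psz <- function(vmask, pixel_size_um) {
  if (!is.null(pixel_size_um)) return(pixel_size_um)
  if (is.matrix(vmask$region)) return(1)
  stop("supply `pixel_size_um`")
}

#' Collagen fractions from a fibre class mask
#'
#' Total collagen fraction (fibre area over ROI area), thick-fibre
#' proportion (thick area over total fibre area), and the area-weighted
#' mean fibre width.
#'
#' @param fcm a `fibre_class_mask` from [segment_fibres()].
#' @param roi optional rectangle `c(x0, y0, x1, y1)` in um; defaults to the
#'   whole mask.
#' @return A list: `collagen_fraction`, `thick_proportion` (NA when there
#'   is no fibre area), `mean_thickness_um` (NA likewise).
#' @export
collagen_fractions <- function(fcm, roi = NULL) {
  stopifnot(inherits(fcm, "fibre_class_mask"))
  lab <- fcm$labels
  if (!is.null(roi)) {
    reg <- region_to_mask(roi, dim(lab), fcm$pixel_size_um)
    sel <- lab[reg]
    thick_um <- fcm$thickness_um[reg]
  } else {
    sel <- as.vector(lab)
    thick_um <- as.vector(fcm$thickness_um)
  }
  n <- length(sel)
  n_thin <- sum(sel == 1L); n_thick <- sum(sel == 2L)
  n_fib <- n_thin + n_thick
  list(
    collagen_fraction = n_fib / n,
    thick_proportion = if (n_fib > 0) n_thick / n_fib else NA_real_,
    mean_thickness_um = if (n_fib > 0) mean(thick_um[sel > 0L])
      else NA_real_
  )
}

#' Fibre orientation field from the structure tensor
#'
#' Per-pixel dominant orientation and coherence from the Gaussian-smoothed
#' structure tensor of the SHG channel. Orientation is the direction along
#' the structure (perpendicular to the dominant gradient), in degrees in
#' `[0, 180)` with 0 parallel to the x axis (the epidermis); coherence is
#' the normalized eigenvalue anisotropy in `[0, 1]`. Both are reported
#' only on fibre pixels.
#'
#' @param shg SHG intensity matrix.
#' @param mask logical fibre mask (e.g. `fcm$mask`).
#' @param pixel_size_um micrometres per pixel.
#' @param smoothing_scale_um Gaussian integration scale of the tensor.
#' @param gradient_sigma_um Gaussian pre-smoothing scale applied before
#'   differentiation; suppresses the rasterization stair-step bias of
#'   gradients on hard-edged fibres.
#' @return A list (`orientation_field`): `angle_deg` and `coherence`
#'   matrices (NA off-fibre), `mask`, `pixel_size_um`,
#'   `smoothing_scale_um`.
#' @export
orientation_field <- function(shg, mask, pixel_size_um,
                              smoothing_scale_um = 6,
                              gradient_sigma_um = 1.5) {
  stopifnot(is.matrix(shg), identical(dim(shg), dim(mask)))
  if (!any(mask)) stop("no fibre pixels in the mask")
  # central-difference gradients on the pre-smoothed image; y increases
  # downwards, so negate gy to measure angles counter-clockwise from the
  # x axis as displayed
  nr <- nrow(shg); nc <- ncol(shg)
  pre <- if (gradient_sigma_um > 0)
    as.matrix(EBImage::gblur(shg, sigma = gradient_sigma_um /
                               pixel_size_um)) else shg
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (pre[, 3:nc] - pre[, 1:(nc - 2)]) / 2
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (pre[3:nr, ] - pre[1:(nr - 2), ]) / 2
  gy <- -gy
  sig <- smoothing_scale_um / pixel_size_um
  sm <- function(m) as.matrix(EBImage::gblur(m, sigma = sig))
  jxx <- sm(gx * gx); jyy <- sm(gy * gy); jxy <- sm(gx * gy)
  # gradient-dominant direction is 0.5 atan2(2Jxy, Jxx - Jyy); the fibre
  # runs perpendicular to it
  ang <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90
  ang <- ang %% 180
  tr <- jxx + jyy
  disc <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coh <- ifelse(tr > 0, disc / tr, 0)
  ang[!mask] <- NA_real_
  coh[!mask] <- NA_real_
  structure(list(angle_deg = ang, coherence = coh, mask = mask,
                 pixel_size_um = pixel_size_um,
                 smoothing_scale_um = smoothing_scale_um),
            class = "orientation_field")
}

#' Alignment coefficient of fibre orientations
#'
#' Mean resultant length of the doubled orientation angles,
#' `R = |sum(w exp(2 i theta))| / sum(w)`. Doubling removes the 180-degree
#' ambiguity of undirected fibres; R is 1 when every fibre has the same
#' orientation and approaches 0 for isotropically distributed fibres.
#'
#' @param x an `orientation_field` (each fibre pixel votes once; set
#'   `weight_by_coherence = TRUE` to weight votes by coherence) or a
#'   numeric vector of angles in degrees.
#' @param weights optional weights for a numeric-angle input.
#' @param weight_by_coherence weight pixels by structure-tensor coherence.
#' @return Coefficient in `[0, 1]`.
#' @export
alignment_coefficient <- function(x, weights = NULL,
                                  weight_by_coherence = FALSE) {
  if (inherits(x, "orientation_field")) {
    ang <- x$angle_deg[x$mask]
    w <- if (weight_by_coherence) x$coherence[x$mask] else NULL
  } else {
    ang <- as.numeric(x)
    w <- weights
  }
  ang <- ang[!is.na(ang)]
  if (length(ang) == 0) stop("no angles to summarize")
  if (is.null(w)) w <- rep(1, length(ang))
  stopifnot(length(w) == length(ang), all(w >= 0), sum(w) > 0)
  th <- 2 * ang * pi / 180
  sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / sum(w)
}

#' Orientation histogram
#'
#' Counts of fibre-pixel orientations in 1-degree bins over `[0, 180)`,
#' for export alongside orientation maps.
#'
#' @param field an `orientation_field`.
#' @param bin_deg bin width in degrees.
#' @return data.frame with `angle_deg` (bin lower edge) and `count`.
#' @export
orientation_histogram <- function(field, bin_deg = 1) {
  ang <- field$angle_deg[field$mask]
  ang <- ang[!is.na(ang)]
  edges <- seq(0, 180, by = bin_deg)
  cnt <- tabulate(findInterval(ang, edges), nbins = length(edges) - 1)
  data.frame(angle_deg = edges[-length(edges)], count = cnt)
}

#' Normalized SHG intensity
#'
#' Mean SHG intensity over fibre pixels divided by the mean over
#' background pixels, so fibre density does not bias the intensity
#' readout.
#'
#' @param shg SHG intensity matrix.
#' @param fibre_mask logical matrix of fibre pixels.
#' @param background logical matrix of background pixels; defaults to the
#'   complement of the fibre mask.
#' @return Ratio (>= 0).
#' @export
normalized_shg_intensity <- function(shg, fibre_mask,
                                     background = NULL) {
  stopifnot(is.matrix(shg), identical(dim(shg), dim(fibre_mask)))
  if (is.null(background)) background <- !fibre_mask
  if (!any(fibre_mask) || !any(background))
    stop("fibre and background regions must both be non-empty")
  bg <- mean(shg[background])
  if (bg == 0) stop("background mean intensity is zero")
  mean(shg[fibre_mask]) / bg
}
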