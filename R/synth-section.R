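#' Specification of a synthetic skin-section image
#'
#' Parameters of the layered section emulated by
#' [generate_section_image()]: a flat upper epidermal surface, an
#' undulating (sinusoidal) epidermal-dermal junction (EDJ), a basement
#' membrane rendered as a Gaussian cross-profile of collagen IV along the
#' EDJ, nuclei as non-overlapping disks with a controllable Ki67-positive
#' fraction in the epidermis, vessel cross-sections as COLIV rings in the
#' dermis, and a dermal collagen-I fibre field with a controllable width
#' mixture and orientation concentration, imaged in the SHG channel.
#'
#' @param width_um,height_um section extent (micrometres).
#' @param pixel_size_um pixel size (micrometres / pixel).
#' @param epidermal_thickness_um mean viable-epidermis thickness (the
#'   vertical distance from the surface to the EDJ averages to this).
#' @param edj_amplitude_um,edj_period_um sinusoidal EDJ undulation:
#'   `y_edj(x) = top + thickness + A sin(2 pi x / L)`.
#' @param bm_sigma_um,bm_peak basement-membrane Gaussian cross-profile
#'   standard deviation (micrometres) and peak intensity.
#' @param nuclei_density_per_mm2 nucleus density applied to the epidermis
#'   and dermis.
#' @param ki67_fraction fraction of epidermal nuclei rendered
#'   Ki67-positive.
#' @param vessel_area_fraction target fraction of the dermal rectangle
#'   covered by vessel-wall (COLIV ring) pixels.
#' @param fibre_widths_um,fibre_width_weights,orientation_kappa,fibre_area_fraction
#'   passed to [generate_fibre_field()] for the dermal SHG field.
#' @param mean_fibre_angle_deg mean fibre orientation (0 = parallel to the
#'   epidermis).
#' @param shg_fibre_intensity,shg_background_intensity SHG intensities on
#'   fibre and non-fibre dermal pixels.
#' @param noise_sd additive Gaussian noise standard deviation applied to
#'   every channel (0 = noiseless, the default, so analytic examples stay
#'   exact).
#' @param nucleus_radius_um rendered nucleus radius.
#' @param seed integer RNG seed; fixed seed gives identical output.
#'
#' @return A validated `section_spec` list.
#' @export
section_spec <- function(width_um = 600, height_um = 450,
                         pixel_size_um = 0.5,
                         epidermal_thickness_um = 60,
                         edj_amplitude_um = 15, edj_period_um = 100,
                         bm_sigma_um = 2, bm_peak = 100,
                         nuclei_density_per_mm2 = 800,
                         ki67_fraction = 0.15,
                         vessel_area_fraction = 0.06,
                         fibre_widths_um = c(6, 14),
                         fibre_width_weights = c(0.5, 0.5),
                         orientation_kappa = 2,
                         mean_fibre_angle_deg = 0,
                         fibre_area_fraction = 0.25,
                         shg_fibre_intensity = 150,
                         shg_background_intensity = 50,
                         noise_sd = 0,
                         nucleus_radius_um = 3,
                         seed = 1L) {
  spec <- as.list(environment())
  validate_section_spec(spec)
  class(spec) <- "section_spec"
  spec
}

validate_section_spec <- function(spec) {
  pos <- c("width_um", "height_um", "pixel_size_um",
           "epidermal_thickness_um", "edj_period_um", "bm_sigma_um",
           "nucleus_radius_um")
  for (f in pos)
    if (!is.numeric(spec[[f]]) || spec[[f]] <= 0)
      stop("invalid section_spec: `", f, "` must be positive")
  nonneg <- c("edj_amplitude_um", "bm_peak", "nuclei_density_per_mm2",
              "orientation_kappa", "shg_fibre_intensity",
              "shg_background_intensity", "noise_sd")
  for (f in nonneg)
    if (!is.numeric(spec[[f]]) || all(spec[[f]] < 0))
      stop("invalid section_spec: `", f, "` must be non-negative")
  frac <- c("ki67_fraction", "vessel_area_fraction", "fibre_area_fraction")
  for (f in frac)
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop("invalid section_spec: `", f, "` must be in [0, 1]")
  if (any(spec$fibre_widths_um <= 0))
    stop("invalid section_spec: `fibre_widths_um` must be positive")
  if (abs(sum(spec$fibre_width_weights) - 1) > 1e-8)
    stop("invalid section_spec: `fibre_width_weights` must sum to 1")
  if (spec$fibre_area_fraction > 0 &&
      spec$pixel_size_um > min(spec$fibre_widths_um) / 3)
    stop("invalid section_spec: `pixel_size_um` must be <= ",
         "min(fibre_widths_um)/3 so fibre widths are resolvable")
  invisible(spec)
}

# vertical EDJ position (um) at lateral position x (um)
edj_y <- function(spec, x, top_margin = 20) {
  top_margin + spec$epidermal_thickness_um +
    spec$edj_amplitude_um * sin(2 * pi * x / spec$edj_period_um)
}

# arc-chord ratio of one sinusoid period by dense polyline summation
sinusoid_arc_chord <- function(amplitude, period, n = 1e5) {
  x <- seq(0, period, length.out = n + 1)
  y <- amplitude * sin(2 * pi * x / period)
  sum(sqrt(diff(x)^2 + diff(y)^2)) / period
}

# dart-throwing Poisson-disk placement inside an x/y-band region
place_nuclei <- function(n_target, width_um, y_lo_fun, y_hi_fun, min_sep,
                         margin_x, max_attempts = NULL) {
  if (n_target <= 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (is.null(max_attempts)) max_attempts <- 200L * n_target
  xs <- numeric(n_target); ys <- numeric(n_target)
  n <- 0L; att <- 0L
  while (n < n_target && att < max_attempts) {
    att <- att + 1L
    x <- runif(1, margin_x, width_um - margin_x)
    lo <- y_lo_fun(x); hi <- y_hi_fun(x)
    if (hi <= lo) next
    y <- runif(1, lo, hi)
    if (n > 0L && any((xs[1:n] - x)^2 + (ys[1:n] - y)^2 < min_sep^2)) next
    n <- n + 1L; xs[n] <- x; ys[n] <- y
  }
  if (n < n_target)
    warning(sprintf("placed %d of %d nuclei before the rejection budget",
                    n, n_target))
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# paint filled disks (centres in um) onto a matrix, returning the matrix
paint_disks <- function(mat, centres, radius_um, value, pixel_size_um) {
  if (nrow(centres) == 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  rpx <- radius_um / pixel_size_um
  for (i in seq_len(nrow(centres))) {
    cc <- um_to_col(centres[i, 1], pixel_size_um)
    rc <- um_to_row(centres[i, 2], pixel_size_um)
    c0 <- max(1L, floor(cc - rpx)); c1 <- min(nc, ceiling(cc + rpx))
    r0 <- max(1L, floor(rc - rpx)); r1 <- min(nr, ceiling(rc + rpx))
    if (c0 > c1 || r0 > r1) next
    dx2 <- (c0:c1 - cc)^2
    dy2 <- (r0:r1 - rc)^2
    hit <- outer(dy2, dx2, "+") <= rpx^2
    sub <- mat[r0:r1, c0:c1, drop = FALSE]
    sub[hit] <- value
    mat[r0:r1, c0:c1] <- sub
  }
  mat
}

#' Generate a synthetic section image with known ground truth
#'
#' Renders the four channels (`DAPI`, `COLIV`, `Ki67`, `SHG`) described by a
#' [section_spec()] and records every generated primitive — nucleus centres
#' and Ki67 labels, per-fibre widths and angles, realized area fractions,
#' the exact EDJ polyline and its numerically integrated arc-chord ratio —
#' so downstream metrics can be validated by parameter recovery.
#'
#' The section is layered top to bottom: a 20 um mounting margin, the viable
#' epidermis (DAPI nuclei, a fraction Ki67-positive), the sinusoidal EDJ
#' with a Gaussian COLIV basement-membrane band, and the dermis (DAPI
#' nuclei, COLIV vessel rings, and the SHG fibre field, which is confined
#' to a rectangle safely below the deepest EDJ excursion).
#'
#' @param spec a [section_spec()].
#' @return A list with `image` (a [section_image()]) and `truth` (a
#'   `ground_truth` list; see [write_ground_truth()]).
#' @export
generate_section_image <- function(spec) {
  validate_section_spec(spec)
  set.seed(spec$seed)
  psz <- spec$pixel_size_um
  nc <- round(spec$width_um / psz)
  nr <- round(spec$height_um / psz)
  top_margin <- 20

  edj_at <- function(x) edj_y(spec, x, top_margin)
  dermis_top <- top_margin + spec$epidermal_thickness_um +
    spec$edj_amplitude_um + max(4 * spec$bm_sigma_um, 4)
  if (dermis_top >= spec$height_um - 20)
    stop("invalid section_spec: `height_um` leaves no room for the dermis")

  ## --- nuclei ------------------------------------------------------------
  r_nuc <- spec$nucleus_radius_um
  sep <- 2 * r_nuc + 1
  area_mm2 <- function(a_um2) a_um2 / 1e6
  epi_area <- spec$width_um * spec$epidermal_thickness_um
  der_area <- spec$width_um * (spec$height_um - dermis_top)
  n_epi <- round(spec$nuclei_density_per_mm2 * area_mm2(epi_area))
  n_der <- round(spec$nuclei_density_per_mm2 * area_mm2(der_area))
  epi_pts <- place_nuclei(n_epi, spec$width_um,
                          function(x) top_margin + r_nuc,
                          function(x) edj_at(x) - r_nuc,
                          sep, r_nuc + 1)
  der_pts <- place_nuclei(n_der, spec$width_um,
                          function(x) dermis_top + r_nuc,
                          function(x) spec$height_um - r_nuc,
                          sep, r_nuc + 1)
  n_pos <- round(spec$ki67_fraction * nrow(epi_pts))
  ki67_lab <- rep(FALSE, nrow(epi_pts))
  if (n_pos > 0) ki67_lab[sample.int(nrow(epi_pts), n_pos)] <- TRUE

  dapi <- matrix(0, nr, nc)
  dapi <- paint_disks(dapi, epi_pts, r_nuc, 200, psz)
  dapi <- paint_disks(dapi, der_pts, r_nuc, 200, psz)
  ki67 <- matrix(0, nr, nc)
  ki67 <- paint_disks(ki67, epi_pts[ki67_lab, , drop = FALSE],
                      r_nuc, 180, psz)

  ## --- basement membrane (COLIV Gaussian band about the EDJ) -------------
  coliv <- matrix(0, nr, nc)
  if (spec$bm_peak > 0) {
    xs <- seq(0, spec$width_um, by = psz / 4)
    curve_mask <- matrix(1L, nr, nc)
    cc <- pmin(nc, pmax(1L, round(um_to_col(xs, psz))))
    rc <- pmin(nr, pmax(1L, round(um_to_row(edj_at(xs), psz))))
    curve_mask[cbind(rc, cc)] <- 0L
    d_um <- as.matrix(EBImage::distmap(curve_mask)) * psz
    coliv <- spec$bm_peak * exp(-d_um^2 / (2 * spec$bm_sigma_um^2))
    coliv[d_um > 5 * spec$bm_sigma_um] <- 0
  }

  ## --- vessels (COLIV rings in the dermal rectangle) ---------------------
  vessel_mask_true <- matrix(FALSE, nr, nc)
  der_r0 <- ceiling(um_to_row(dermis_top, psz))
  der_px <- (nr - der_r0 + 1L) * nc
  vessels <- data.frame(x = numeric(0), y = numeric(0),
                        r_out = numeric(0), r_in = numeric(0))
  if (spec$vessel_area_fraction > 0) {
    target <- spec$vessel_area_fraction * der_px
    placed <- 0; att <- 0L
    while (placed < target && att < 5000L) {
      att <- att + 1L
      r_out <- runif(1, 5, 10); r_in <- r_out - 2.5
      x <- runif(1, r_out + 1, spec$width_um - r_out - 1)
      y <- runif(1, dermis_top + r_out + 1, spec$height_um - r_out - 1)
      if (nrow(vessels) > 0 &&
          any((vessels$x - x)^2 + (vessels$y - y)^2 <
                (vessels$r_out + r_out + 2)^2)) next
      tmp <- matrix(FALSE, nr, nc)
      tmp <- paint_disks(tmp, cbind(x, y), r_out, TRUE, psz)
      tmp <- paint_disks(tmp, cbind(x, y), r_in, FALSE, psz)
      vessel_mask_true <- vessel_mask_true | tmp
      placed <- placed + sum(tmp)
      vessels <- rbind(vessels,
                       data.frame(x = x, y = y, r_out = r_out, r_in = r_in))
    }
    coliv[vessel_mask_true] <- pmax(coliv[vessel_mask_true], 120)
  }

  ## --- dermal SHG fibre field --------------------------------------------
  shg <- matrix(0, nr, nc)
  fib <- NULL
  if (spec$fibre_area_fraction > 0) {
    fz_h <- spec$height_um - dermis_top
    fib <- generate_fibre_field(
      width_um = spec$width_um, height_um = fz_h, pixel_size_um = psz,
      widths_um = spec$fibre_widths_um,
      weights = spec$fibre_width_weights,
      kappa = spec$orientation_kappa,
      mean_angle_deg = spec$mean_fibre_angle_deg,
      area_fraction = spec$fibre_area_fraction,
      fibre_intensity = spec$shg_fibre_intensity,
      background_intensity = spec$shg_background_intensity,
      seed = NULL
    )
    rows <- der_r0:nr
    sub <- fib$raster[seq_len(length(rows)), , drop = FALSE]
    shg[rows, ] <- sub
  } else {
    shg[der_r0:nr, ] <- spec$shg_background_intensity
  }

  ## --- noise --------------------------------------------------------------
  channels <- list(DAPI = dapi, COLIV = coliv, Ki67 = ki67, SHG = shg)
  if (spec$noise_sd > 0)
    channels <- lapply(channels, function(ch)
      pmax(ch + matrix(rnorm(length(ch), 0, spec$noise_sd), nrow(ch)), 0))

  img <- section_image(channels, psz)

  edj_xs <- seq(0, spec$width_um, by = 1)
  nuc <- rbind(
    if (nrow(epi_pts) > 0)
      data.frame(x = epi_pts[, 1], y = epi_pts[, 2], region = "epidermis",
                 ki67 = ki67_lab),
    if (nrow(der_pts) > 0)
      data.frame(x = der_pts[, 1], y = der_pts[, 2], region = "dermis",
                 ki67 = FALSE)
  )
  truth <- structure(list(
    spec = unclass(spec),
    top_margin_um = top_margin,
    dermis_top_um = dermis_top,
    nuclei = nuc,
    edj = data.frame(x_um = edj_xs, y_um = edj_at(edj_xs)),
    true_arc_chord = sinusoid_arc_chord(spec$edj_amplitude_um,
                                        spec$edj_period_um),
    fibres = if (!is.null(fib)) fib$fibres else NULL,
    true_collagen_fraction = if (!is.null(fib))
      fib$area_fraction_realized else 0,
    true_thick_proportion = if (!is.null(fib))
      fib$thick_area_proportion else NA_real_,
    true_vessel_fraction = sum(vessel_mask_true) / der_px,
    fibre_label_offset_row = der_r0 - 1L
  ), class = "ground_truth")

  list(image = img, truth = truth)
}

#' Serialize / read ground truth
#'
#' Ground truth round-trips through JSON at full floating-point precision.
#'
#' @param truth a `ground_truth` list from [generate_section_image()].
#' @param path JSON path.
#' @return `read_ground_truth` returns the `ground_truth` list.
#' @export
write_ground_truth <- function(truth, path) {
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("nuclei", "edj", "fibres"))
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]])
  structure(x, class = "ground_truth")
}
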