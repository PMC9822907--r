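# shared fixture builders; everything is generated in code at test time

# compact section spec that renders in well under a second
small_spec <- function(...) {
  args <- list(
    width_um = 300, height_um = 220, pixel_size_um = 1,
    epidermal_thickness_um = 40, edj_amplitude_um = 8, edj_period_um = 75,
    nuclei_density_per_mm2 = 600, ki67_fraction = 0.2,
    vessel_area_fraction = 0.05, fibre_area_fraction = 0.13,
    seed = 42L
  )
  do.call(section_spec, utils::modifyList(args, list(...)))
}

# ideal parallel stripes at a given angle (y-down raster, angle from x axis)
stripe_raster <- function(angle_deg, n = 200, width = 7, gap = 16,
                          hi = 100, lo = 0) {
  th <- angle_deg * pi / 180
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), n), n)
  d <- (xs * sin(th) + ys * cos(th)) %% gap
  ifelse(d < width, hi, lo)
}

# sinusoidal boundary sampled densely
sinusoid_curve <- function(amplitude, period, n_periods = 3,
                           step = 0.05) {
  x <- seq(0, n_periods * period, by = step)
  boundary_curve(x, amplitude * sin(2 * pi * x / period))
}

# rotate a boundary curve rigidly about the origin
rotate_curve <- function(curve, angle_deg) {
  th <- angle_deg * pi / 180
  boundary_curve(curve$x_um * cos(th) - curve$y_um * sin(th),
                 curve$x_um * sin(th) + curve$y_um * cos(th))
}

# exhaustive largest-inscribed-disk local thickness (independent oracle):
# for every candidate centre, brute-force the exact distance to the
# nearest background pixel, then assign 2r to every covered pixel
brute_local_thickness <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  if (nrow(fg) == 0) return(out)
  for (i in seq_len(nrow(fg))) {
    r <- fg[i, 1]; c <- fg[i, 2]
    rad <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
    cover <- (fg[, 1] - r)^2 + (fg[, 2] - c)^2 < rad^2
    idx <- fg[cover, , drop = FALSE]
    val <- 2 * rad
    sel <- out[idx] < val
    out[idx[sel, , drop = FALSE]] <- val
  }
  out
}
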