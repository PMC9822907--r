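#' Boundary curve along the epidermal-dermal junction
#'
#' An ordered, open polyline in micrometres. Real sections are traced
#' manually and read from CSV; synthetic sections carry the exact curve in
#' their ground truth.
#'
#' @param x_um,y_um vertex coordinates in micrometres, ordered along the
#'   boundary.
#' @return A `boundary_curve` data.frame with columns `x_um`, `y_um`.
#' @export
boundary_curve <- function(x_um, y_um) {
  stopifnot(length(x_um) == length(y_um), length(x_um) >= 2)
  d <- sqrt(diff(x_um)^2 + diff(y_um)^2)
  if (any(d == 0)) stop("consecutive boundary vertices must be distinct")
  structure(data.frame(x_um = x_um, y_um = y_um),
            class = c("boundary_curve", "data.frame"))
}

#' @rdname boundary_curve
#' @param path CSV with columns `x_um`, `y_um`.
#' @export
read_boundary_csv <- function(path) {
  df <- utils::read.csv(path)
  boundary_curve(df$x_um, df$y_um)
}

#' @rdname boundary_curve
#' @param curve a `boundary_curve`.
#' @export
write_boundary_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

arc_lengths <- function(curve) {
  c(0, cumsum(sqrt(diff(curve$x_um)^2 + diff(curve$y_um)^2)))
}

# point at arc-length position s along the polyline (linear interpolation)
point_at_arc <- function(curve, s, cum = arc_lengths(curve)) {
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(cum) - 1L)
  f <- (s - cum[i]) / (cum[i + 1L] - cum[i])
  cbind(x = curve$x_um[i] + f * (curve$x_um[i + 1L] - curve$x_um[i]),
        y = curve$y_um[i] + f * (curve$y_um[i + 1L] - curve$y_um[i]))
}

#' Arc-chord interdigitation ratio of a boundary
#'
#' Divides the boundary into consecutive sections of equal arc length and,
#' for each section, divides its arc length by the straight-line distance
#' between its endpoints. A flat boundary gives 1; deeper interdigitation
#' of the epidermal-dermal junction gives larger values. The trailing
#' remainder shorter than one section is discarded. The ratio is
#' dimensionless and invariant under rigid motions and uniform scaling of
#' the curve (when the section length is scaled with it).
#'
#' @param curve a [boundary_curve()].
#' @param section_length_um section arc length in micrometres (default
#'   100).
#' @return A list: `mean_ratio` (mean over sections), `per_section`
#'   (data.frame with section index, arc length, chord length, ratio), and
#'   `whole_boundary_ratio` (total arc length over end-to-end distance).
#' @export
arc_chord_ratio <- function(curve, section_length_um = 100) {
  if (section_length_um <= 0) stop("`section_length_um` must be positive")
  cum <- arc_lengths(curve)
  total <- cum[length(cum)]
  if (total < section_length_um)
    stop(sprintf(
      "curve arc length (%.1f um) is shorter than one section (%.1f um)",
      total, section_length_um))
  n_sec <- floor(total / section_length_um)
  breaks <- seq(0, n_sec * section_length_um, by = section_length_um)
  pts <- point_at_arc(curve, breaks, cum)
  chord <- sqrt(diff(pts[, "x"])^2 + diff(pts[, "y"])^2)
  ratio <- section_length_um / chord
  whole <- total / sqrt((curve$x_um[nrow(curve)] - curve$x_um[1])^2 +
                          (curve$y_um[nrow(curve)] - curve$y_um[1])^2)
  list(
    mean_ratio = mean(ratio),
    per_section = data.frame(section = seq_len(n_sec),
                             arc_um = section_length_um,
                             chord_um = chord, ratio = ratio),
    whole_boundary_ratio = whole
  )
}

# linear interpolation of a boundary's y at arbitrary x
boundary_y_at <- function(curve, x) {
  stats::approx(curve$x_um, curve$y_um, xout = x, rule = 1)$y
}

#' Viable-epidermis thickness
#'
#' Probes the vertical distance between the epidermal surface and the
#' epidermal-dermal junction at `n_probes` lateral positions spaced
#' `spacing_um` apart (defaults: 10 probes, 150 um apart), centred within
#' the span both curves cover.
#'
#' @param top,edj [boundary_curve()]s for the epidermal surface and the
#'   EDJ.
#' @param n_probes number of probe locations.
#' @param spacing_um lateral spacing between probes (um).
#' @return A list: `mean_um` and `per_probe` (data.frame `x_um`,
#'   `thickness_um`).
#' @export
epidermal_thickness <- function(top, edj, n_probes = 10,
                                spacing_um = 150) {
  span_lo <- max(min(top$x_um), min(edj$x_um))
  span_hi <- min(max(top$x_um), max(edj$x_um))
  need <- (n_probes - 1) * spacing_um
  if (span_hi - span_lo < need)
    stop(sprintf(
      "boundaries span %.0f um laterally but %d probes %.0f um apart need %.0f um",
      span_hi - span_lo, n_probes, spacing_um, need))
  x0 <- span_lo + (span_hi - span_lo - need) / 2
  xs <- x0 + (seq_len(n_probes) - 1) * spacing_um
  th <- boundary_y_at(edj, xs) - boundary_y_at(top, xs)
  if (any(th <= 0))
    stop("EDJ lies above the surface at some probe positions")
  list(mean_um = mean(th),
       per_probe = data.frame(x_um = xs, thickness_um = th))
}

#' Ki67-positive fraction of epidermal nuclei
#'
#' A nucleus is positive when its mean Ki67 intensity over a disk at its
#' centre exceeds the positivity threshold (Otsu over the per-nucleus
#' means by default, fixed override available). Fractions are reported per
#' 250 um lateral window and pooled; windows without nuclei are missing,
#' not zero.
#'
#' @param nuclei data.frame of nucleus centres `x`, `y` (um), e.g. from
#'   [detect_nuclei()]; an optional logical column `ki67` supplies known
#'   labels directly and skips intensity measurement.
#' @param ki67 Ki67 intensity matrix (ignored when labels are supplied).
#' @param pixel_size_um micrometres per pixel.
#' @param region optional logical matrix; only nuclei whose centre pixel
#'   falls in the region (the epidermis) are used.
#' @param window_um lateral window width (default 250).
#' @param threshold `"otsu"` or fixed numeric positivity threshold.
#' @param radius_um disk radius for the per-nucleus mean intensity.
#' @return A list: `pooled_fraction` (NA when no nuclei), `per_window`
#'   (data.frame `window`, `x_lo_um`, `n`, `n_positive`, `fraction`), `n`,
#'   and threshold provenance.
#' @export
ki67_fraction <- function(nuclei, ki67 = NULL, pixel_size_um = NULL,
                          region = NULL, window_um = 250,
                          threshold = "otsu", radius_um = 2) {
  if (!is.null(region)) {
    stopifnot(is.matrix(region), !is.null(pixel_size_um))
    rr <- pmin(nrow(region), pmax(1L, round(um_to_row(nuclei$y,
                                                      pixel_size_um))))
    cc <- pmin(ncol(region), pmax(1L, round(um_to_col(nuclei$x,
                                                      pixel_size_um))))
    nuclei <- nuclei[region[cbind(rr, cc)], , drop = FALSE]
  }
  if (nrow(nuclei) == 0)
    return(list(pooled_fraction = NA_real_,
                per_window = data.frame(), n = 0L,
                threshold = NA_real_, threshold_mode = "none"))
  if (!is.null(nuclei$ki67)) {
    pos <- as.logical(nuclei$ki67)
    thr <- list(value = NA_real_, mode = "labels")
  } else {
    stopifnot(is.matrix(ki67), !is.null(pixel_size_um))
    means <- vapply(seq_len(nrow(nuclei)), function(i)
      disk_mean(ki67, nuclei$x[i], nuclei$y[i], radius_um,
                pixel_size_um), numeric(1))
    if (max(means) == min(means)) {
      thr <- list(value = max(means), mode = "degenerate")
      pos <- rep(FALSE, length(means))
    } else {
      thr <- resolve_threshold(means, threshold)
      pos <- means > thr$value
    }
  }
  win <- floor((nuclei$x - min(nuclei$x)) / window_um)
  per <- do.call(rbind, lapply(sort(unique(win)), function(w) {
    sel <- win == w
    data.frame(window = w + 1L,
               x_lo_um = min(nuclei$x) + w * window_um,
               n = sum(sel), n_positive = sum(pos[sel]),
               fraction = mean(pos[sel]))
  }))
  list(pooled_fraction = mean(pos), per_window = per,
       n = nrow(nuclei), threshold = thr$value,
       threshold_mode = thr$mode)
}

disk_mean <- function(img, x_um, y_um, radius_um, pixel_size_um) {
  rpx <- radius_um / pixel_size_um
  cc <- um_to_col(x_um, pixel_size_um); rc <- um_to_row(y_um, pixel_size_um)
  c0 <- max(1L, floor(cc - rpx)); c1 <- min(ncol(img), ceiling(cc + rpx))
  r0 <- max(1L, floor(rc - rpx)); r1 <- min(nrow(img), ceiling(rc + rpx))
  hit <- outer((r0:r1 - rc)^2, (c0:c1 - cc)^2, "+") <= rpx^2
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  mean(sub[hit])
}

#' Intensity profiles across the EDJ
#'
#' Samples a channel along trajectories normal to the local EDJ tangent,
#' centred on the EDJ, spanning `trajectory_length_um` (default 25 um) at
#' pixel resolution. Positions are signed distances along the trajectory
#' with 0 at the EDJ crossing and positive values on the dermal side.
#' Trajectories that would leave the image are skipped (and counted).
#'
#' @param channel intensity matrix (typically COLIV).
#' @param pixel_size_um micrometres per pixel.
#' @param edj a [boundary_curve()].
#' @param trajectory_length_um total trajectory span (um).
#' @param n_trajectories number of equally spaced trajectories along the
#'   curve.
#' @return A list of `intensity_profile` data.frames (`position_um`,
#'   `value`), with attribute `n_skipped`.
#' @export
edj_profiles <- function(channel, pixel_size_um, edj,
                         trajectory_length_um = 25,
                         n_trajectories = 20) {
  stopifnot(is.matrix(channel), pixel_size_um > 0, n_trajectories >= 1)
  cum <- arc_lengths(edj)
  total <- cum[length(cum)]
  margin <- trajectory_length_um / 2
  ss <- seq(margin, total - margin, length.out = n_trajectories)
  pos <- seq(-trajectory_length_um / 2, trajectory_length_um / 2,
             by = pixel_size_um)
  eps <- max(total / 1000, 1e-6)
  out <- list(); skipped <- 0L
  for (s in ss) {
    p <- point_at_arc(edj, s, cum)
    a <- point_at_arc(edj, max(0, s - eps), cum)
    b <- point_at_arc(edj, min(total, s + eps), cum)
    tv <- c(b[1] - a[1], b[2] - a[2])
    tv <- tv / sqrt(sum(tv^2))
    nv <- c(-tv[2], tv[1])
    if (nv[2] < 0) nv <- -nv  # positive positions point into the dermis
    px <- p[1] + pos * nv[1]
    py <- p[2] + pos * nv[2]
    vals <- bilinear_sample(channel, px, py, pixel_size_um)
    if (any(is.na(vals))) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <-
      structure(data.frame(position_um = pos, value = vals),
                class = c("intensity_profile", "data.frame"))
  }
  attr(out, "n_skipped") <- skipped
  out
}

# bilinear interpolation at physical coordinates; NA outside the image
bilinear_sample <- function(img, x_um, y_um, pixel_size_um) {
  cc <- um_to_col(x_um, pixel_size_um)
  rr <- um_to_row(y_um, pixel_size_um)
  c0 <- floor(cc); r0 <- floor(rr)
  ok <- c0 >= 1 & r0 >= 1 & c0 + 1 <= ncol(img) & r0 + 1 <= nrow(img)
  out <- rep(NA_real_, length(cc))
  if (!any(ok)) return(out)
  fc <- cc[ok] - c0[ok]; fr <- rr[ok] - r0[ok]
  i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
  i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
  out[ok] <- img[i00] * (1 - fr) * (1 - fc) + img[i01] * (1 - fr) * fc +
    img[i10] * fr * (1 - fc) + img[i11] * fr * fc
  out
}

#' Width and peak of a basement-membrane intensity profile
#'
#' The baseline is the mean of the outer 20 percent of samples at each end
#' of the profile; the peak is the baseline-subtracted maximum; the width
#' is the full width at half maximum, linearly interpolated between
#' samples. A profile with no peak above baseline reports a missing width.
#'
#' @param profile an intensity profile data.frame (`position_um`,
#'   `value`) as returned by [edj_profiles()].
#' @return A list: `width_um` (NA when undefined), `peak`, `baseline`,
#'   `peak_position_um`.
#' @export
profile_width_peak <- function(profile) {
  v <- profile$value; p <- profile$position_um
  n <- length(v)
  if (n < 5) stop("profile needs at least 5 samples")
  k <- max(1L, floor(0.2 * n))
  baseline <- mean(c(v[seq_len(k)], v[seq(n - k + 1L, n)]))
  imax <- which.max(v)
  peak <- v[imax] - baseline
  if (peak <= 0)
    return(list(width_um = NA_real_, peak = peak, baseline = baseline,
                peak_position_um = p[imax]))
  half <- baseline + peak / 2
  cross <- function(i0, i1) {
    # linear interpolation of the crossing between samples i0 and i1
    p[i0] + (half - v[i0]) / (v[i1] - v[i0]) * (p[i1] - p[i0])
  }
  left <- NA_real_
  if (imax >= 2L) for (i in imax:2L) {
    if (v[i - 1L] < half && v[i] >= half) { left <- cross(i - 1L, i); break }
  }
  right <- NA_real_
  if (imax < n) for (i in seq(imax, n - 1L)) {
    if (v[i] >= half && v[i + 1L] < half) { right <- cross(i + 1L, i); break }
  }
  width <- if (is.na(left) || is.na(right)) NA_real_ else right - left
  list(width_um = width, peak = peak, baseline = baseline,
       peak_position_um = p[imax])
}
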