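#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the circular uniform;
#' `kappa = Inf` returns `mu` exactly.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in radians, wrapped to `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  (out + pi) %% (2 * pi) - pi
}

#' Generate a synthetic collagen fibre field
#'
#' Draws non-branching straight strokes of constant width (capsules) into a
#' raster until a requested area fraction is reached. Strokes do not overlap
#' (rejection packing with a one-pixel clearance) so the painted area of
#' each width class is known exactly at generation time. Orientation angles
#' follow an axial von Mises model: the doubled angle `2*theta` is von
#' Mises-distributed about `2*mean_angle_deg` with concentration `kappa`,
#' so `kappa = 0` gives isotropic fibres and `kappa = Inf` perfectly
#' aligned ones.
#'
#' @param width_um,height_um field extent in micrometres.
#' @param pixel_size_um pixel size; must resolve the narrowest fibre
#'   (`pixel_size_um <= min(widths_um) / 3`).
#' @param widths_um fibre width classes in micrometres.
#' @param weights mixture weights over width classes (sum to 1).
#' @param weight_type `"area"`: weights are target shares of painted area;
#'   `"count"`: weights are per-stroke sampling probabilities.
#' @param kappa orientation concentration of the doubled angles (>= 0,
#'   `Inf` allowed).
#' @param mean_angle_deg mean fibre orientation, degrees in `[0, 180)`,
#'   0 = parallel to the x axis.
#' @param area_fraction target fibre area fraction in (0, 1).
#' @param stroke_length_um stroke length (micrometres).
#' @param fibre_intensity,background_intensity raster intensities.
#' @param allow_overlap permit overlapping strokes (area bookkeeping then
#'   reports painted pixels, which can be fewer than the per-stroke sum).
#' @param max_attempts rejection budget before packing is declared
#'   infeasible.
#' @param seed optional integer seed (uses the current RNG state when
#'   `NULL`).
#'
#' @return A list with `raster` (intensity matrix), `label` (integer matrix,
#'   0 background, else fibre id), `fibres` (data.frame: id, width_um,
#'   angle_deg, n_pixels), `area_fraction_realized`, `class_area_px`
#'   (named by width class), `thick_area_proportion` (area with width
#'   > 10 um over total fibre area), and `pixel_size_um`.
#' @export
generate_fibre_field <- function(width_um = 600, height_um = 450,
                                 pixel_size_um = 1,
                                 widths_um = c(6, 14),
                                 weights = c(0.5, 0.5),
                                 weight_type = c("area", "count"),
                                 kappa = 2,
                                 mean_angle_deg = 0,
                                 area_fraction = 0.25,
                                 stroke_length_um = 80,
                                 fibre_intensity = 1,
                                 background_intensity = 0,
                                 allow_overlap = FALSE,
                                 max_attempts = 50000L,
                                 seed = NULL) {
  weight_type <- match.arg(weight_type)
  if (any(widths_um <= 0)) stop("`widths_um` must be positive")
  if (area_fraction <= 0 || area_fraction >= 1)
    stop("`area_fraction` must be in (0, 1)")
  if (abs(sum(weights) - 1) > 1e-8) stop("`weights` must sum to 1")
  if (pixel_size_um > min(widths_um) / 3)
    stop("`pixel_size_um` too coarse: must be <= min(widths_um)/3 = ",
         format(min(widths_um) / 3))
  if (!is.null(seed)) set.seed(seed)

  nc <- round(width_um / pixel_size_um)
  nr <- round(height_um / pixel_size_um)
  total_px <- nr * nc
  target_px <- area_fraction * total_px
  # strokes must fit with room to spare or rejection packing saturates
  stroke_length_um <- min(stroke_length_um,
                          0.45 * min(width_um, height_um))

  label <- matrix(0L, nr, nc)
  blocked <- matrix(FALSE, nr, nc)
  k <- length(widths_um)
  class_px <- setNames(numeric(k), as.character(widths_um))
  fib_id <- integer(0); fib_w <- numeric(0); fib_a <- numeric(0)
  fib_n <- integer(0)
  painted <- 0
  attempts <- 0L
  id <- 0L
  # clearance > sqrt(2) px guarantees distinct strokes are never
  # 8-connected, so every connected component is a single stroke
  clearance_px <- 1.5
  pending_ci <- NA_integer_

  while (painted < target_px) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      if (painted < 0.9 * target_px)
        stop(sprintf(
          "infeasible fibre packing: reached area fraction %.3f of requested %.3f after %d attempts",
          painted / total_px, area_fraction, attempts))
      break
    }
    # the class is drawn once per stroke, not once per placement attempt,
    # so rejection does not bias the class mix towards small strokes
    if (is.na(pending_ci)) {
      pending_ci <- if (weight_type == "count") {
        sample.int(k, 1L, prob = weights)
      } else {
        # greedy: fill the class with the largest absolute area deficit
        which.max(weights * target_px - class_px)
      }
    }
    ci <- pending_ci
    w <- widths_um[ci]
    theta_deg <- (mean_angle_deg +
                    0.5 * rvonmises(1, 0, kappa) * 180 / pi) %% 180
    theta <- theta_deg * pi / 180
    half <- stroke_length_um / 2
    margin <- half + w / 2 + 2 * pixel_size_um
    if (2 * margin >= width_um || 2 * margin >= height_um)
      stop("stroke_length_um too long for the field extent")
    cx <- runif(1, margin, width_um - margin)
    cy <- runif(1, margin, height_um - margin)
    # y grows downward; negate sin so positive angles tilt up-right
    ux <- cos(theta); uy <- -sin(theta)
    x0 <- cx - half * ux; y0 <- cy - half * uy
    x1 <- cx + half * ux; y1 <- cy + half * uy

    pad <- w / 2 + clearance_px * pixel_size_um
    c0 <- max(1L, floor(um_to_col(min(x0, x1) - pad, pixel_size_um)))
    c1 <- min(nc, ceiling(um_to_col(max(x0, x1) + pad, pixel_size_um)))
    r0 <- max(1L, floor(um_to_row(min(y0, y1) - pad, pixel_size_um)))
    r1 <- min(nr, ceiling(um_to_row(max(y0, y1) + pad, pixel_size_um)))
    cols <- c0:c1; rows <- r0:r1
    px <- px_x(matrix(cols, length(rows), length(cols), byrow = TRUE),
               pixel_size_um)
    py <- px_y(matrix(rows, length(rows), length(cols)), pixel_size_um)
    # distance from pixel centres to the stroke segment
    vx <- px - x0; vy <- py - y0
    t <- pmin(1, pmax(0, (vx * ux + vy * uy) / stroke_length_um))
    dx <- vx - t * stroke_length_um * ux
    dy <- vy - t * stroke_length_um * uy
    d2 <- dx * dx + dy * dy
    # half-open coverage: pixel centres strictly inside the capsule, so a
    # nominal width w renders at most w/pixel_size pixels across
    inside <- d2 < (w / 2)^2
    if (!any(inside)) next
    near <- d2 <= (w / 2 + clearance_px * pixel_size_um)^2
    sub_blocked <- blocked[rows, cols, drop = FALSE]
    if (!allow_overlap && any(sub_blocked[inside])) next

    id <- id + 1L
    sub_lab <- label[rows, cols, drop = FALSE]
    newpx <- inside & sub_lab == 0L
    sub_lab[newpx] <- id
    label[rows, cols] <- sub_lab
    blocked[rows, cols] <- sub_blocked | near
    n_new <- sum(newpx)
    painted <- painted + n_new
    class_px[ci] <- class_px[ci] + n_new
    fib_id <- c(fib_id, id); fib_w <- c(fib_w, w)
    fib_a <- c(fib_a, theta_deg); fib_n <- c(fib_n, n_new)
    pending_ci <- NA_integer_
  }

  thick <- widths_um > 10
  raster <- matrix(background_intensity, nr, nc)
  raster[label > 0L] <- fibre_intensity
  list(
    raster = raster,
    label = label,
    fibres = data.frame(id = fib_id, width_um = fib_w,
                        angle_deg = fib_a, n_pixels = fib_n),
    area_fraction_realized = painted / total_px,
    class_area_px = class_px,
    thick_area_proportion = if (painted > 0)
      sum(class_px[thick]) / painted else NA_real_,
    pixel_size_um = pixel_size_um
  )
}
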