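test_that("arc-chord ratio has the right closed-form values", {
  straight <- boundary_curve(seq(0, 2000, by = 10), rep(5, 201))
  r <- arc_chord_ratio(straight, 100)
  expect_equal(r$mean_ratio, 1, tolerance = 1e-12)
  expect_equal(r$whole_boundary_ratio, 1, tolerance = 1e-12)

  # semicircle of radius r as a single section: pi r / 2r = pi/2
  th <- seq(0, pi, length.out = 20001)
  semi <- boundary_curve(50 * cos(th), 50 * sin(th))
  arc_total <- sum(sqrt(diff(semi$x_um)^2 + diff(semi$y_um)^2))
  r2 <- arc_chord_ratio(semi, arc_total)
  expect_equal(r2$mean_ratio, pi / 2, tolerance = 1e-5)
})

test_that("arc-chord on sinusoids matches the dense integration oracle", {
  # A = 10, L = 100: quadrature value 1.0923835473 (one section per period)
  cv <- sinusoid_curve(10, 100, n_periods = 4, step = 0.02)
  per_period_arc <- 100 * 1.0923835473
  r <- arc_chord_ratio(cv, per_period_arc)
  expect_equal(r$mean_ratio, 1.0923835473, tolerance = 0.005 * 1.09)
  expect_equal(r$mean_ratio, 1.0923835473, tolerance = 1e-4)
})

test_that("arc-chord is invariant to rigid motion and uniform scaling", {
  cv <- sinusoid_curve(12, 80, n_periods = 3, step = 0.05)
  base <- arc_chord_ratio(cv, 60)$mean_ratio
  rot <- rotate_curve(cv, 33)
  expect_equal(arc_chord_ratio(rot, 60)$mean_ratio, base,
               tolerance = 1e-10)
  shifted <- boundary_curve(cv$x_um + 111, cv$y_um - 55)
  expect_equal(arc_chord_ratio(shifted, 60)$mean_ratio, base,
               tolerance = 1e-12)
  scaled <- boundary_curve(cv$x_um * 3, cv$y_um * 3)
  expect_equal(arc_chord_ratio(scaled, 180)$mean_ratio, base,
               tolerance = 1e-10)
})

test_that("arc-chord grows monotonically with sinusoid amplitude", {
  ratios <- vapply(c(2, 5, 8, 12, 16, 20), function(a)
    arc_chord_ratio(sinusoid_curve(a, 100, 3), 100)$mean_ratio,
    numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios >= 1))
})

test_that("arc-chord input validation", {
  cv <- sinusoid_curve(5, 100, 1)
  expect_error(arc_chord_ratio(cv, -1), "positive")
  expect_error(arc_chord_ratio(cv, 1e6), "shorter")
  expect_error(boundary_curve(c(0, 0, 1), c(0, 0, 1)), "distinct")
})

test_that("epidermal thickness is exact on flat and wedge boundaries", {
  top <- boundary_curve(c(0, 2000), c(0, 0))
  flat <- boundary_curve(c(0, 2000), c(100, 100))
  r <- epidermal_thickness(top, flat)
  expect_equal(r$mean_um, 100, tolerance = 1e-12)
  expect_identical(nrow(r$per_probe), 10L)
  expect_equal(diff(r$per_probe$x_um), rep(150, 9))
  # linear wedge 50 -> 150 over the probed span: symmetric mean 100
  wedge <- boundary_curve(c(0, 2000), c(50, 150))
  rw <- epidermal_thickness(top, wedge)
  expect_equal(rw$mean_um,
               mean(scarmorph:::boundary_y_at(wedge, rw$per_probe$x_um)),
               tolerance = 1e-12)
  probes <- rw$per_probe$thickness_um
  expect_equal(mean(probes), (probes[1] + probes[10]) / 2,
               tolerance = 1e-12)
})

test_that("epidermal thickness errors name the required span", {
  top <- boundary_curve(c(0, 500), c(0, 0))
  edj <- boundary_curve(c(0, 500), c(80, 80))
  expect_error(epidermal_thickness(top, edj), "1350")
})

test_that("thickness on a sinusoidal EDJ matches a dense sampling oracle", {
  spec <- small_spec(width_um = 1500, epidermal_thickness_um = 60,
                     edj_amplitude_um = 12, edj_period_um = 110,
                     nuclei_density_per_mm2 = 0, fibre_area_fraction = 0,
                     vessel_area_fraction = 0, seed = 2L)
  gen <- generate_section_image(spec)
  top <- boundary_curve(c(0, 1500), rep(gen$truth$top_margin_um, 2))
  edj <- boundary_curve(gen$truth$edj$x_um, gen$truth$edj$y_um)
  r <- epidermal_thickness(top, edj, n_probes = 10, spacing_um = 150)
  # dense 1-um-step vertical-ray oracle over the same probed span
  xs <- seq(min(r$per_probe$x_um), max(r$per_probe$x_um), by = 1)
  dense <- mean(scarmorph:::boundary_y_at(edj, xs) -
                  gen$truth$top_margin_um)
  expect_equal(r$mean_um, dense, tolerance = 0.02)
  # and the flat-EDJ section recovers the generator thickness within 2%
  gen0 <- generate_section_image(small_spec(edj_amplitude_um = 0))
  top0 <- boundary_curve(c(0, 300), rep(gen0$truth$top_margin_um, 2))
  edj0 <- boundary_curve(gen0$truth$edj$x_um, gen0$truth$edj$y_um)
  r0 <- epidermal_thickness(top0, edj0, n_probes = 4, spacing_um = 80)
  expect_equal(r0$mean_um, 40, tolerance = 0.02)
})

test_that("ki67 fraction recovers labels exactly and handles empties", {
  gen <- generate_section_image(small_spec(ki67_fraction = 0.15,
                                           nuclei_density_per_mm2 = 1500,
                                           seed = 6L))
  truth <- gen$truth$nuclei
  epi <- truth[truth$region == "epidermis", ]
  # labels taken from truth: pooled fraction is exact
  r <- ki67_fraction(epi)
  expect_equal(r$pooled_fraction, mean(epi$ki67), tolerance = 1e-12)
  # intensity-based call on the noiseless rendering matches the labels
  psz <- gen$image$pixel_size_um
  det <- detect_nuclei(gen$image$channels$DAPI, psz)
  d <- dim(gen$image$channels$DAPI)
  reg <- matrix(FALSE, d[1], d[2])
  reg[seq_len(floor(gen$truth$dermis_top_um / psz)), ] <- TRUE
  ri <- ki67_fraction(det, gen$image$channels$Ki67, psz, region = reg)
  expect_equal(ri$pooled_fraction, mean(epi$ki67), tolerance = 0.03)
  # all-negative fixture
  neg <- data.frame(x = c(10, 20, 30), y = c(5, 5, 5), ki67 = FALSE)
  expect_equal(ki67_fraction(neg)$pooled_fraction, 0)
  # zero nuclei: missing, not zero
  none <- data.frame(x = numeric(0), y = numeric(0))
  expect_true(is.na(ki67_fraction(none)$pooled_fraction))
})

test_that("EDJ profiles peak at the junction for flat and tilted boundaries", {
  spec <- small_spec(edj_amplitude_um = 0, bm_sigma_um = 2,
                     bm_peak = 100, nuclei_density_per_mm2 = 0,
                     vessel_area_fraction = 0, fibre_area_fraction = 0,
                     seed = 3L)
  gen <- generate_section_image(spec)
  psz <- gen$image$pixel_size_um
  edj <- boundary_curve(gen$truth$edj$x_um, gen$truth$edj$y_um)
  prof <- edj_profiles(gen$image$channels$COLIV, psz, edj,
                       n_trajectories = 8)
  expect_gte(length(prof), 6)
  for (p in prof) {
    wp <- profile_width_peak(p)
    expect_lt(abs(wp$peak_position_um), psz + 1e-9)
  }
  # tilted EDJ: peak offset still under 1 um
  tilt <- boundary_curve(c(0, 300), c(60, 90))
  curve_mask <- matrix(1L, 220, 300)
  xs <- seq(0, 300, by = 0.25)
  ys <- 60 + xs / 10
  rr <- pmin(220, pmax(1, round(ys + 0.5)))
  cc <- pmin(300, pmax(1, round(xs + 0.5)))
  curve_mask[cbind(rr, cc)] <- 0L
  d_um <- as.matrix(EBImage::distmap(curve_mask))
  coliv <- 100 * exp(-d_um^2 / (2 * 4))
  ptilt <- edj_profiles(coliv, 1, tilt, n_trajectories = 6)
  for (p in ptilt)
    expect_lt(abs(profile_width_peak(p)$peak_position_um), 1)
  # uniform channel: flat profile
  flatp <- edj_profiles(matrix(5, 220, 300), 1, tilt,
                        n_trajectories = 3)
  expect_lt(max(flatp[[1]]$value) - min(flatp[[1]]$value), 1e-9)
})

test_that("profile width/peak match the Gaussian closed form", {
  pos <- seq(-12.5, 12.5, by = 0.25)
  prof <- data.frame(position_um = pos,
                     value = 10 + 100 * exp(-pos^2 / (2 * 2^2)))
  wp <- profile_width_peak(prof)
  expect_equal(wp$peak, 100, tolerance = 1e-3)
  expect_equal(wp$width_um, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.02)
  # flat profile: width missing, peak ~ 0
  flat <- data.frame(position_um = pos, value = rep(7, length(pos)))
  wf <- profile_width_peak(flat)
  expect_true(is.na(wf$width_um))
  expect_equal(wf$peak, 0)
  expect_error(profile_width_peak(flat[1:3, ]), "5 samples")
})

test_that("profile FWHM stays within 15% of truth under noise", {
  set.seed(99)
  true_w <- 2 * sqrt(2 * log(2)) * 2
  ws <- vapply(1:20, function(i) {
    pos <- seq(-12.5, 12.5, by = 0.25)
    v <- 10 + 100 * exp(-pos^2 / 8) + rnorm(length(pos), 0, 5)
    profile_width_peak(data.frame(position_um = pos, value = v))$width_um
  }, numeric(1))
  expect_equal(mean(ws), true_w, tolerance = 0.15)
})
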