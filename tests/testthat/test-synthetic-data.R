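test_that("section spec validation names the offending field", {
  expect_error(small_spec(pixel_size_um = -1), "pixel_size_um")
  expect_error(small_spec(ki67_fraction = 1.2), "ki67_fraction")
  expect_error(small_spec(fibre_width_weights = c(0.7, 0.7)),
               "fibre_width_weights")
  expect_error(small_spec(pixel_size_um = 3, fibre_widths_um = c(6, 14)),
               "resolvable")
})

test_that("flat EDJ gives arc-chord truth of exactly 1", {
  gen <- generate_section_image(small_spec(edj_amplitude_um = 0))
  expect_identical(gen$truth$true_arc_chord, 1)
  expect_true(all(diff(gen$truth$edj$y_um) == 0))
})

test_that("zero nucleus density leaves the DAPI channel empty", {
  gen <- generate_section_image(small_spec(nuclei_density_per_mm2 = 0))
  expect_identical(sum(gen$image$channels$DAPI), 0)
  expect_identical(nrow(gen$truth$nuclei), NULL)
})

test_that("recorded arc-chord truth matches a dense numeric integration oracle", {
  # independent quadrature value for A = 10, L = 100 (scipy.integrate.quad)
  gen <- generate_section_image(small_spec(edj_amplitude_um = 10,
                                           edj_period_um = 100))
  expect_equal(gen$truth$true_arc_chord, 1.0923835473, tolerance = 1e-6)
})

test_that("section generation is deterministic for a fixed seed", {
  g1 <- generate_section_image(small_spec(seed = 7L))
  g2 <- generate_section_image(small_spec(seed = 7L))
  expect_identical(g1$image$channels, g2$image$channels)
  expect_identical(g1$truth$nuclei, g2$truth$nuclei)
  g3 <- generate_section_image(small_spec(seed = 8L))
  expect_false(identical(g1$image$channels$DAPI,
                         g3$image$channels$DAPI))
})

test_that("rendered nuclei agree with the recorded centres", {
  gen <- generate_section_image(small_spec(seed = 3L))
  nuc <- gen$truth$nuclei
  # every recorded centre sits on a bright DAPI pixel
  psz <- gen$image$pixel_size_um
  rows <- round(nuc$y / psz + 0.5)
  cols <- round(nuc$x / psz + 0.5)
  expect_true(all(gen$image$channels$DAPI[cbind(rows, cols)] > 0))
  # and detection recovers exactly one centre per nucleus
  det <- detect_nuclei(gen$image$channels$DAPI, psz)
  expect_identical(nrow(det), nrow(nuc))
})

test_that("ground truth round-trips through JSON exactly", {
  gen <- generate_section_image(small_spec(seed = 5L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gen$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$true_arc_chord, gen$truth$true_arc_chord,
               tolerance = 0)
  expect_equal(back$true_collagen_fraction,
               gen$truth$true_collagen_fraction, tolerance = 0)
  expect_equal(back$nuclei$x, gen$truth$nuclei$x, tolerance = 0)
  expect_equal(back$fibres$angle_deg, gen$truth$fibres$angle_deg,
               tolerance = 0)
})

test_that("section image round-trips through TIFF with sidecar metadata", {
  gen <- generate_section_image(small_spec(seed = 5L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_section_tiff(gen$image, path)
  back <- read_section_tiff(path)
  expect_identical(names(back$channels), names(gen$image$channels))
  expect_equal(back$pixel_size_um, gen$image$pixel_size_um)
  # 16-bit quantization bounds the intensity error
  hi <- max(vapply(gen$image$channels, max, numeric(1)))
  expect_lt(max(abs(back$channels$SHG - gen$image$channels$SHG)),
            hi / 65535 * 1.01)
})

test_that("fibre field honours area weights, count weights and kappa", {
  # equal AREA weights: thick share of painted area is 0.5 by construction
  ffa <- generate_fibre_field(width_um = 300, height_um = 300,
                              widths_um = c(6, 14),
                              weights = c(0.5, 0.5),
                              weight_type = "area",
                              area_fraction = 0.15, seed = 1L)
  # granularity: the last placed stroke can shift the balance by ~0.03
  expect_lt(abs(ffa$thick_area_proportion - 0.5), 0.05)
  # equal COUNT weights: expected thick share is 14/(6+14) = 0.7
  shares <- vapply(1:4, function(s)
    generate_fibre_field(width_um = 300, height_um = 300,
                         widths_um = c(6, 14), weights = c(0.5, 0.5),
                         weight_type = "count", area_fraction = 0.15,
                         seed = s)$thick_area_proportion, numeric(1))
  expect_equal(mean(shares), 0.7, tolerance = 0.05)
  # realized area within 10% relative of request
  expect_equal(ffa$area_fraction_realized, 0.15, tolerance = 0.1)
  # kappa = Inf: all angles identical
  ffk <- generate_fibre_field(width_um = 200, height_um = 200,
                              kappa = Inf, mean_angle_deg = 30,
                              area_fraction = 0.15, seed = 3L)
  expect_equal(var(ffk$fibres$angle_deg), 0)
  expect_true(all(ffk$fibres$angle_deg == 30))
})

test_that("fibre field is deterministic and rejects infeasible packing", {
  f1 <- generate_fibre_field(width_um = 200, height_um = 200,
                             area_fraction = 0.15, seed = 9L)
  f2 <- generate_fibre_field(width_um = 200, height_um = 200,
                             area_fraction = 0.15, seed = 9L)
  expect_identical(f1$raster, f2$raster)
  expect_identical(f1$fibres, f2$fibres)
  expect_error(
    generate_fibre_field(width_um = 150, height_um = 150,
                         area_fraction = 0.9, max_attempts = 2000L,
                         seed = 1L),
    "infeasible")
})

test_that("ground-truth areas re-measured by pixel counting match exactly", {
  ff <- generate_fibre_field(width_um = 250, height_um = 250,
                             area_fraction = 0.2, seed = 4L)
  expect_identical(sum(ff$label > 0L) / length(ff$label),
                   ff$area_fraction_realized)
  thick_ids <- ff$fibres$id[ff$fibres$width_um > 10]
  expect_identical(sum(ff$label %in% thick_ids) / sum(ff$label > 0L),
                   ff$thick_area_proportion)
  expect_identical(as.integer(tabulate(ff$label[ff$label > 0L])),
                   ff$fibres$n_pixels)
})

test_that("noiseless planted genes have exact fold changes", {
  gen <- generate_expression_dataset(n_genes = 200,
                                     n_per_timepoint = 3,
                                     n_unique = c(5, 5, 5), n_core = 5,
                                     effect_log2 = 1, noise_sd = 0,
                                     seed = 1L)
  ds <- gen$dataset
  tp <- ds$sample_sheet$timepoint
  g <- gen$truth$core[1]
  fc <- 2^(mean(ds$matrix[g, tp == 2]) - mean(ds$matrix[g, tp == 0]))
  expect_equal(abs(log2(fc)), 1, tolerance = 1e-12)
  # unique-2mo genes shift only at 2 months
  u <- gen$truth$unique2[1]
  expect_equal(mean(ds$matrix[u, tp == 4]),
               mean(ds$matrix[u, tp == 0]), tolerance = 1e-12)
  # null genes identical across timepoints at noise 0
  nl <- gen$truth$null[1]
  expect_equal(var(ds$matrix[nl, ]), 0, tolerance = 1e-20)
})

test_that("expression dataset round-trips through TSV", {
  gen <- generate_expression_dataset(n_genes = 50, n_per_timepoint = 2,
                                     n_unique = c(2, 2, 2), n_core = 2,
                                     seed = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(gen$dataset, path)
  back <- read_expression_tsv(path)
  expect_equal(back$matrix, gen$dataset$matrix, tolerance = 1e-12)
  expect_identical(back$sample_sheet$timepoint,
                   gen$dataset$sample_sheet$timepoint)
})

test_that("von Mises sampler hits closed-form resultant lengths", {
  set.seed(11)
  th <- rvonmises(20000, 0, 2)
  r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_equal(r, besselI(2, 1) / besselI(2, 0), tolerance = 0.02)
  expect_identical(rvonmises(5, 0.3, Inf), rep(0.3, 5))
  set.seed(12)
  u <- rvonmises(5000, 0, 0)
  ru <- sqrt(mean(cos(u))^2 + mean(sin(u))^2)
  expect_lt(ru, 0.05)
})
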