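# Synthetic generator: conservation, analytic truths, determinism, fixtures.

test_that("noiseless unblurred channels conserve the specified totals", {
  rc <- cell_noiseless()
  sp <- strain_preset("wildtype")
  expect_equal(sum(rc$stack$channels$dna), sp$dna_total_intensity)
  expect_equal(sum(rc$stack$channels$mukb), sp$mukb_total_intensity)
  expect_equal(sum(rc$stack$channels$ori), sp$focus_intensity)
})

test_that("derived ground truths follow the stated geometry", {
  sp <- synthetic_spec(topology = "toroid", ring_radius_um = 0.716,
                       tube_sigma_um = 0.187, noise_model = "none",
                       psf_sigma_um = 0)
  rc <- render_cell(sp)
  expect_equal(rc$truth$true_contour_length_um, 2 * pi * 0.716)
  expect_equal(rc$truth$true_contour_length_um, 4.5, tolerance = 1e-3)
  expect_equal(rc$truth$true_fwhm_um, 2 * sqrt(2 * log(2)) * 0.187)
  expect_equal(rc$truth$true_fwhm_um, 0.44, tolerance = 1e-2)
  expect_equal(rc$truth$chromosome_multiplicity, 1L)
  rc8 <- cell_fig8()
  expect_equal(rc8$truth$chromosome_multiplicity, 2L)
  expect_equal(rc8$truth$true_contour_length_um,
               2 * 2 * pi * rc8$truth$ring_radius_um)
})

test_that("geometry that does not fit the frame is rejected with a sizing message", {
  expect_error(synthetic_spec(image_size = c(40L, 40L)), "does not fit")
  expect_error(synthetic_spec(cell_radius_um = 0.5), "footprint")
  expect_error(synthetic_spec(arm_bias = 1.2), "arm_bias")
  expect_error(synthetic_spec(compaction_factor = 0.8), "compaction")
  expect_error(synthetic_spec(ori_angles_deg = numeric(0)), "1 to 4")
  expect_error(synthetic_spec(ter_angles_deg = 1:5 * 10), "1 to 4")
})

test_that("rendering is deterministic given the seed", {
  sp <- strain_preset("wildtype", noise_model = "poisson+gaussian", seed = 9L)
  a <- render_cell(sp); b <- render_cell(sp)
  expect_identical(a$stack$channels, b$stack$channels)
  p1 <- render_population(rep(list(sp), 2), seed = 3L)
  p2 <- render_population(rep(list(sp), 2), seed = 3L)
  expect_identical(p1$stack$channels, p2$stack$channels)
  p3 <- render_population(rep(list(sp), 2), seed = 4L)
  expect_false(identical(p1$stack$channels$dna, p3$stack$channels$dna))
})

test_that("an empty population renders an empty background field", {
  p0 <- render_population(list())
  expect_length(p0$truths, 0)
  expect_equal(sum(p0$stack$channels$dna), 0)
})

test_that("PSF blur with zero padding conserves in-frame intensity to <1%", {
  sp <- strain_preset("wildtype", noise_model = "none")  # object well inside
  rc <- render_cell(sp)
  expect_equal(sum(rc$stack$channels$dna), sp$dna_total_intensity,
               tolerance = 0.01)
  expect_equal(sum(rc$stack$channels$mukb), sp$mukb_total_intensity,
               tolerance = 0.01)
})

test_that("asymmetricity of the noiseless unblurred MukB truth equals arm_bias", {
  for (b in c(0, 0.33, 0.49, 1)) {
    rc <- render_cell(strain_preset("wildtype", noise_model = "none",
                                    psf_sigma_um = 0, arm_bias = b,
                                    dna_arm_bias = 0))
    a <- asymmetricity(rc$stack$channels$mukb[, , 1], rc$truth$ori_px[1, ],
                       rc$truth$com_px)
    expect_equal(a$A, b, tolerance = 1e-6)
  }
})

test_that("raising compaction_factor strictly raises the true density ratio", {
  ratios <- vapply(c(1, 1.2, 1.5, 1.8, 2.4), function(cf) {
    rc <- render_cell(strain_preset("wildtype", noise_model = "none",
                                    psf_sigma_um = 0, dna_arm_bias = 0,
                                    compaction_factor = cf))
    tm <- true_masks(rc$truth)
    compaction_ratio(rc$stack$channels$dna[, , 1], tm$dna, tm$mukb)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("fixture suite writes >=5 fixtures, reruns bit-identically, and respects read-only dirs", {
  d1 <- withr::local_tempdir()
  m1 <- write_fixture_suite(d1, seed = 3L)
  expect_gte(length(m1$fixtures), 5L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  d2 <- withr::local_tempdir()
  write_fixture_suite(d2, seed = 3L)
  for (f in list.files(d1, pattern = "\\.tif$")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)                 # a plain file blocks the path
  ro <- file.path(blocker, "sub")
  expect_error(write_fixture_suite(ro), "not writable")
  expect_false(file.exists(file.path(ro, "manifest.json")))
})
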