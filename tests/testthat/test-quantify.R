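# Focus detection, QC, colocalization, compaction ratio.

test_that("a single rendered focus is found within 0.5 px of its true center", {
  rc <- cell_noisy()
  seg <- segment_cells(rc$stack$channels$phase[, , 1])
  f <- detect_foci(rc$stack$channels$ori[, , 1], seg, 1L, channel = "ori")
  expect_equal(nrow(f), 1L)
  expect_lt(sqrt((f$x - rc$truth$ori_px[1, 1])^2 +
                 (f$y - rc$truth$ori_px[1, 2])^2), 0.5)
})

test_that("close peaks merge keeping the brighter; separated peaks stay", {
  cell <- matrix(TRUE, 60, 60)
  img <- matrix(0, 60, 60)
  img[30, 20] <- 100; img[30, 30] <- 80
  expect_equal(nrow(detect_foci(img, cell)), 2L)
  img2 <- matrix(0, 60, 60)
  img2[30, 20] <- 100; img2[30, 22] <- 80
  f <- detect_foci(img2, cell)
  expect_equal(nrow(f), 1L)
  expect_lt(abs(f$x - 20), 1.5)            # kept the brighter of the pair
  expect_equal(nrow(detect_foci(matrix(0, 60, 60), cell)), 0L)
})

test_that("foci counts are exact for separations beyond 3 PSF sigma", {
  sp <- strain_preset("wildtype", noise_model = "poisson+gaussian",
                      ori_angles_deg = c(0, 120, 240), seed = 19L)
  rc <- render_cell(sp)
  seg <- segment_cells(rc$stack$channels$phase[, , 1])
  f <- detect_foci(rc$stack$channels$ori[, , 1], seg, 1L)
  expect_equal(nrow(f), 3L)
})

test_that("more ter than ori foci discards the cell; zero foci flags anucleate", {
  mk <- function(n) structure(data.frame(x = seq_len(n), y = seq_len(n),
                                         peak_intensity = rep(1, n)),
                              class = c("foci_set", "data.frame"))
  expect_false(qc_foci(mk(1), mk(2))$keep)
  expect_true(qc_foci(mk(2), mk(1))$keep)
  q0 <- qc_foci(mk(0), mk(0))
  expect_true(q0$keep)
  expect_true(q0$anucleate)
})

test_that("intensity overlap spans 0-100% with undefined flagged", {
  img <- matrix(0, 10, 10); img[3:5, 3:5] <- 2
  cell <- matrix(TRUE, 10, 10)
  all_mask <- matrix(TRUE, 10, 10)
  none_mask <- matrix(FALSE, 10, 10); none_mask[8:9, 8:9] <- TRUE
  expect_equal(as.numeric(intensity_overlap_fraction(img, all_mask, cell)), 100)
  expect_equal(as.numeric(intensity_overlap_fraction(img, none_mask, cell)), 0)
  und <- intensity_overlap_fraction(matrix(0, 10, 10), all_mask, cell)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("overlap fraction grows monotonically with the region mask", {
  rc <- cell_noisy()
  seg <- segment_cells(rc$stack$channels$phase[, , 1])
  cell <- seg$labels == 1L
  th <- threshold_channel(rc$stack$channels$dna[, , 1], seg, 1L)
  mk <- threshold_channel(rc$stack$channels$mukb[, , 1], seg, 1L)
  mask <- mk$mask
  prev <- -1
  for (i in 1:3) {
    v <- as.numeric(intensity_overlap_fraction(th$image_raw_bgsub, mask, cell))
    expect_gte(v, prev)
    prev <- v
    mask <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(mask * 1), EBImage::makeBrush(5, "disc"))) > 0
  }
})

test_that("binary focus-mask colocalization follows the 1 px footprint rule", {
  mask <- matrix(FALSE, 40, 40); mask[18:22, 18:22] <- TRUE
  fwhm_px <- 0.35 / 0.065
  expect_true(focus_overlaps_mask(list(x = 20, y = 20), mask, fwhm_px))
  expect_false(focus_overlaps_mask(list(x = 20 + 10 * fwhm_px, y = 20),
                                   mask, fwhm_px))
  # tangent: footprint disk just reaches the mask edge pixel
  expect_true(focus_overlaps_mask(list(x = 22 + fwhm_px / 2 - 1e-9, y = 20),
                                  mask, fwhm_px))
})

test_that("compaction ratio follows the per-area formula", {
  dna <- matrix(0, 20, 20)
  dmask <- matrix(FALSE, 20, 20); dmask[5:15, 5:15] <- TRUE
  mmask <- matrix(FALSE, 20, 20); mmask[5:15, 5:9] <- TRUE
  dna[dmask] <- 3
  expect_equal(compaction_ratio(dna, dmask, mmask)$ratio, 1)
  dna[dmask & mmask] <- 6
  expect_equal(compaction_ratio(dna, dmask, mmask)$ratio, 2)
  # invariant to positive rescaling
  expect_equal(compaction_ratio(5.7 * dna, dmask, mmask)$ratio, 2)
  # empty partition flagged
  und <- compaction_ratio(dna, dmask, dmask)
  expect_true(is.na(und$ratio))
  expect_true(attr(und, "undefined"))
})

test_that("compaction factors 1.8 and 1.2 are recovered on noisy fixtures", {
  for (case in list(list(cf = 1.8, tol = 0.15), list(cf = 1.2, tol = 0.10))) {
    vals <- vapply(1:6, function(s) {
      rc <- render_cell(strain_preset("wildtype",
                                      noise_model = "poisson+gaussian",
                                      dna_arm_bias = 0,
                                      compaction_factor = case$cf, seed = s))
      tm <- true_masks(rc$truth)
      compaction_ratio(rc$stack$channels$dna[, , 1], tm$dna, tm$mukb)$ratio
    }, numeric(1))
    expect_lt(abs(mean(vals) - case$cf), case$tol)
  }
})

test_that("DNA-in-MukB fraction is recovered within 2 points on noisy fixtures", {
  truth <- cell_noiseless()$truth$true_dna_in_mukb_fraction * 100
  vals <- vapply(1:6, function(s) {
    rc <- render_cell(strain_preset("wildtype", noise_model = "poisson+gaussian",
                                    dna_arm_bias = 0, seed = s))
    tm <- true_masks(rc$truth)
    as.numeric(intensity_overlap_fraction(
      rc$stack$channels$dna[, , 1], tm$mukb,
      truth_cell_mask(rc)))
  }, numeric(1))
  expect_lt(abs(mean(vals) - truth), 2)
})

test_that("MatP-deletion-like fixture keeps ter-MukB overlap and compaction recovery", {
  # dna_arm_bias = 0 isolates the compaction parameter: a global DNA arm
  # bias confounds the per-area ratio when the MukB arc is one-sided
  rc <- render_cell(strain_preset("matP_del", noise_model = "poisson",
                                  dna_arm_bias = 0, seed = 3L))
  res <- analyze_stack(rc$stack, strain_label = "matP_del")
  expect_true(res$ter_overlaps_mukb)
  tm <- true_masks(rc$truth)
  ratio <- compaction_ratio(rc$stack$channels$dna[, , 1], tm$dna, tm$mukb)$ratio
  expect_lt(abs(ratio - rc$truth$compaction_factor), 0.15)
})
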