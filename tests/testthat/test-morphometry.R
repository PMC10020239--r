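# Backbone extraction, topology, contour length, FWHM width, Feret diameter.

test_that("a perfect annulus traces to one clean loop of length ~2*pi*r", {
  mask <- annulus_mask(r = 10)
  bb <- extract_backbone(mask)
  expect_equal(bb$cycle_count, 1L)
  expect_equal(bb$branch_nodes, 0L)
  expect_true(bb$closed[1])
  len <- contour_length(bb, 1)
  expect_equal(len, 2 * pi * 10, tolerance = 0.05)
})

test_that("rotating a mask by 90 degrees changes the contour length by <2%", {
  mask <- annulus_mask(r = 13, hw = 4)
  l1 <- contour_length(extract_backbone(mask), 1)
  l2 <- contour_length(extract_backbone(t(mask)), 1)
  expect_lt(abs(l1 - l2) / l1, 0.02)
})

test_that("a straight bar gives an open path with exact polyline length", {
  bb <- extract_backbone(bar_mask(n = 10))
  expect_equal(bb$cycle_count, 0L)
  expect_equal(bb$branch_nodes, 0L)
  expect_equal(classify_topology(bb), "open")
  # 10 pixels -> 9 unit steps -> 0.585 um at 0.065 um/px
  expect_equal(contour_length(bb, 0.065), 9 * 0.065)
})

test_that("empty or tiny masks degrade gracefully", {
  expect_warning(bb <- extract_backbone(matrix(FALSE, 10, 10)), "empty")
  expect_equal(contour_length(bb, 0.065), 0)
  expect_equal(classify_topology(bb), "open")
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
  bb1 <- extract_backbone(m)
  expect_equal(contour_length(bb1, 0.065), 0)
})

test_that("backbone pixels stay inside the mask and ordering is deterministic", {
  mask <- annulus_mask(r = 10)
  bb <- extract_backbone(mask)
  coords <- bb$paths[[1]]
  expect_true(all(mask[cbind(coords[, 2], coords[, 1])]))
  bb2 <- extract_backbone(mask)
  expect_identical(bb$paths, bb2$paths)
})

test_that("synthetic toroid recovers contour length within 5%", {
  rc <- cell_noisy()
  seg <- segment_cells(rc$stack$channels$phase[, , 1])
  th <- threshold_channel(rc$stack$channels$dna[, , 1], seg, 1L)
  bb <- extract_backbone(th)
  expect_equal(classify_topology(bb), "toroid")
  len <- contour_length(bb, 0.065)
  expect_equal(len, rc$truth$true_contour_length_um, tolerance = 0.05)
})

test_that("figure-eight fixture yields two loops sharing a branch node", {
  rc <- cell_fig8()
  seg <- segment_cells(rc$stack$channels$phase[, , 1])
  th <- threshold_channel(rc$stack$channels$dna[, , 1], seg, 1L)
  bb <- extract_backbone(th)
  expect_equal(bb$cycle_count, 2L)
  expect_gte(bb$branch_nodes, 1L)
  expect_equal(classify_topology(bb), "figure_eight")
})

test_that("FWHM of a noiseless Gaussian tube matches the closed form", {
  rc <- cell_noiseless()
  seg <- segment_cells(rc$stack$channels$phase[, , 1])
  th <- threshold_channel(rc$stack$channels$dna[, , 1], seg, 1L)
  bb <- extract_backbone(th)
  wf <- width_fwhm(bb, th$image_raw_bgsub, 0.065)
  expect_equal(wf$width_fwhm_um, 2 * sqrt(2 * log(2)) * 0.187,
               tolerance = 0.05)
  expect_gte(wf$n_stations, 10L)
  # scale invariance
  wf2 <- width_fwhm(bb, 2 * th$image_raw_bgsub, 0.065)
  expect_equal(wf2$width_fwhm_um, wf$width_fwhm_um, tolerance = 1e-9)
})

test_that("apparent width of the blurred noisy fixture recovers truth within 10%", {
  rc <- cell_noisy()
  seg <- segment_cells(rc$stack$channels$phase[, , 1])
  th <- threshold_channel(rc$stack$channels$dna[, , 1], seg, 1L)
  bb <- extract_backbone(th)
  wf <- width_fwhm(bb, th$image_raw_bgsub, 0.065)
  expect_equal(wf$width_fwhm_um, rc$truth$true_fwhm_um, tolerance = 0.10)
})

test_that("too few stations yields a flagged NA width", {
  bb <- extract_backbone(bar_mask(n = 6))
  wf <- width_fwhm(bb, matrix(1, 26, 26), 0.065)
  expect_true(is.na(wf$width_fwhm_um))
})

test_that("Feret diameter follows the caliper geometry", {
  expect_equal(feret_diameter(cbind(5, 5), 0.065), 0)
  expect_equal(feret_diameter(rbind(c(2, 3), c(7, 3)), 0.065), 5 * 0.065)
  # rendered disk of diameter 15 px
  side <- 31
  xs <- matrix(seq_len(side), side, side, byrow = TRUE)
  ys <- matrix(seq_len(side), side, side)
  disk <- (xs - 16)^2 + (ys - 16)^2 <= 7.5^2
  idx <- which(disk, arr.ind = TRUE)
  d <- feret_diameter(cbind(idx[, 2], idx[, 1]), 1)
  expect_equal(d, 15, tolerance = 1 / 15)
})

test_that("topology classification matches generator truth on a noisy population", {
  res <- population50()$results
  expect_equal(nrow(res), 50L)
  expect_gte(mean(res$topology == "toroid"), 0.95)
  rc <- cell_noiseless()
  r0 <- analyze_stack(rc$stack)
  expect_equal(r0$topology, "toroid")
})
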