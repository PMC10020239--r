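# Center of mass, central axis, and the arm-asymmetry statistic.

test_that("center of mass behaves like an intensity-weighted centroid", {
  # symmetric annulus: compaction 1 so no arc pulls the centroid sideways
  rc <- render_cell(strain_preset("wildtype", noise_model = "none",
                                  psf_sigma_um = 0, dna_arm_bias = 0,
                                  compaction_factor = 1))
  dna <- rc$stack$channels$dna[, , 1]
  com <- center_of_mass(dna)
  expect_lt(sqrt(sum((com - rc$truth$com_px)^2)), 0.5)
  one <- matrix(0, 9, 9); one[3, 7] <- 5
  expect_equal(unname(center_of_mass(one)), c(7, 3))
  # translation equivariance
  shifted <- matrix(0, 9, 9); shifted[4, 8] <- 5
  expect_equal(unname(center_of_mass(shifted)),
               unname(center_of_mass(one)) + c(1, 1))
  expect_error(center_of_mass(matrix(0, 5, 5)), "zero total")
})

test_that("central axis requires distinct points and A is side-symmetric", {
  expect_error(central_axis(c(3, 3), c(3, 3)), "undefined")
  img <- matrix(0, 40, 40)
  img[15:25, 24] <- 3; img[15:25, 16] <- 1
  a1 <- asymmetricity(img, ori = c(20, 12), com = c(20, 28))
  a2 <- asymmetricity(img, ori = c(20, 28), com = c(20, 12))
  expect_equal(a1$A, a2$A)                      # swapping flips labels only
  expect_equal(a1$sum_right, a2$sum_left)
})

test_that("asymmetricity hits its analytic anchors", {
  img <- matrix(0, 40, 40)
  img[20, 16] <- 5; img[20, 24] <- 5            # equal split
  a <- asymmetricity(img, ori = c(20.5, 20), com = c(20.5, 30))
  expect_equal(a$A, 0)
  img2 <- matrix(0, 40, 40); img2[20, 24] <- 5  # all on one side
  a2 <- asymmetricity(img2, ori = c(20.5, 20), com = c(20.5, 30))
  expect_equal(a2$A, 1)
  img3 <- matrix(0, 40, 40)
  img3[20, 24] <- 3; img3[20, 16] <- 1          # 3:1 -> 0.5
  a3 <- asymmetricity(img3, ori = c(20.5, 20), com = c(20.5, 30))
  expect_equal(a3$A, 0.5)
})

test_that("axis pixels split 50/50 by default and can be excluded", {
  img <- matrix(0, 40, 40)
  img[20, 20] <- 8                              # exactly on a vertical axis
  img[20, 24] <- 4
  a <- asymmetricity(img, ori = c(20, 20), com = c(20, 30))
  expect_equal(a$sum_right, 4 + 4)              # half of the axis pixel
  expect_equal(a$sum_left, 4)
  ax <- asymmetricity(img, ori = c(20, 20), com = c(20, 30),
                      axis_pixels = "exclude")
  expect_equal(ax$sum_left, 0)
  expect_equal(ax$A, 1)
})

test_that("A is invariant to rescaling and to rigid 90-degree rotation", {
  rc <- cell_noiseless()
  m <- rc$stack$channels$mukb[, , 1]
  ori <- rc$truth$ori_px[1, ]; com <- rc$truth$com_px
  a <- asymmetricity(m, ori, com)
  expect_equal(asymmetricity(3.7 * m, ori, com)$A, a$A)
  # rotate image and geometry together by 90 degrees (x,y) -> (H+1-y, x)
  H <- nrow(m)
  mr <- t(m)[, H:1]                              # 90-degree rotation
  rot <- function(p) c(H + 1 - p[2], p[1])
  ar <- asymmetricity(mr, rot(ori), rot(com))
  expect_lt(abs(ar$A - a$A), 0.02)
})

test_that("zero ROI signal is flagged undefined", {
  a <- asymmetricity(matrix(0, 40, 40), ori = c(20, 20), com = c(20, 30))
  expect_true(is.na(a$A))
  expect_true(attr(a, "undefined"))
})

test_that("noiseless generator truth reproduces arm_bias to 1e-6 (cross-module)", {
  rc <- render_cell(strain_preset("wildtype", noise_model = "none",
                                  psf_sigma_um = 0, dna_arm_bias = 0,
                                  arm_bias = 0.27))
  a <- asymmetricity(rc$stack$channels$mukb[, , 1], rc$truth$ori_px[1, ],
                     rc$truth$com_px)
  expect_equal(a$A, 0.27, tolerance = 1e-6)
})

test_that("arm bias is recovered within 0.05 by the full pipeline at fixture SNR", {
  vals <- vapply(1:12, function(s) {
    rc <- render_cell(strain_preset("wildtype", noise_model = "poisson",
                                    psf_sigma_um = 0, dna_arm_bias = 0,
                                    seed = s))
    analyze_stack(rc$stack)$asym_mukb
  }, numeric(1))
  expect_lt(abs(median(vals) - 0.33), 0.05)
})

test_that("wildtype preset populations order median A as DNA < MukB", {
  res <- population50()$results
  expect_lt(median(res$asym_dna, na.rm = TRUE),
            median(res$asym_mukb, na.rm = TRUE))
})
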