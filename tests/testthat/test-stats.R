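# One-way ANOVA, significance stars, population summaries.

# independent oracle: explicit between/within sum-of-squares decomposition
anova_by_hand <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(all) - length(groups)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the hand sum-of-squares oracle", {
  g <- list(c(1, 2, 3), c(2, 3, 4))
  a <- one_way_anova(g)
  oracle <- anova_by_hand(g)
  expect_equal(a$F, 1.5)                       # SSB = 1.5, SSW = 4, df (1,4)
  expect_equal(a$F, oracle$F)
  expect_equal(a$p, oracle$p)
  expect_equal(a$df, c(1L, 4L))
  set.seed(5)
  g2 <- list(rnorm(8), rnorm(12, 0.5), rnorm(6, 1))
  a2 <- one_way_anova(g2)
  o2 <- anova_by_hand(g2)
  expect_equal(a2$F, o2$F)
  expect_equal(a2$p, o2$p)
})

test_that("two identical groups give F = 0 and permutations leave F unchanged", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  g <- list(c(4, 7, 1, 3), c(2, 9, 5))
  f1 <- one_way_anova(g)$F
  f2 <- one_way_anova(list(g[[1]][c(3, 1, 4, 2)], g[[2]][c(2, 3, 1)]))$F
  expect_equal(f1, f2)
})

test_that("F equals t-squared for two groups", {
  set.seed(9)
  a <- rnorm(15); b <- rnorm(12, 0.8)
  f <- one_way_anova(list(a, b))$F
  t <- stats::t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(f, unname(t)^2)
})

test_that("degenerate variance cases are flagged", {
  z <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(z$p, 0)
  expect_equal(z$flag, "zero_within_variance")
  id <- one_way_anova(list(c(3, 3), c(3, 3)))
  expect_true(is.nan(id$F))
  expect_equal(id$flag, "identical_data")
})

test_that("significance stars follow the printed conventions", {
  expect_equal(significance_stars(0.2), "ns")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.00005), "****")
  # boundaries go to the more significant bin
  expect_equal(significance_stars(0.05), "*")
  expect_equal(significance_stars(0.01), "**")
  expect_equal(significance_stars(1e-4), "****")
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
})

test_that("population summaries handle single cells and are deterministic", {
  tab <- data.frame(strain_label = "wt", discarded = FALSE,
                    compaction_ratio = 1.7, asym_dna = 0.2, asym_mukb = 0.3)
  rep1 <- summarize_population(tab)
  expect_equal(rep1$summary$n, rep(1L, 3))
  expect_true(all(is.na(rep1$summary$sd)))
  tab2 <- data.frame(strain_label = rep(c("a", "b"), each = 4),
                     discarded = FALSE,
                     compaction_ratio = c(1.8, 1.7, 1.9, 1.75,
                                          1.2, 1.25, 1.15, 1.3))
  expect_identical(summarize_population(tab2), summarize_population(tab2))
  av <- summarize_population(tab2)$anova
  expect_equal(av$metric, "compaction_ratio")
  expect_lt(av$p, 0.05)
})

test_that("populations generated with different arm bias separate by ANOVA", {
  res_wt <- population50()$results
  pop_eq <- render_population(
    rep(list(strain_preset("mukB_EQ", noise_model = "poisson+gaussian")), 20),
    seed = 13L)
  res_eq <- analyze_stack(pop_eq$stack, strain_label = "mukB_EQ")
  a <- one_way_anova(list(res_wt$asym_mukb[!is.na(res_wt$asym_mukb)],
                          res_eq$asym_mukb[!is.na(res_eq$asym_mukb)]))
  expect_lt(a$p, 0.05)
})
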