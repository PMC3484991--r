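test_that("delta-delta Ct arithmetic matches the hand example", {
  plate <- data.frame(
    sample = rep(c("cal", "trt"), each = 2),
    target = rep(c("Tbp", "Crhr1"), 2),
    ct = c(20, 26, 20, 25))
  out <- ddct_quantify(plate, calibrator = "cal")
  trt <- out[out$sample == "trt", ]
  expect_equal(trt$delta_delta_ct, -1)
  expect_equal(trt$rel_quantity, 2)
  cal <- out[out$sample == "cal", ]
  expect_equal(cal$rel_quantity, 1)   # calibrator relative to itself
})

test_that("technical duplicates are averaged on the Ct scale", {
  plate <- data.frame(
    sample = rep(c("cal", "trt"), each = 4),
    target = rep(rep(c("Tbp", "G"), each = 2), 2),
    ct = c(20, 20, 25, 27, 20, 20, 24, 24),
    replicate = rep(1:2, 4))
  out <- ddct_quantify(plate, calibrator = "cal")
  # calibrator G mean Ct 26, trt 24 -> ddCt = -2 -> quantity 4
  expect_equal(out$rel_quantity[out$sample == "trt"], 4)
})

test_that("quantities are invariant to a constant shift of a sample's Ct values", {
  plate <- data.frame(
    sample = rep(c("cal", "trt"), each = 2),
    target = rep(c("Tbp", "G"), 2),
    ct = c(20, 26, 21.7, 26.7))   # trt shifted by +1.7 across both targets
  out <- ddct_quantify(plate, calibrator = "cal")
  expect_equal(out$rel_quantity[out$sample == "trt"], 2^(26 - 20 - (26.7 - 21.7)))
  plate2 <- plate
  plate2$ct[plate2$sample == "trt"] <- plate2$ct[plate2$sample == "trt"] + 3
  out2 <- ddct_quantify(plate2, calibrator = "cal")
  expect_equal(out2$rel_quantity, out$rel_quantity)
})

test_that("wells beyond 34 cycles are non-detects, flagged not imputed", {
  plate <- data.frame(
    sample = rep(c("cal", "trt"), each = 2),
    target = rep(c("Tbp", "G"), 2),
    ct = c(20, 26, 20, 34.5))
  out <- ddct_quantify(plate, calibrator = "cal")
  trt <- out[out$sample == "trt", ]
  expect_false(trt$detected)
  expect_true(is.na(trt$rel_quantity))
  # control-gene non-detect is an error
  bad <- plate; bad$ct[3] <- 35
  expect_error(ddct_quantify(bad, calibrator = "cal"), "control")
  # calibrator non-detect makes the target uncomputable in all samples
  cal_nd <- plate; cal_nd$ct[2] <- 36; cal_nd$ct[4] <- 26
  out2 <- ddct_quantify(cal_nd, calibrator = "cal")
  expect_true(all(is.na(out2$rel_quantity)))
})

test_that("pooled t-test matches the hand example and its symmetries", {
  ht <- two_group_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(abs(ht$t), sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(ht$p, 0.287864134727, tolerance = 1e-9)
  expect_equal(ht$df, 4)
  swapped <- two_group_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$t, -ht$t)
  expect_equal(swapped$p, ht$p)
  same <- two_group_ttest(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  det <- two_group_ttest(c(1, 1), c(2, 2))
  expect_equal(det$p, 0)
})

test_that("ANOVA + Dunnett respects its contracts on fixtures", {
  flat <- list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2))
  res <- anova_dunnett(flat, nsim = 1e3, seed = 1)
  expect_equal(res$F, 0)
  expect_true(all(res$comparisons$p_adj == 1))
  set.seed(61)
  groups <- list(ctrl = rnorm(5), a = rnorm(5, 1), b = rnorm(5, 2),
                 c = rnorm(5))
  res <- anova_dunnett(groups, nsim = 2e4, seed = 2)
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw))
  expect_true(all(res$comparisons$p_adj <= 1))
  expect_error(anova_dunnett(list(1:3, 4:6)), "two_group_ttest")
  expect_error(anova_dunnett(list(1:3, 4:6, 7)), "at least 2")
})

test_that("Dunnett adjusted p-values agree with multcomp", {
  skip_if_not_installed("multcomp")
  set.seed(67)
  groups <- list(ctrl = rnorm(6), t1 = rnorm(6, 0.8), t2 = rnorm(6, 1.6),
                 t3 = rnorm(6, -0.5))
  res <- anova_dunnett(groups, nsim = 2e5, seed = 3)
  y <- unlist(groups)
  g <- factor(rep(names(groups), each = 6), levels = names(groups))
  fit <- stats::aov(y ~ g)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(res$comparisons$p_adj, as.numeric(ref), tolerance = 0.01)
  # F and its p match the classical ANOVA
  av <- summary(fit)[[1]]
  expect_equal(res$F, av$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_anova, av$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("4PL fit recovers noiseless curve parameters and inverts exactly", {
  true <- list(a = 0.1, b = 1.3, c = 18, d = 2.4)
  x <- c(0, 1, 3, 9, 27, 81, 243)
  y <- true$d + (true$a - true$d) / (1 + (x / true$c)^true$b)
  fit <- fourpl_fit(x, y)
  for (p in names(true))
    expect_equal(fit[[p]], true[[p]], tolerance = 1e-4)
  # inflection identity: response (a+d)/2 inverts to c
  mid <- fourpl_invert(fit, (fit$a + fit$d) / 2)
  expect_equal(mid$concentration, fit$c, tolerance = 1e-6)
  # round trip on interior points
  inv <- fourpl_invert(fit, y[2:6])
  expect_equal(inv$concentration, x[2:6], tolerance = 1e-3)
})

test_that("4PL inversion flags the assay sensitivity floor and bad responses", {
  true <- list(a = 0.05, b = 1.1, c = 30, d = 3)
  x <- c(0, 2, 6, 18, 54, 162)
  y <- true$d + (true$a - true$d) / (1 + (x / true$c)^true$b)
  fit <- fourpl_fit(x, y)
  y3 <- true$d + (true$a - true$d) / (1 + (3 / true$c)^true$b)
  inv <- fourpl_invert(fit, y3, sensitivity = 4.5)
  expect_equal(inv$concentration, 3, tolerance = 1e-3)
  expect_true(inv$below_sensitivity)
  ok <- fourpl_invert(fit, y[5], sensitivity = 4.5)
  expect_false(ok$below_sensitivity)
  expect_error(fourpl_invert(fit, 10), "outside")
  # non-monotone standards warn
  expect_warning(fourpl_fit(x, y[c(1, 3, 2, 4, 5, 6)]), "monotone")
})
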