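log2_ds <- function(m, groups) {
  sheet <- data.frame(sample_id = colnames(m), group = groups,
                      stringsAsFactors = FALSE)
  expression_dataset(m, sheet, "mogene_1_0_st", "log2")
}

test_that("two-group fit computes means, folds and pooled variances", {
  m <- rbind(A = c(3, 3, 5, 5), B = c(2, 2, 2, 2), C = c(1, 3, 2, 6))
  colnames(m) <- paste0("s", 1:4)
  ds <- log2_ds(m, c("g1", "g1", "g2", "g2"))
  fit <- fit_two_group(ds, c("s1", "s2"), c("s3", "s4"))
  expect_equal(fit$logFC[fit$gene == "A"], 2)
  expect_equal(fit$fold[fit$gene == "A"], 4)
  expect_equal(fit$s2[fit$gene == "A"], 0)
  expect_equal(fit$df, rep(2, 3))
  expect_equal(fit$logFC[fit$gene == "B"], 0)
  # C: groups (1,3) and (2,6): s2 = (2 + 8) / 2 = 5
  expect_equal(fit$s2[fit$gene == "C"], 5)
  expect_error(fit_two_group(ds, "s1", c("s3", "s4")), "reference")
})

test_that("pooled variance is unbiased for the simulation truth", {
  set.seed(31)
  sigma <- 0.7
  m <- matrix(rnorm(1000 * 6, sd = sigma), 1000, 6,
              dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:6)))
  ds <- log2_ds(m, rep(c("a", "b"), each = 3))
  fit <- fit_two_group(ds, paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(abs(mean(fit$s2) - sigma^2) / sigma^2, 0.05)
})

test_that("prior estimation solves the trigamma moment equations", {
  # all variances equal -> point-mass prior at that value
  pr <- estimate_prior(rep(2.5, 50), df = 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s02, 2.5)
  # scale equivariance: doubling s2 doubles s02, d0 unchanged
  set.seed(17)
  s2 <- 1 * 4 / rchisq(5000, 4) * rchisq(5000, 4) / 4
  p1 <- estimate_prior(s2, 4)
  p2 <- estimate_prior(2 * s2, 4)
  expect_equal(p2$s02, 2 * p1$s02, tolerance = 1e-8)
  expect_equal(p2$d0, p1$d0, tolerance = 1e-6)
  expect_error(estimate_prior(rep(0, 50), 4), "zero")
})

test_that("prior estimation agrees with limma's moment fit", {
  skip_if_not_installed("limma")
  set.seed(23)
  s2 <- 1.3 * 5 / rchisq(20000, 5) * rchisq(20000, 6) / 6
  mine <- estimate_prior(s2, 6)
  ref <- limma::fitFDist(s2, df1 = 6)
  expect_equal(mine$d0, ref$df2, tolerance = 0.05)
  expect_equal(mine$s02, ref$scale, tolerance = 0.05)
})

test_that("moderation follows the shrinkage formulas", {
  # plug-in arithmetic: d0 = 4, s02 = 1, s2 = 3, df = 4, n1 = n2 = 3, logFC = 1
  fit <- structure(
    data.frame(gene = "g", mean_ref = 0, mean_trt = 1,
               mean_lin_ref = 1, mean_lin_trt = 2,
               logFC = 1, fold = 2, s2 = 3, df = 4),
    class = c("de_fit", "data.frame"), n_ref = 3, n_trt = 3)
  prior <- structure(list(d0 = 4, s02 = 1), class = "ebayes_prior")
  res <- moderate(fit, prior)
  expect_equal(res$s2_post, 2)
  expect_equal(res$t, 0.8660254, tolerance = 1e-7)
  expect_equal(res$p, 0.411694431826, tolerance = 1e-9)   # 2*pt(-t, 8)
  # zero logFC -> t = 0, p = 1
  fit0 <- fit; fit0$logFC <- 0
  res0 <- moderate(fit0, prior)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # d0 = Inf -> shared variance s02
  resinf <- moderate(fit, structure(list(d0 = Inf, s02 = 2),
                                    class = "ebayes_prior"))
  expect_equal(resinf$s2_post, 2)
})

test_that("the d0 = 0 limit is the ordinary pooled t", {
  set.seed(41)
  m <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  m[1:10, 4:6] <- m[1:10, 4:6] + 1
  ds <- log2_ds(m, rep(c("a", "b"), each = 3))
  fit <- fit_two_group(ds, paste0("s", 1:3), paste0("s", 4:6))
  res <- moderate(fit, structure(list(d0 = 0, s02 = 1),
                                 class = "ebayes_prior"))
  ref_p <- apply(m, 1, function(x) stats::t.test(x[4:6], x[1:3],
                                                 var.equal = TRUE)$p.value)
  expect_equal(res$p, unname(ref_p), tolerance = 1e-12)
  # zero-variance genes under d0 = 0 are flagged degenerate
  m2 <- rbind(flat = rep(c(1, 2), each = 3))
  colnames(m2) <- paste0("s", 1:6)
  ds2 <- log2_ds(m2, rep(c("a", "b"), each = 3))
  fit2 <- fit_two_group(ds2, paste0("s", 1:3), paste0("s", 4:6))
  res2 <- moderate(fit2, structure(list(d0 = 0, s02 = 1),
                                   class = "ebayes_prior"))
  expect_true(res2$degenerate)
  expect_equal(res2$p, 0)
})

test_that("shrinkage compresses the spread of the gene variances", {
  set.seed(47)
  m <- matrix(rnorm(2000 * 6), 2000, 6,
              dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:6)))
  ds <- log2_ds(m, rep(c("a", "b"), each = 3))
  res <- de_two_group(ds, paste0("s", 1:3), paste0("s", 4:6))
  pr <- attr(res, "prior")
  expect_true(is.finite(pr$d0) && pr$d0 > 0)
  expect_lt(var(log(res$s2_post)), var(log(res$s2[res$s2 > 0])))
})

test_that("moderated statistics agree with limma on shared hyperparameters", {
  skip_if_not_installed("limma")
  set.seed(53)
  # heterogeneous true variances so the prior df is small and informative
  sig <- sqrt(1 * 5 / rchisq(500, 5))
  m <- matrix(rnorm(500 * 8, sd = rep(sig, 8)), 500, 8,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:8)))
  m[1:25, 5:8] <- m[1:25, 5:8] + 1.5
  ds <- log2_ds(m, rep(c("a", "b"), each = 4))
  fit <- fit_two_group(ds, paste0("s", 1:4), paste0("s", 5:8))
  design <- cbind(1, rep(c(0, 1), each = 4))
  lfit <- limma::eBayes(limma::lmFit(m, design))
  prior <- structure(list(d0 = lfit$df.prior, s02 = lfit$s2.prior),
                     class = "ebayes_prior")
  res <- moderate(fit, prior)
  expect_equal(res$t, lfit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p, lfit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("BH step-up matches the hand calculation and its contracts", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(59)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= 0))
  expect_true(all(res <- q >= 0 & q <= 1))
})
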