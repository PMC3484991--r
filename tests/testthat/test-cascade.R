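test_that("the hand-traced fixture flows through all seven rules", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$de, fx$signals, fx$annotation)
  expect_setequal(res$candidates$gene,
                  c("PASS", "GONO200", "RATIO1", "CARRY"))
  # verdicts at the culling steps
  s1 <- res$steps$step1
  expect_equal(s1$verdict[s1$gene == "SIG110"], "culled")   # strict > 110
  expect_equal(s1$verdict[s1$gene == "LOWQ"], "culled")
  s2 <- res$steps$step2
  expect_equal(s2$verdict[s2$gene == "GONO"], "culled")
  expect_equal(s2$verdict[s2$gene == "GONO200"], "retained") # strict > 200
  s3 <- res$steps$step3
  expect_equal(s3$verdict[s3$gene == "SERT"], "culled")
  expect_equal(s3$verdict[s3$gene == "RATIO1"], "retained")  # ratio 1.0 passes
  expect_equal(res$steps$step4$verdict[res$steps$step4$gene == "NOWT"],
               "culled")
  expect_equal(res$steps$step6$verdict[res$steps$step6$gene == "MOUSEHIT"],
               "culled")
  # carry rule: absent from every 3' platform at steps 4-6
  for (i in 4:6) {
    st <- res$steps[[i]]
    expect_equal(st$verdict[st$gene == "CARRY"], "carried")
  }
})

test_that("candidate table is sorted, one-decimal, with Mafb+ GD13/GD11 folds", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$de, fx$signals, fx$annotation)
  tab <- fold_change_table(res)
  expect_true(all(diff(tab$fold) <= 0))
  expect_equal(tab$fold[tab$gene == "CARRY"], 3.0)
  expect_equal(tab$fold, round(tab$fold, 1))
})

test_that("audit trails expose every decision with its numbers", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$de, fx$signals, fx$annotation)
  tr <- audit_trail(res, "GONO")
  expect_equal(nrow(tr), 2)                       # stopped at step 2
  expect_equal(tr$verdict, c("retained", "culled"))
  expect_match(tr$rule[2], ">200")
  expect_match(tr$values[2], "signal=250")
  full <- audit_trail(res, "CARRY")
  expect_equal(nrow(full), 7)
  expect_equal(full$verdict[4:6], rep("carried", 3))
  expect_error(audit_trail(res, "NOSUCH"), "unknown gene")
})

test_that("missing contrasts and inconsistent tables raise structured errors", {
  fx <- cascade_fixture()
  de <- fx$de
  de$rat_dbp <- NULL
  expect_error(run_cascade(de, fx$signals, fx$annotation), "step 5")
  de <- fx$de
  # annotation says present on mouse430_2 but the table lacks the gene
  de$whole_gd14_vs_gd11 <-
    de$whole_gd14_vs_gd11[de$whole_gd14_vs_gd11$gene != "PASS", ]
  attr(de$whole_gd14_vs_gd11, "platform") <- "mouse430_2"
  expect_error(run_cascade(de, fx$signals, fx$annotation), "step 4")
})

test_that("the step sequence is equivalent to its set-algebra composition", {
  # independent oracle: evaluate each rule as a global predicate and
  # intersect, ignoring step order; cull-only steps commute
  run <- run_screen(small_config(seed = 77, n_genes = 300))
  de <- run$de; sg <- run$signals; th <- run$cascade$thresholds
  ann <- run$study$annotation
  genes <- sort(de$mafb_gd13_vs_gd11$gene)
  v <- function(tab, col) stats::setNames(tab[[col]], tab$gene)[genes]
  p1 <- sg$mafb_gd13[genes] > th$signal_floor &
    v(de$mafb_gd13_vs_gd11, "fold") > 1 & v(de$mafb_gd13_vs_gd11, "q") < 0.25
  p2 <- !(sg$pou5f1_gd13[genes] > th$signal_ceiling)
  p3 <- !(sg$sox9_gd13[genes] / sg$mafb_gd13[genes] > 1)
  pres <- function(pf) platform_presence(ann, pf)[genes]
  ok <- function(tab) {
    f <- v(tab, "fold"); q <- v(tab, "q")
    !is.na(f) & f > 1 & q < 0.25
  }
  okdn <- function(tab) {
    f <- v(tab, "fold"); q <- v(tab, "q")
    !is.na(f) & f < 1 & q < 0.25
  }
  p4 <- !pres("mouse430_2") | ok(de$whole_gd14_vs_gd11) |
    ok(de$whole_gd14_vs_gd12)
  rat_pres <- Reduce(`|`, lapply(de$rat_dbp, function(tab)
    pres(attr(tab, "platform"))))
  p5 <- !rat_pres | Reduce(`|`, lapply(de$rat_dbp, okdn))
  p6 <- !pres("mouse430_2") | !Reduce(`|`, lapply(de$mouse_dbp, okdn))
  p7 <- ok(de$testis_vs_ovary)
  oracle <- genes[p1 & p2 & p3 & p4 & p5 & p6 & p7]
  expect_setequal(run$cascade$candidates$gene, oracle)
})

test_that("tightening any threshold never enlarges the final set", {
  fx <- cascade_fixture()
  base <- run_cascade(fx$de, fx$signals, fx$annotation)$candidates$gene
  tighter <- list(
    cascade_thresholds(signal_floor = 400),
    cascade_thresholds(signal_ceiling = 40),
    cascade_thresholds(fdr_cutoff = 0.05),
    cascade_thresholds(ratio_threshold = 2.5))
  for (th in tighter) {
    cand <- run_cascade(fx$de, fx$signals, fx$annotation, th)$candidates$gene
    expect_true(all(cand %in% base))
  }
})
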