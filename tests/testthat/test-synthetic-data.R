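test_that("config validation names the offending field", {
  expect_error(generator_config(contamination = 0.6), "contamination")
  expect_error(generator_config(dbp_rat_suppression = 1.5),
               "dbp_rat_suppression")
  expect_error(generator_config(replicate_sd = 0), "replicate_sd")
  expect_error(generator_config(n_genes = 10, n_gonocyte_markers = 20),
               "n_genes")
})

test_that("study-scale defaults sit on the intended side of the signal cutoffs", {
  cfg <- default_paper_config()
  expect_lt(2^cfg$background_mean, 110)
  expect_gt(2^cfg$marker_high_level, 200)
  expect_identical(cfg$replicates_per_group, 3)
  expect_identical(cfg$n_genes, 28000)
  expect_identical(cfg$n_leydig_markers, 12)
  expect_identical(cfg$n_sertoli_markers, 17)
  expect_identical(cfg$n_gonocyte_markers, 135)
})

test_that("same config and seed give byte-identical studies", {
  cfg <- small_config(seed = 7)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  for (nm in names(s1$datasets))
    expect_identical(s1$datasets[[nm]]$signal, s2$datasets[[nm]]$signal)
  expect_identical(s1$annotation, s2$annotation)
})

test_that("study emits all nine dataset types with study-design group sizes", {
  study <- generate_study(small_config())
  expect_setequal(names(study$datasets),
                  c("mafb_testis", "sox9_testis", "pou5f1_testis",
                    "mafb_ovary", "whole_testis", "mouse_dbp_acute",
                    "mouse_dbp_subchronic", "rat_dbp_acute",
                    "rat_dbp_subchronic"))
  mafb <- study$datasets$mafb_testis
  expect_setequal(unique(mafb$sheet$gestational_day), c(11, 12, 13))
  expect_equal(unname(table(mafb$sheet$gestational_day)), rep(3L, 3),
               ignore_attr = TRUE)
  rat <- study$datasets$rat_dbp_acute
  expect_setequal(rat$sheet$arm[rat$sheet$exposure == "DBP"],
                  c("1h", "3h", "6h", "18h"))
})

test_that("zero contamination leaves off-target markers at background", {
  cfg <- small_config(contamination = 0, seed = 11)
  study <- generate_study(cfg)
  mafb <- study$datasets$mafb_testis
  gd13 <- select_samples(mafb, gestational_day = 13)
  gono <- study$annotation$gene[study$annotation$known_class == "gonocyte"]
  m <- log2(mafb$signal[gono, gd13, drop = FALSE])
  # per-gene mean should sit within 3 * replicate_sd / sqrt(n) of its own
  # baseline; against the population background mean allow the baseline
  # spread too
  tol <- 3 * sqrt(cfg$replicate_sd^2 / length(gd13) + cfg$background_sd^2 /
                    length(gono))
  expect_lt(abs(mean(m) - cfg$background_mean), tol)
})

test_that("empirical Mafb+ GD13/GD11 folds track the configured induction", {
  cfg <- small_config(leydig_gd_effect = 4, replicate_sd = 0.1,
                      contamination = 0, seed = 21)
  study <- generate_study(cfg)
  mafb <- study$datasets$mafb_testis
  gd11 <- select_samples(mafb, gestational_day = 11)
  gd13 <- select_samples(mafb, gestational_day = 13)
  ley <- study$annotation$gene[study$annotation$known_class == "leydig"]
  fold <- 2^(rowMeans(log2(mafb$signal[ley, gd13])) -
               rowMeans(log2(mafb$signal[ley, gd11])))
  expect_true(all(fold >= 3.0 & fold <= 5.3))
})

test_that("vanishing replicate noise recovers configured folds exactly", {
  cfg <- small_config(leydig_gd_effect = 6, replicate_sd = 1e-9,
                      contamination = 0, seed = 5)
  study <- generate_study(cfg)
  mafb <- study$datasets$mafb_testis
  gd11 <- select_samples(mafb, gestational_day = 11)
  gd13 <- select_samples(mafb, gestational_day = 13)
  ley <- study$annotation$gene[study$annotation$known_class == "leydig"]
  fold <- 2^(rowMeans(log2(mafb$signal[ley, gd13])) -
               rowMeans(log2(mafb$signal[ley, gd11])))
  expect_equal(unname(fold), rep(6, length(ley)), tolerance = 1e-6)
  # rat DBP suppression likewise
  rat <- study$datasets$rat_dbp_subchronic
  veh <- select_samples(rat, exposure = "vehicle")
  dbp <- select_samples(rat, exposure = "DBP")
  ley_rat <- intersect(ley, rownames(rat$signal))
  fold_rat <- 2^(rowMeans(log2(rat$signal[ley_rat, dbp])) -
                   rowMeans(log2(rat$signal[ley_rat, veh])))
  expect_equal(unname(fold_rat), rep(cfg$dbp_rat_suppression,
                                     length(ley_rat)), tolerance = 1e-6)
})

test_that("off-target marker signal rises strictly with contamination", {
  means <- vapply(c(0, 0.1, 0.3), function(cc) {
    study <- generate_study(small_config(contamination = cc,
                                         replicate_sd = 1e-6, seed = 3))
    mafb <- study$datasets$mafb_testis
    gd13 <- select_samples(mafb, gestational_day = 13)
    gono <- study$annotation$gene[study$annotation$known_class == "gonocyte"]
    mean(log2(mafb$signal[gono, gd13]))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("masked genes appear as absence flags, never numeric rows", {
  study <- generate_study(small_config(platform_absent_fraction = 0.2,
                                       seed = 9))
  ann <- study$annotation
  absent <- ann$gene[!ann$present_mouse430_2]
  expect_gt(length(absent), 0)
  wt <- study$datasets$whole_testis
  expect_length(intersect(absent, rownames(wt$signal)), 0)
  # markers are never masked by default
  markers <- ann$gene[ann$known_class != "none"]
  for (pf in c("mouse430_2", "rat230a", "rat230_2"))
    expect_true(all(platform_presence(ann, pf)[markers]))
})

test_that("study round-trips through the TSV writers", {
  study <- generate_study(small_config(n_genes = 60, n_gonocyte_markers = 5,
                                       seed = 2))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  ds <- read_dataset(file.path(dir, "mafb_testis_matrix.tsv"),
                     file.path(dir, "mafb_testis_sheet.tsv"),
                     platform = "mogene_1_0_st", scale = "linear")
  expect_equal(ds$signal, study$datasets$mafb_testis$signal,
               tolerance = 1e-12)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$known_class, study$annotation$known_class)
})
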