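#!/usr/bin/env Rscript
# Stage 3: moderated-t differential expression for every cascade contrast.
#
# Fits each two-group contrast the filter cascade consumes (empirical-Bayes
# moderated t, BH FDR): Mafb+ GD13 vs GD11; whole testis GD14 vs GD11/GD12;
# each rat DBP arm vs vehicle; mouse DBP vs vehicle; GD13 Mafb+ testis vs
# ovary. Also computes the GD13 linear group-mean signal vectors used by
# the signal-threshold steps. Writes DE tables under results/de/.

suppressPackageStartupMessages(library(flcscreen))

platforms <- c(mafb_testis = "mogene_1_0_st", sox9_testis = "mogene_1_0_st",
               pou5f1_testis = "mogene_1_0_st", mafb_ovary = "mogene_1_0_st",
               whole_testis = "mouse430_2", mouse_dbp_acute = "mouse430_2",
               mouse_dbp_subchronic = "mouse430_2", rat_dbp_acute = "rat230a",
               rat_dbp_subchronic = "rat230_2")
norm <- lapply(names(platforms), function(nm)
  read_dataset(file.path("results/normalized", paste0(nm, "_matrix.tsv")),
               file.path("results/normalized", paste0(nm, "_sheet.tsv")),
               platform = platforms[[nm]], scale = "log2"))
names(norm) <- names(platforms)

dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
save_de <- function(de, name) {
  write_de_table(de, file.path("results/de", paste0(name, ".tsv")))
  cat(sprintf("%-24s %5d genes, %4d with q < 0.25\n", name, nrow(de),
              sum(de$q < 0.25)))
}

mafb <- norm$mafb_testis
gd11 <- select_samples(mafb, gestational_day = 11)
gd13 <- select_samples(mafb, gestational_day = 13)
save_de(de_two_group(mafb, gd11, gd13, "mafb_gd13_vs_gd11"),
        "mafb_gd13_vs_gd11")

wt <- norm$whole_testis
for (ref_gd in c(11, 12)) {
  de <- de_two_group(wt, select_samples(wt, gestational_day = ref_gd),
                     select_samples(wt, gestational_day = 14))
  save_de(de, sprintf("whole_gd14_vs_gd%d", ref_gd))
}

dbp <- function(ds, arm) {
  de_two_group(ds, select_samples(ds, exposure = "vehicle"),
               select_samples(ds, exposure = "DBP", arm = arm))
}
for (arm in c("1h", "3h", "6h", "18h"))
  save_de(dbp(norm$rat_dbp_acute, arm), paste0("rat_dbp_acute_", arm))
save_de(dbp(norm$rat_dbp_subchronic, "subchronic"), "rat_dbp_subchronic")
save_de(dbp(norm$mouse_dbp_acute, "acute"), "mouse_dbp_acute")
save_de(dbp(norm$mouse_dbp_subchronic, "subchronic"), "mouse_dbp_subchronic")

# testis vs ovary within GD13 Mafb+ cells (same sorted-cell platform)
ov <- norm$mafb_ovary
common <- intersect(rownames(mafb$signal), rownames(ov$signal))
tvo <- expression_dataset(
  cbind(mafb$signal[common, gd13, drop = FALSE],
        ov$signal[common, , drop = FALSE]),
  rbind(mafb$sheet[mafb$sheet$sample_id %in% gd13, ], ov$sheet),
  mafb$platform, "log2")
save_de(de_two_group(tvo, ov$sheet$sample_id, gd13, "testis_vs_ovary"),
        "testis_vs_ovary")

signals <- data.frame(
  gene = rownames(mafb$signal),
  mafb_gd13 = group_mean_linear(mafb, gd13),
  pou5f1_gd13 = group_mean_linear(norm$pou5f1_testis,
                                  colnames(norm$pou5f1_testis$signal)),
  sox9_gd13 = group_mean_linear(norm$sox9_testis,
                                colnames(norm$sox9_testis$signal)))
write.table(signals, "results/de/signals.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/de/ (DE tables + GD13 signal vectors)\n")
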