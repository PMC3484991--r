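#!/usr/bin/env Rscript
# Stage 5: screen diagnostics.
#
# Recovery accounting: how many planted Leydig / Sertoli / gonocyte markers
# entered the screen and how many survived to the candidate list, with the
# exact hypergeometric enrichment of the Leydig set. Contamination
# profiling: class-mean signals of each marker class in each sorted GD13
# fraction against that fraction's background, flagging admixture.

suppressPackageStartupMessages(library(flcscreen))

# rebuild the cascade from the stage-3/4 tables (cheap and deterministic)
annotation <- read_annotation("results/study/annotation.tsv")
sig <- read.delim("results/de/signals.tsv")
signals <- list(mafb_gd13 = setNames(sig$mafb_gd13, sig$gene),
                pou5f1_gd13 = setNames(sig$pou5f1_gd13, sig$gene),
                sox9_gd13 = setNames(sig$sox9_gd13, sig$gene))
rd <- function(name, platform)
  read_de_table(file.path("results/de", paste0(name, ".tsv")), platform)
de <- list(
  mafb_gd13_vs_gd11 = rd("mafb_gd13_vs_gd11", "mogene_1_0_st"),
  whole_gd14_vs_gd11 = rd("whole_gd14_vs_gd11", "mouse430_2"),
  whole_gd14_vs_gd12 = rd("whole_gd14_vs_gd12", "mouse430_2"),
  rat_dbp = c(lapply(setNames(nm = c("1h", "3h", "6h", "18h")), function(a)
    rd(paste0("rat_dbp_acute_", a), "rat230a")),
    list(subchronic = rd("rat_dbp_subchronic", "rat230_2"))),
  mouse_dbp = list(acute = rd("mouse_dbp_acute", "mouse430_2"),
                   subchronic = rd("mouse_dbp_subchronic", "mouse430_2")),
  testis_vs_ovary = rd("testis_vs_ovary", "mogene_1_0_st"))
res <- run_cascade(de, signals, annotation)

rec <- recovery_report(res, annotation)
print(rec)
jsonlite::write_json(list(counts = rec$counts, universe_n = rec$universe_n,
                          candidates_n = rec$candidates_n,
                          enrichment_p = rec$enrichment_p),
                     "results/recovery.json",
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)

fracs <- c("Mafb+" = "mafb_testis", "Sox9+" = "sox9_testis",
           "Pou5f1+" = "pou5f1_testis")
sorted <- lapply(names(fracs), function(f) {
  ds <- read_dataset(
    file.path("results/normalized", paste0(fracs[[f]], "_matrix.tsv")),
    file.path("results/normalized", paste0(fracs[[f]], "_sheet.tsv")),
    platform = "mogene_1_0_st", scale = "log2")
  ids <- select_samples(ds, gestational_day = 13, gonad = "testis")
  expression_dataset(ds$signal[, ids, drop = FALSE],
                     ds$sheet[ds$sheet$sample_id %in% ids, ],
                     ds$platform, ds$scale)
})
names(sorted) <- names(fracs)
prof <- contamination_profile(sorted, annotation)
print(prof, row.names = FALSE)
write.table(prof, "results/contamination.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nown-fraction classes are far above background; off-target classes\n",
    "reflect the generator's admixture rate\n")
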