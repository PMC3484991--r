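#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-dataset study.
#
# Emulates the screen's nine microarray dataset types (sorted Mafb+/Sox9+/
# Pou5f1+ fractions, whole testis time course, rat and mouse DBP exposures)
# at the study's conditions: 28,000 genes, 12 planted Leydig / 17 Sertoli /
# 135 gonocyte markers, 10% sorted-fraction contamination, 3 replicates per
# group. Writes every dataset, the annotation and the ground truth as TSV
# under results/study/.

suppressPackageStartupMessages(library(flcscreen))

cfg <- default_paper_config()
cat("generator config: ", cfg$n_genes, "genes, seed", cfg$seed, "\n")

study <- generate_study(cfg)
print(study)

dir.create("results", showWarnings = FALSE)
write_study(study, "results/study")
cat("wrote results/study/ (",
    length(list.files("results/study")), "files )\n")

# quick look: planted Leydig markers are induced GD11 -> GD13 in Mafb+ cells
mafb <- study$datasets$mafb_testis
ley <- study$annotation$gene[study$annotation$known_class == "leydig"]
gd11 <- select_samples(mafb, gestational_day = 11)
gd13 <- select_samples(mafb, gestational_day = 13)
fold <- rowMeans(mafb$signal[ley, gd13]) / rowMeans(mafb$signal[ley, gd11])
cat("raw Mafb+ GD13/GD11 fold of planted Leydig markers:",
    paste(round(range(fold), 2), collapse = " - "), "\n")
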