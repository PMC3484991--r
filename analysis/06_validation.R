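#!/usr/bin/env Rscript
# Stage 6: downstream quantification statistics.
#
# Demonstrates the validation-side tools on generated example data shaped
# like the study's confirmatory experiments: delta-delta Ct quantification
# of a candidate transcript against the Tbp endogenous control with the
# 34-cycle non-detect rule; a CRH concentration-response analyzed by
# one-way ANOVA with Dunnett's comparisons against vehicle; and a 4PL
# immunoassay standard curve with a 4.5 pM sensitivity floor.

suppressPackageStartupMessages(library(flcscreen))
set.seed(20121025)
dir.create("results", showWarnings = FALSE)

## -- qPCR: ddCt quantification against Tbp ------------------------------
samples <- c("vehicle", "crh_1nM", "crh_10nM", "crh_100nM")
true_fold <- c(1, 1.6, 3.2, 3.6)
plate <- do.call(rbind, lapply(seq_along(samples), function(i) {
  data.frame(sample = samples[i],
             target = rep(c("Tbp", "Cyp17a1"), each = 2),
             ct = c(rnorm(2, 20, 0.1),
                    rnorm(2, 26 - log2(true_fold[i]), 0.1)),
             replicate = rep(1:2, 2))
}))
qr <- ddct_quantify(plate, calibrator = "vehicle")
cat("relative Cyp17a1 quantity (vehicle = 1):\n")
print(qr[, c("sample", "delta_delta_ct", "rel_quantity")], row.names = FALSE)
write.table(qr, "results/qpcr_quantities.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## -- group comparison: ANOVA + Dunnett vs vehicle -----------------------
groups <- lapply(seq_along(samples), function(i)
  2^(-rnorm(6, log2(1 / true_fold[i]), 0.4)))
names(groups) <- samples
ad <- anova_dunnett(groups, control_index = 1, nsim = 1e5, seed = 77)
print(ad)
write.table(ad$comparisons, "results/dunnett.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## -- immunoassay: 4PL standard curve ------------------------------------
true <- list(a = 0.08, b = 1.15, c = 32, d = 2.6)   # c in pM
std_conc <- c(0, 1, 3, 10, 30, 100, 300, 1000)
std_resp <- true$d + (true$a - true$d) / (1 + (std_conc / true$c)^true$b) +
  rnorm(length(std_conc), 0, 0.01)
fit <- fourpl_fit(std_conc, std_resp)
cat(sprintf("4PL fit: a=%.3f b=%.3f c=%.1f pM d=%.3f\n",
            fit$a, fit$b, fit$c, fit$d))
unknown_resp <- c(0.35, 0.9, 1.8, 0.15)
conc <- fourpl_invert(fit, unknown_resp, sensitivity = 4.5)
cat("inverted sample concentrations (pM), sensitivity floor 4.5 pM:\n")
print(conc, row.names = FALSE)
write.table(conc, "results/crh_concentrations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
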