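#' Run the full candidate-gene screen end to end
#'
#' Generates (or accepts) a synthetic study, normalizes every dataset
#' (background shift, quantile normalization, log2), fits the moderated-t
#' contrasts the cascade needs, runs the seven-step filter, and produces
#' the recovery report and contamination profile. All randomness derives
#' from the generator config's master seed.
#'
#' Contrasts fitted: Mafb+ GD13 vs GD11; whole testis GD14 vs GD11 and
#' GD14 vs GD12; each rat DBP arm (acute 1/3/6/18 h, subchronic) vs its
#' vehicle; mouse DBP acute and subchronic vs vehicle; GD13 Mafb+ testis
#' vs ovary.
#'
#' @param config A [generator_config()] (default [default_paper_config()]).
#' @param study Optionally a pre-built `synthetic_study` (config ignored
#'   for generation).
#' @param thresholds A [cascade_thresholds()].
#' @param floor Background floor passed to normalization (default 0).
#' @param output_dir Optional directory; when given, writes candidates TSV,
#'   per-step counts JSON, recovery JSON, contamination TSV and a combined
#'   summary JSON.
#' @return List of class `screen_run`: `study`, `normalized` (named list of
#'   log2 datasets), `de` (contrast tables), `signals`, `cascade`,
#'   `recovery`, `contamination`, `summary`.
#' @examples
#' run <- run_screen(generator_config(n_genes = 400, seed = 5))
#' run$recovery$counts
#' @export
run_screen <- function(config = default_paper_config(), study = NULL,
                       thresholds = cascade_thresholds(), floor = 0,
                       output_dir = NULL) {
  if (is.null(study)) study <- generate_study(config)
  stopifnot(inherits(study, "synthetic_study"))
  annotation <- study$annotation

  normalized <- lapply(study$datasets, function(ds)
    normalize_dataset(ds, floor = floor)$dataset)

  mafb <- normalized$mafb_testis
  gd11 <- select_samples(mafb, gestational_day = 11)
  gd13 <- select_samples(mafb, gestational_day = 13)
  wt <- normalized$whole_testis
  wt11 <- select_samples(wt, gestational_day = 11)
  wt12 <- select_samples(wt, gestational_day = 12)
  wt14 <- select_samples(wt, gestational_day = 14)

  # GD13 Mafb+ testis vs ovary: same platform, combine on common genes
  ov <- normalized$mafb_ovary
  common <- intersect(rownames(mafb$signal), rownames(ov$signal))
  tvo_mat <- cbind(mafb$signal[common, gd13, drop = FALSE],
                   ov$signal[common, , drop = FALSE])
  tvo_sheet <- rbind(mafb$sheet[mafb$sheet$sample_id %in% gd13, ],
                     ov$sheet)
  tvo <- expression_dataset(tvo_mat, tvo_sheet, mafb$platform, "log2")
  ov_ids <- ov$sheet$sample_id

  dbp_contrast <- function(ds, arm_label) {
    veh <- select_samples(ds, exposure = "vehicle")
    dbp <- select_samples(ds, exposure = "DBP", arm = arm_label)
    de_two_group(ds, veh, dbp, contrast = arm_label)
  }
  rat_acute <- normalized$rat_dbp_acute
  rat_arms <- setdiff(unique(rat_acute$sheet$arm[rat_acute$sheet$exposure == "DBP"]), "")
  rat_dbp <- c(
    stats::setNames(lapply(rat_arms, function(a) dbp_contrast(rat_acute, a)),
                    paste0("rat_acute_", rat_arms)),
    list(rat_subchronic = dbp_contrast(normalized$rat_dbp_subchronic,
                                       "subchronic")))
  mouse_dbp <- list(
    mouse_acute = dbp_contrast(normalized$mouse_dbp_acute, "acute"),
    mouse_subchronic = dbp_contrast(normalized$mouse_dbp_subchronic,
                                    "subchronic"))

  de <- list(
    mafb_gd13_vs_gd11 = de_two_group(mafb, gd11, gd13,
                                     contrast = "mafb_gd13_vs_gd11"),
    whole_gd14_vs_gd11 = de_two_group(wt, wt11, wt14,
                                      contrast = "whole_gd14_vs_gd11"),
    whole_gd14_vs_gd12 = de_two_group(wt, wt12, wt14,
                                      contrast = "whole_gd14_vs_gd12"),
    rat_dbp = rat_dbp,
    mouse_dbp = mouse_dbp,
    testis_vs_ovary = de_two_group(tvo, ov_ids, gd13,
                                   contrast = "testis_vs_ovary"))

  signals <- list(
    mafb_gd13 = group_mean_linear(mafb, gd13),
    pou5f1_gd13 = group_mean_linear(normalized$pou5f1_testis,
                                    colnames(normalized$pou5f1_testis$signal)),
    sox9_gd13 = group_mean_linear(normalized$sox9_testis,
                                  colnames(normalized$sox9_testis$signal)))

  cascade <- run_cascade(de, signals, annotation, thresholds)
  recovery <- recovery_report(cascade, annotation)
  sorted_sets <- list("Mafb+" = mafb_gd13_subset(mafb, gd13),
                      "Sox9+" = normalized$sox9_testis,
                      "Pou5f1+" = normalized$pou5f1_testis)
  contamination <- contamination_profile(sorted_sets, annotation)

  summary <- list(
    seed = study$config$seed,
    n_genes = study$config$n_genes,
    step_counts = cascade$step_counts,
    candidates_n = nrow(cascade$candidates),
    recovery = recovery$counts,
    enrichment_p = recovery$enrichment_p,
    top_candidates = utils::head(fold_change_table(cascade), 10))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fold_change_table(cascade),
                       file.path(output_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cascade$step_counts,
                         file.path(output_dir, "step_counts.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(counts = recovery$counts,
                              universe_n = recovery$universe_n,
                              candidates_n = recovery$candidates_n,
                              enrichment_p = recovery$enrichment_p),
                         file.path(output_dir, "recovery.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.table(contamination,
                       file.path(output_dir, "contamination.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  structure(list(study = study, normalized = normalized, de = de,
                 signals = signals, cascade = cascade, recovery = recovery,
                 contamination = contamination, summary = summary),
            class = "screen_run")
}

# GD13 testis subset of the Mafb+ dataset (for the contamination profile)
mafb_gd13_subset <- function(mafb, gd13_ids) {
  expression_dataset(mafb$signal[, gd13_ids, drop = FALSE],
                     mafb$sheet[mafb$sheet$sample_id %in% gd13_ids, ],
                     mafb$platform, mafb$scale)
}

#' @export
print.screen_run <- function(x, ...) {
  cat("screen_run\n")
  print(x$cascade)
  print(x$recovery)
  invisible(x)
}
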