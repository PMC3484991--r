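#' Generator configuration for the synthetic multi-dataset study
#'
#' Parameterizes the simulated study: planted marker counts, signal scale,
#' the GD11 to GD13 Leydig induction, sorted-fraction contamination, the
#' rat-specific phthalate suppression, replicate noise, group sizes, and
#' 3'-platform presence masking. Signals live on the log2 scale internally;
#' emitted matrices are linear.
#'
#' @param n_genes Total genes simulated.
#' @param n_leydig_markers,n_sertoli_markers,n_gonocyte_markers Number of
#'   planted marker genes per class.
#' @param background_mean,background_sd Mean and gene-to-gene SD (log2 units)
#'   of the non-specific background expression level.
#' @param marker_high_level Log2 signal of a marker gene in its own fraction
#'   at its peak.
#' @param leydig_gd_effect Linear fold induction of Leydig markers from GD11
#'   to GD13 in Mafb+ cells (and GD11 to GD14 in whole testis).
#' @param contamination Fraction in `[0, 0.5)` of off-target cell admixture
#'   in each sorted fraction; admixture mixes linear-scale signals.
#' @param dbp_rat_suppression Linear fold (in `(0,1)`) applied to Leydig
#'   markers in rat DBP-exposed arms only.
#' @param replicate_sd Replicate noise SD, log2 units.
#' @param replicates_per_group Arrays per group.
#' @param platform_absent_fraction Fraction of genes masked off each
#'   3' platform (never planted markers unless `allow_marker_masking`).
#' @param seed Master integer seed; per-dataset substreams are derived from
#'   it so each dataset can be regenerated independently.
#' @param allow_marker_masking Allow planted markers to be masked off
#'   3' platforms (default FALSE).
#' @return An object of class `generator_config` (a validated list).
#' @seealso [default_paper_config()], [generate_study()]
#' @export
generator_config <- function(n_genes = 2000,
                             n_leydig_markers = 12,
                             n_sertoli_markers = 17,
                             n_gonocyte_markers = 135,
                             background_mean = 6,
                             background_sd = 0.8,
                             marker_high_level = 10,
                             leydig_gd_effect = 8,
                             contamination = 0.1,
                             dbp_rat_suppression = 0.3,
                             replicate_sd = 0.25,
                             replicates_per_group = 3,
                             platform_absent_fraction = 0.1,
                             seed = 101,
                             allow_marker_masking = FALSE) {
  cfg <- list(n_genes = n_genes,
              n_leydig_markers = n_leydig_markers,
              n_sertoli_markers = n_sertoli_markers,
              n_gonocyte_markers = n_gonocyte_markers,
              background_mean = background_mean,
              background_sd = background_sd,
              marker_high_level = marker_high_level,
              leydig_gd_effect = leydig_gd_effect,
              contamination = contamination,
              dbp_rat_suppression = dbp_rat_suppression,
              replicate_sd = replicate_sd,
              replicates_per_group = replicates_per_group,
              platform_absent_fraction = platform_absent_fraction,
              seed = seed,
              allow_marker_masking = isTRUE(allow_marker_masking))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid generator config field `", field, "`: ", msg,
                  call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$n_genes) && cfg$n_genes >= 1, "n_genes", "must be >= 1")
  for (f in c("n_leydig_markers", "n_sertoli_markers", "n_gonocyte_markers"))
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, f, "must be >= 0")
  n_markers <- cfg$n_leydig_markers + cfg$n_sertoli_markers +
    cfg$n_gonocyte_markers
  chk(n_markers <= cfg$n_genes, "n_genes",
      "marker counts must sum to at most n_genes")
  chk(num1(cfg$background_sd) && cfg$background_sd > 0,
      "background_sd", "must be > 0")
  chk(num1(cfg$replicate_sd) && cfg$replicate_sd > 0,
      "replicate_sd", "must be > 0")
  chk(num1(cfg$contamination) && cfg$contamination >= 0 &&
        cfg$contamination < 0.5, "contamination", "must be in [0, 0.5)")
  chk(num1(cfg$dbp_rat_suppression) && cfg$dbp_rat_suppression > 0 &&
        cfg$dbp_rat_suppression < 1, "dbp_rat_suppression",
      "must be in (0, 1)")
  chk(num1(cfg$leydig_gd_effect) && cfg$leydig_gd_effect > 0,
      "leydig_gd_effect", "must be > 0")
  chk(num1(cfg$replicates_per_group) && cfg$replicates_per_group >= 2,
      "replicates_per_group", "must be >= 2")
  chk(num1(cfg$platform_absent_fraction) &&
        cfg$platform_absent_fraction >= 0 && cfg$platform_absent_fraction < 1,
      "platform_absent_fraction", "must be in [0, 1)")
  chk(num1(cfg$seed) && cfg$seed == round(cfg$seed), "seed",
      "must be an integer")
  invisible(cfg)
}

#' Study-scale default configuration
#'
#' The configuration matching the study conditions the screen emulates:
#' 28,000 genes with 12 planted Leydig, 17 Sertoli and 135 gonocyte markers;
#' background linear signal below the 110 signal floor and marker peaks
#' above the 200 signal ceiling; three replicates per group; modest (10%)
#' sorted-fraction contamination.
#'
#' @return A `generator_config`.
#' @export
default_paper_config <- function() {
  generator_config(n_genes = 28000,
                   n_leydig_markers = 12,
                   n_sertoli_markers = 17,
                   n_gonocyte_markers = 135,
                   background_mean = 6,      # 2^6 = 64 < 110
                   background_sd = 0.8,
                   marker_high_level = 10,   # 2^10 = 1024 > 200
                   leydig_gd_effect = 8,
                   contamination = 0.1,
                   dbp_rat_suppression = 0.3,
                   replicate_sd = 0.25,
                   replicates_per_group = 3,
                   platform_absent_fraction = 0.1,
                   seed = 101)
}

# deterministic substream seed below 2^31, one per dataset index
substream_seed <- function(seed, index) {
  (abs(seed) * 1009L + index * 9973L) %% 2147483647L
}

# log2 expected "pure" profile of every gene in one cell fraction.
# ages: Leydig induction is linear in log2 signal from GD11 to GD13
# (sorted cells / whole testis reaches peak at GD14).
pure_profile <- function(genes, classes, baseline, cfg, fraction, gonad,
                         gestational_day) {
  prof <- baseline
  if (gonad == "ovary") return(prof)  # planted testis programs absent in ovary
  eff <- log2(cfg$leydig_gd_effect)
  if (fraction == "Mafb+") {
    ley <- classes == "leydig"
    frac_of_peak <- min(max((gestational_day - 11) / 2, 0), 1)
    prof[ley] <- cfg$marker_high_level - eff * (1 - frac_of_peak)
  } else if (fraction == "Sox9+") {
    prof[classes == "sertoli"] <- cfg$marker_high_level
  } else if (fraction == "Pou5f1+") {
    prof[classes == "gonocyte"] <- cfg$marker_high_level
  } else if (fraction == "whole") {
    ley <- classes == "leydig"
    frac_of_peak <- min(max((gestational_day - 11) / 3, 0), 1)
    prof[ley] <- cfg$marker_high_level - eff * (1 - frac_of_peak)
    prof[classes == "sertoli"] <- cfg$marker_high_level
    prof[classes == "gonocyte"] <- cfg$marker_high_level
  }
  prof
}

# expected linear signal in a sorted fraction after cell admixture:
# (1 - c) * own profile + c * mean of the two other fractions' profiles
mixed_linear <- function(genes, classes, baseline, cfg, fraction, gonad,
                         gestational_day) {
  fracs <- c("Mafb+", "Sox9+", "Pou5f1+")
  own <- 2^pure_profile(genes, classes, baseline, cfg, fraction, gonad,
                        gestational_day)
  if (!fraction %in% fracs || cfg$contamination == 0) return(own)
  others <- setdiff(fracs, fraction)
  other_lin <- vapply(others, function(f)
    2^pure_profile(genes, classes, baseline, cfg, f, gonad, gestational_day),
    numeric(length(genes)))
  (1 - cfg$contamination) * own + cfg$contamination * rowMeans(other_lin)
}

make_sheet <- function(groups, cfg) {
  rows <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, , drop = FALSE]
    n <- if (!is.null(g$n) && !is.na(g$n)) g$n else cfg$replicates_per_group
    data.frame(g[rep(1, n), setdiff(names(g), "n"), drop = FALSE],
               replicate = seq_len(n), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  rows$sample_id <- paste0(rows$group_id, "_r", rows$replicate)
  rows$group_id <- NULL
  rows[, c("sample_id", setdiff(names(rows), "sample_id"))]
}

# one synthetic dataset: expected log2 per group + replicate noise -> linear
simulate_dataset <- function(genes, classes, baseline, cfg, platform,
                             species, tissue, groups, sub_seed,
                             keep_genes = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sub_seed)
  sheet0 <- make_sheet(groups, cfg)
  expected <- vapply(seq_len(nrow(sheet0)), function(j) {
    row <- sheet0[j, ]
    if (row$fraction == "whole") {
      lin <- 2^pure_profile(genes, classes, baseline, cfg, "whole", row$gonad,
                            row$gestational_day)
    } else {
      lin <- mixed_linear(genes, classes, baseline, cfg, row$fraction,
                          row$gonad, row$gestational_day)
    }
    if (row$exposure == "DBP" && species == "rat") {
      lin[classes == "leydig"] <- lin[classes == "leydig"] *
        cfg$dbp_rat_suppression
    }
    log2(lin)
  }, numeric(length(genes)))
  noise <- matrix(stats::rnorm(length(expected), sd = cfg$replicate_sd),
                  nrow = nrow(expected))
  m <- 2^(expected + noise)
  dimnames(m) <- list(genes, sheet0$sample_id)
  sheet <- data.frame(sample_id = sheet0$sample_id, species = species,
                      tissue = tissue, fraction = sheet0$fraction,
                      gonad = sheet0$gonad,
                      gestational_day = sheet0$gestational_day,
                      exposure = sheet0$exposure, arm = sheet0$arm,
                      replicate = sheet0$replicate,
                      stringsAsFactors = FALSE)
  if (!is.null(keep_genes)) m <- m[keep_genes, , drop = FALSE]
  expression_dataset(m, sheet, platform, "linear")
}

#' Generate the full synthetic study
#'
#' Emits the nine dataset types of the study design: mouse Mafb+ testis
#' cells at GD11/12/13, Sox9+ and Pou5f1+ testis cells and Mafb+ ovary cells
#' at GD13 (all on the sorted-cell ST platform); whole mouse testis at
#' GD11/12/14; mouse DBP exposure (acute and subchronic) and rat DBP
#' exposure (acute arms at 1/3/6/18 h and subchronic) with vehicle controls
#' (3' platforms). Leydig markers are induced from GD11 to GD13 in Mafb+
#' cells, rise to GD14 in whole testis, are suppressed in rat (not mouse)
#' DBP arms, and are testis-specific. Each sorted fraction's expected
#' linear signal is `(1 - contamination) * own profile + contamination *`
#' mean of the other fractions' profiles. Gaussian log2 replicate noise is
#' added and matrices are emitted on the linear scale.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_study`: list with `datasets` (named
#'   list of `expression_dataset`), `annotation` (a [gene_annotation()] with
#'   per-platform presence flags), `truth` (planted classes, configured fold
#'   effects per contrast, contamination, seed) and `config`.
#' @examples
#' study <- generate_study(generator_config(n_genes = 300, seed = 1))
#' names(study$datasets)
#' @export
generate_study <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  validate_generator_config(config)
  cfg <- config
  n <- cfg$n_genes
  classes <- rep("none", n)
  i <- 1
  mk <- function(k, cls, prefix) {
    if (k > 0) {
      classes[i:(i + k - 1)] <<- cls
      i <<- i + k
    }
  }
  mk(cfg$n_leydig_markers, "leydig")
  mk(cfg$n_sertoli_markers, "sertoli")
  mk(cfg$n_gonocyte_markers, "gonocyte")
  genes <- character(n)
  genes[classes == "leydig"] <- sprintf("LEY%04d", seq_len(cfg$n_leydig_markers))
  genes[classes == "sertoli"] <- sprintf("SER%04d", seq_len(cfg$n_sertoli_markers))
  genes[classes == "gonocyte"] <- sprintf("GON%04d", seq_len(cfg$n_gonocyte_markers))
  genes[classes == "none"] <- sprintf("BKG%05d", seq_len(sum(classes == "none")))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  baseline <- stats::rnorm(n, cfg$background_mean, cfg$background_sd)
  names(baseline) <- genes

  # per-3'-platform absence masks
  platforms_3p <- c("mouse430_2", "rat230a", "rat230_2")
  maskable <- if (cfg$allow_marker_masking) genes else genes[classes == "none"]
  n_mask <- floor(cfg$platform_absent_fraction * n)
  masks <- lapply(platforms_3p, function(pf) {
    absent <- sample(maskable, min(n_mask, length(maskable)))
    !genes %in% absent
  })
  names(masks) <- platforms_3p
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  grp <- function(group_id, fraction, gonad, gd, exposure = "none",
                  arm = "", n = NA)
    data.frame(group_id = group_id, fraction = fraction, gonad = gonad,
               gestational_day = gd, exposure = exposure, arm = arm, n = n,
               stringsAsFactors = FALSE)

  specs <- list(
    mafb_testis = list(platform = "mogene_1_0_st", species = "mouse",
      tissue = "sorted",
      groups = rbind(grp("mafb_t_gd11", "Mafb+", "testis", 11),
                     grp("mafb_t_gd12", "Mafb+", "testis", 12),
                     grp("mafb_t_gd13", "Mafb+", "testis", 13))),
    sox9_testis = list(platform = "mogene_1_0_st", species = "mouse",
      tissue = "sorted",
      groups = grp("sox9_t_gd13", "Sox9+", "testis", 13)),
    pou5f1_testis = list(platform = "mogene_1_0_st", species = "mouse",
      tissue = "sorted",
      groups = grp("pou5f1_t_gd13", "Pou5f1+", "testis", 13)),
    mafb_ovary = list(platform = "mogene_1_0_st", species = "mouse",
      tissue = "sorted",
      groups = grp("mafb_o_gd13", "Mafb+", "ovary", 13)),
    whole_testis = list(platform = "mouse430_2", species = "mouse",
      tissue = "whole",
      groups = rbind(grp("wt_gd11", "whole", "testis", 11),
                     grp("wt_gd12", "whole", "testis", 12),
                     grp("wt_gd14", "whole", "testis", 14))),
    mouse_dbp_acute = list(platform = "mouse430_2", species = "mouse",
      tissue = "whole",
      groups = rbind(grp("m_ac_veh", "whole", "testis", 18, "vehicle", "acute"),
                     grp("m_ac_dbp", "whole", "testis", 18, "DBP", "acute"))),
    mouse_dbp_subchronic = list(platform = "mouse430_2", species = "mouse",
      tissue = "whole",
      groups = rbind(grp("m_sc_veh", "whole", "testis", 17, "vehicle", "subchronic"),
                     grp("m_sc_dbp", "whole", "testis", 17, "DBP", "subchronic"))),
    rat_dbp_acute = list(platform = "rat230a", species = "rat",
      tissue = "whole",
      groups = rbind(grp("r_ac_veh", "whole", "testis", 19, "vehicle", "acute_veh"),
                     grp("r_ac_1h", "whole", "testis", 19, "DBP", "1h"),
                     grp("r_ac_3h", "whole", "testis", 19, "DBP", "3h"),
                     grp("r_ac_6h", "whole", "testis", 19, "DBP", "6h"),
                     grp("r_ac_18h", "whole", "testis", 19, "DBP", "18h"))),
    rat_dbp_subchronic = list(platform = "rat230_2", species = "rat",
      tissue = "whole",
      groups = rbind(grp("r_sc_veh", "whole", "testis", 19, "vehicle", "subchronic"),
                     grp("r_sc_dbp", "whole", "testis", 19, "DBP", "subchronic")))
  )

  datasets <- vector("list", length(specs))
  names(datasets) <- names(specs)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    keep <- if (sp$platform %in% platforms_3p) genes[masks[[sp$platform]]]
            else NULL
    datasets[[k]] <- simulate_dataset(genes, classes, baseline, cfg,
                                      sp$platform, sp$species, sp$tissue,
                                      sp$groups,
                                      substream_seed(cfg$seed, k),
                                      keep_genes = keep)
  }

  presence <- c(list(mogene_1_0_st = rep(TRUE, n)), masks)
  annotation <- gene_annotation(genes, classes, presence)

  truth <- list(
    classes = stats::setNames(classes, genes),
    effects = list(
      mafb_gd13_vs_gd11 = stats::setNames(
        ifelse(classes == "leydig", cfg$leydig_gd_effect, 1), genes),
      whole_gd14_vs_gd11 = stats::setNames(
        ifelse(classes == "leydig", cfg$leydig_gd_effect, 1), genes),
      rat_dbp_vs_vehicle = stats::setNames(
        ifelse(classes == "leydig", cfg$dbp_rat_suppression, 1), genes),
      mouse_dbp_vs_vehicle = stats::setNames(rep(1, n), genes)),
    contamination = cfg$contamination,
    seed = cfg$seed)

  structure(list(datasets = datasets, annotation = annotation,
                 truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes, %d datasets, seed %d\n",
              x$config$n_genes, length(x$datasets), x$config$seed))
  for (nm in names(x$datasets))
    cat(sprintf("  %-22s %5d genes x %2d samples [%s]\n", nm,
                nrow(x$datasets[[nm]]$signal), ncol(x$datasets[[nm]]$signal),
                x$datasets[[nm]]$platform))
  invisible(x)
}

#' Write a synthetic study to a directory of TSV/JSON files
#'
#' One matrix + sheet TSV pair per dataset, plus annotation TSV,
#' ground-truth TSV and the generator config as JSON.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$datasets))
    write_dataset(study$datasets[[nm]],
                  file.path(dir, paste0(nm, "_matrix.tsv")),
                  file.path(dir, paste0(nm, "_sheet.tsv")))
  write_annotation(study$annotation, file.path(dir, "annotation.tsv"))
  truth_tab <- data.frame(gene = names(study$truth$classes),
                          planted_class = unname(study$truth$classes),
                          stringsAsFactors = FALSE)
  for (ct in names(study$truth$effects))
    truth_tab[[paste0("fold_", ct)]] <- unname(study$truth$effects[[ct]])
  utils::write.table(truth_tab, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(study$config),
                       file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
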