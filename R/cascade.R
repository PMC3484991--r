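#' Cascade thresholds
#'
#' The filter constants of the candidate-gene cascade: the linear signal
#' floor a candidate must exceed in GD13 Mafb+ cells (110), the gonocyte
#' signal ceiling above which step 2 discards (200), the FDR cutoff (0.25),
#' and the expression-ratio threshold (1). All comparisons are strict.
#'
#' @param signal_floor,signal_ceiling Linear signal thresholds (> 0).
#' @param fdr_cutoff FDR q-value cutoff in (0, 1].
#' @param ratio_threshold Linear expression-ratio threshold (> 0).
#' @return A list of class `cascade_thresholds`.
#' @export
cascade_thresholds <- function(signal_floor = 110, signal_ceiling = 200,
                               fdr_cutoff = 0.25, ratio_threshold = 1) {
  stopifnot(signal_floor > 0, signal_ceiling > 0,
            fdr_cutoff > 0, fdr_cutoff <= 1, ratio_threshold > 0)
  structure(list(signal_floor = signal_floor,
                 signal_ceiling = signal_ceiling,
                 fdr_cutoff = fdr_cutoff,
                 ratio_threshold = ratio_threshold),
            class = "cascade_thresholds")
}

de_vec <- function(de, col) stats::setNames(de[[col]], de$gene)

# presence of `genes` on `platform` per annotation; carried = !present
presence_for <- function(annotation, platform, genes) {
  pres <- platform_presence(annotation, platform)
  miss <- setdiff(genes, names(pres))
  if (length(miss))
    stop("genes missing from annotation: ", paste(utils::head(miss, 5),
                                                  collapse = ", "))
  pres[genes]
}

# fold/q for `genes` from one contrast; NA where platform-absent
contrast_values <- function(de, annotation, genes, step, name) {
  platform <- attr(de, "platform")
  if (is.null(platform))
    stop("DE table `", name, "` carries no platform attribute (step ", step, ")")
  pres <- presence_for(annotation, platform, genes)
  fold <- de_vec(de, "fold")[genes]
  q <- de_vec(de, "q")[genes]
  missing_but_present <- pres & (is.na(fold) | is.na(q))
  if (any(missing_but_present))
    stop("step ", step, ": contrast `", name, "` lacks rows for genes the ",
         "annotation marks present on ", platform, ": ",
         paste(utils::head(genes[missing_but_present], 5), collapse = ", "))
  fold[!pres] <- NA_real_
  q[!pres] <- NA_real_
  list(fold = fold, q = q, present = pres)
}

#' Run the seven-step candidate-gene cascade
#'
#' Applies, in order: (1) retain genes with GD13 Mafb+ linear signal above
#' the floor, GD13-vs-GD11 fold above 1 and q below the FDR cutoff;
#' (2) discard genes with GD13 Pou5f1+ signal above the ceiling; (3) cull
#' genes whose Sox9+/Mafb+ signal ratio exceeds 1; (4) retain genes
#' increasing in whole testis (GD14 vs GD11 or GD14 vs GD12, fold > 1,
#' q < cutoff); (5) retain genes suppressed in any rat DBP contrast
#' (fold < 1, q < cutoff); (6) cull genes suppressed in any mouse DBP
#' contrast; (7) retain genes higher in GD13 testis than ovary Mafb+ cells
#' (fold > 1, q < cutoff). At steps 4-6, genes absent from the relevant
#' 3' platform(s) are carried to the next step unfiltered. All threshold
#' comparisons are strict.
#'
#' @param de Named list of `de_result` tables:
#'   `mafb_gd13_vs_gd11`, `whole_gd14_vs_gd11`, `whole_gd14_vs_gd12`,
#'   `rat_dbp` (list of tables, one per exposure contrast), `mouse_dbp`
#'   (list), `testis_vs_ovary`. Each table needs `gene`, `fold`, `q`
#'   columns and a `platform` attribute (see [read_de_table()]).
#' @param signals List of named linear-signal vectors `mafb_gd13`,
#'   `pou5f1_gd13`, `sox9_gd13` (see [group_mean_linear()]).
#' @param annotation A [gene_annotation()] with per-platform presence flags.
#' @param thresholds A [cascade_thresholds()].
#' @return An object of class `cascade_result`: per-step decision tables
#'   (`steps`), per-step counts (`step_counts`), the final `candidates`
#'   data.frame (gene, GD11 to GD13 Mafb+ linear fold, descending), the
#'   thresholds, and the starting `universe`.
#' @export
run_cascade <- function(de, signals, annotation,
                        thresholds = cascade_thresholds()) {
  th <- thresholds
  stopifnot(inherits(th, "cascade_thresholds"))
  required <- c("mafb_gd13_vs_gd11", "whole_gd14_vs_gd11",
                "whole_gd14_vs_gd12", "rat_dbp", "mouse_dbp",
                "testis_vs_ovary")
  step_of <- c(mafb_gd13_vs_gd11 = 1, whole_gd14_vs_gd11 = 4,
               whole_gd14_vs_gd12 = 4, rat_dbp = 5, mouse_dbp = 6,
               testis_vs_ovary = 7)
  for (nm in required)
    if (is.null(de[[nm]]))
      stop("missing contrast `", nm, "` required at step ", step_of[[nm]])
  for (nm in c("mafb_gd13", "pou5f1_gd13", "sox9_gd13"))
    if (is.null(signals[[nm]]))
      stop("missing signal vector `", nm, "`")

  universe <- sort(de$mafb_gd13_vs_gd11$gene)
  for (nm in c("mafb_gd13", "pou5f1_gd13", "sox9_gd13")) {
    miss <- setdiff(universe, names(signals[[nm]]))
    if (length(miss))
      stop("signal vector `", nm, "` lacks genes: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }

  steps <- vector("list", 7)
  names(steps) <- paste0("step", 1:7)
  active <- universe

  record <- function(i, tab) steps[[i]] <<- tab

  # --- step 1: retain on Mafb+ GD13 signal, induction and FDR -------------
  sig <- signals$mafb_gd13[active]
  fold <- de_vec(de$mafb_gd13_vs_gd11, "fold")[active]
  q <- de_vec(de$mafb_gd13_vs_gd11, "q")[active]
  if (anyNA(fold) || anyNA(q))
    stop("step 1: Mafb+ contrast lacks rows for genes in the universe")
  keep <- sig > th$signal_floor & fold > th$ratio_threshold & q < th$fdr_cutoff
  record(1, data.frame(gene = active, signal = sig, fold = fold, q = q,
                       verdict = as.character(ifelse(keep, "retained", "culled")),
                       rule = rep(sprintf("retain: signal>%g & fold>%g & q<%g",
                                          th$signal_floor, th$ratio_threshold,
                                          th$fdr_cutoff), length(active)),
                       row.names = NULL, stringsAsFactors = FALSE))
  active <- active[keep]

  # --- step 2: discard on Pou5f1+ (gonocyte) signal -----------------------
  sig <- signals$pou5f1_gd13[active]
  keep <- !(sig > th$signal_ceiling)
  record(2, data.frame(gene = active, signal = sig,
                       verdict = as.character(ifelse(keep, "retained", "culled")),
                       rule = rep(sprintf("discard: Pou5f1+ signal>%g",
                                          th$signal_ceiling), length(active)),
                       row.names = NULL, stringsAsFactors = FALSE))
  active <- active[keep]

  # --- step 3: cull on Sox9+/Mafb+ ratio ----------------------------------
  ratio <- signals$sox9_gd13[active] / signals$mafb_gd13[active]
  keep <- !(ratio > th$ratio_threshold)
  record(3, data.frame(gene = active, ratio = ratio,
                       verdict = as.character(ifelse(keep, "retained", "culled")),
                       rule = rep(sprintf("cull: Sox9+/Mafb+ ratio>%g",
                                          th$ratio_threshold), length(active)),
                       row.names = NULL, stringsAsFactors = FALSE))
  active <- active[keep]

  # --- step 4: retain on whole-testis induction (GD14 vs GD11 OR GD12) ----
  v11 <- contrast_values(de$whole_gd14_vs_gd11, annotation, active, 4,
                         "whole_gd14_vs_gd11")
  v12 <- contrast_values(de$whole_gd14_vs_gd12, annotation, active, 4,
                         "whole_gd14_vs_gd12")
  present <- v11$present | v12$present
  ok11 <- !is.na(v11$fold) & v11$fold > th$ratio_threshold & v11$q < th$fdr_cutoff
  ok12 <- !is.na(v12$fold) & v12$fold > th$ratio_threshold & v12$q < th$fdr_cutoff
  verdict <- ifelse(!present, "carried",
                    ifelse(ok11 | ok12, "retained", "culled"))
  record(4, data.frame(gene = active,
                       fold_gd14_vs_gd11 = v11$fold, q_gd14_vs_gd11 = v11$q,
                       fold_gd14_vs_gd12 = v12$fold, q_gd14_vs_gd12 = v12$q,
                       verdict = verdict,
                       rule = rep(sprintf("retain: (fold>%g & q<%g) in GD14 vs GD11 or GD12; absent => carry",
                                          th$ratio_threshold, th$fdr_cutoff), length(active)),
                       row.names = NULL, stringsAsFactors = FALSE))
  active <- active[verdict != "culled"]

  # --- steps 5/6: species-differential DBP response -----------------------
  dbp_step <- function(i, tables, mode) {
    if (!length(tables)) stop("step ", i, ": no DBP contrasts supplied")
    vals <- lapply(seq_along(tables), function(k)
      contrast_values(tables[[k]], annotation, active, i,
                      paste0(names(tables)[k])))
    present_any <- Reduce(`|`, lapply(vals, `[[`, "present"))
    hit_any <- Reduce(`|`, lapply(vals, function(v)
      !is.na(v$fold) & v$fold < th$ratio_threshold & v$q < th$fdr_cutoff))
    verdict <- if (mode == "retain")
      ifelse(!present_any, "carried", ifelse(hit_any, "retained", "culled"))
    else
      ifelse(!present_any, "carried", ifelse(hit_any, "culled", "retained"))
    min_fold <- do.call(pmin, c(lapply(vals, `[[`, "fold"), na.rm = TRUE))
    min_q <- do.call(pmin, c(lapply(vals, `[[`, "q"), na.rm = TRUE))
    tab <- data.frame(gene = active, min_fold = min_fold, min_q = min_q,
                      verdict = verdict,
                      rule = rep(sprintf("%s: any contrast fold<%g & q<%g; absent => carry",
                                         if (mode == "retain") "retain" else "cull",
                                         th$ratio_threshold, th$fdr_cutoff), length(active)),
                      row.names = NULL, stringsAsFactors = FALSE)
    record(i, tab)
    verdict
  }
  verdict <- dbp_step(5, de$rat_dbp, "retain")
  active <- active[verdict != "culled"]
  verdict <- dbp_step(6, de$mouse_dbp, "cull")
  active <- active[verdict != "culled"]

  # --- step 7: testis over ovary in Mafb+ cells ---------------------------
  fold <- de_vec(de$testis_vs_ovary, "fold")[active]
  q <- de_vec(de$testis_vs_ovary, "q")[active]
  if (anyNA(fold) || anyNA(q))
    stop("step 7: testis_vs_ovary contrast lacks rows for surviving genes")
  keep <- fold > th$ratio_threshold & q < th$fdr_cutoff
  record(7, data.frame(gene = active, fold = fold, q = q,
                       verdict = as.character(ifelse(keep, "retained", "culled")),
                       rule = rep(sprintf("retain: testis/ovary fold>%g & q<%g",
                                          th$ratio_threshold, th$fdr_cutoff), length(active)),
                       row.names = NULL, stringsAsFactors = FALSE))
  active <- active[keep]

  cand_fold <- de_vec(de$mafb_gd13_vs_gd11, "fold")[active]
  candidates <- data.frame(gene = active, fold = unname(cand_fold),
                           row.names = NULL, stringsAsFactors = FALSE)
  candidates <- candidates[order(-candidates$fold, candidates$gene), ,
                           drop = FALSE]
  rownames(candidates) <- NULL

  counts <- do.call(rbind, lapply(1:7, function(i) {
    tab <- steps[[i]]
    data.frame(step = i, input = nrow(tab),
               retained = sum(tab$verdict == "retained"),
               culled = sum(tab$verdict == "culled"),
               carried = sum(tab$verdict == "carried"))
  }))

  structure(list(steps = steps, step_counts = counts,
                 candidates = candidates, thresholds = th,
                 universe = universe),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("cascade_result: %d genes in, %d candidates out\n",
              length(x$universe), nrow(x$candidates)))
  print(x$step_counts, row.names = FALSE)
  invisible(x)
}

#' Candidate fold-change table
#'
#' Final candidates with the GD11 to GD13 Mafb+ linear fold change,
#' descending, reported to one decimal.
#'
#' @param result A `cascade_result`.
#' @return `data.frame` with columns `gene`, `fold`.
#' @export
fold_change_table <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  out <- result$candidates
  out$fold <- round(out$fold, 1)
  out
}

#' Per-gene audit trail through the cascade
#'
#' Every step's verdict for one gene, with the numeric values that were
#' compared to the thresholds, until the step (if any) at which the gene
#' was culled.
#'
#' @param result A `cascade_result`.
#' @param gene Gene symbol.
#' @return `data.frame` with one row per step the gene reached: `step`,
#'   `verdict`, `rule`, `values` (compact `name=value` string).
#' @export
audit_trail <- function(result, gene) {
  stopifnot(inherits(result, "cascade_result"))
  if (!gene %in% result$universe)
    stop("unknown gene: ", gene)
  rows <- lapply(1:7, function(i) {
    tab <- result$steps[[i]]
    r <- tab[tab$gene == gene, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    vals <- setdiff(names(r), c("gene", "verdict", "rule"))
    data.frame(step = i, verdict = r$verdict, rule = r$rule,
               values = paste(sprintf("%s=%.6g", vals,
                                      unlist(r[1, vals])), collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
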