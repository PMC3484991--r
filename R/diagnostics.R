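#' Sorted-fraction contamination profile
#'
#' For each sorted fraction, the mean linear-scale signal of each known
#' marker class, compared against that fraction's background distribution
#' (non-marker genes). A class is flagged `above_background` when its mean
#' exceeds the background mean + 2 background SDs — off-target classes
#' above background indicate admixture of other cell types in the isolate.
#' Signal magnitudes are compared on the linear scale, the scale on which
#' array signal thresholds are stated.
#'
#' @param datasets Named list of log2 `expression_dataset` objects, one per
#'   sorted fraction (names used as fraction labels), or a single dataset
#'   whose sheet has a `fraction` column.
#' @param annotation A [gene_annotation()] with `known_class` populated.
#' @return `data.frame` of class `contamination_profile`: one row per
#'   fraction x marker class with `mean_signal`, `sd_signal`,
#'   `background_mean`, `background_sd`, `above_background`.
#' @export
contamination_profile <- function(datasets, annotation) {
  if (inherits(datasets, "expression_dataset")) {
    ds <- datasets
    fracs <- unique(ds$sheet$fraction)
    datasets <- lapply(fracs, function(f) {
      ids <- ds$sheet$sample_id[ds$sheet$fraction == f]
      expression_dataset(ds$signal[, ids, drop = FALSE],
                         ds$sheet[ds$sheet$sample_id %in% ids, ],
                         ds$platform, ds$scale)
    })
    names(datasets) <- fracs
  }
  classes <- c("leydig", "sertoli", "gonocyte")
  cls_map <- stats::setNames(annotation$known_class, annotation$gene)
  for (cl in classes)
    if (!any(cls_map == cl))
      stop("annotation has no markers of class `", cl, "`")
  rows <- list()
  for (frac in names(datasets)) {
    ds <- datasets[[frac]]
    m <- ds$signal
    if (ds$scale == "log2") m <- 2^m
    gene_means <- rowMeans(m)
    gcls <- cls_map[rownames(m)]
    bg <- gene_means[gcls == "none"]
    if (!length(bg)) stop("fraction `", frac, "` has no background genes")
    bg_mean <- mean(bg); bg_sd <- stats::sd(bg)
    for (cl in classes) {
      v <- gene_means[gcls == cl]
      if (!length(v)) stop("fraction `", frac,
                           "` has no markers of class `", cl, "`")
      rows[[length(rows) + 1]] <- data.frame(
        fraction = frac, class = cl,
        mean_signal = mean(v), sd_signal = stats::sd(v),
        background_mean = bg_mean, background_sd = bg_sd,
        above_background = mean(v) > bg_mean + 2 * bg_sd,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contamination_profile", "data.frame")
  out
}

#' Exact hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= overlap_k)` of drawing at least
#' `overlap_k` known genes when `selected_n` genes are sampled without
#' replacement from a universe of `universe_n` genes containing `known_k`
#' known genes.
#'
#' @param universe_n,known_k,selected_n,overlap_k Non-negative counts with
#'   `known_k <= universe_n`, `selected_n <= universe_n`,
#'   `overlap_k <= min(known_k, selected_n)`.
#' @return Exact tail p-value.
#' @examples
#' hypergeom_enrichment(20, 5, 5, 5)   # 1 / choose(20, 5)
#' @export
hypergeom_enrichment <- function(universe_n, known_k, selected_n, overlap_k) {
  for (v in list(universe_n, known_k, selected_n, overlap_k))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop("all counts must be single non-negative integers")
  if (known_k > universe_n || selected_n > universe_n)
    stop("known_k and selected_n must not exceed universe_n")
  if (overlap_k > min(known_k, selected_n))
    stop("overlap_k exceeds min(known_k, selected_n)")
  stats::phyper(overlap_k - 1, known_k, universe_n - known_k, selected_n,
                lower.tail = FALSE)
}

#' Known-marker recovery report
#'
#' Counts of known Leydig, Sertoli and gonocyte genes in the cascade's
#' starting universe and in the final candidate list, with the exact
#' hypergeometric enrichment p-value for the Leydig set.
#'
#' @param result A `cascade_result`.
#' @param annotation A [gene_annotation()].
#' @return List of class `recovery_report`: `counts` data.frame (class,
#'   start, final), `universe_n`, `candidates_n`, `enrichment_p` (Leydig).
#' @export
recovery_report <- function(result, annotation) {
  stopifnot(inherits(result, "cascade_result"))
  cls_map <- stats::setNames(annotation$known_class, annotation$gene)
  start_cls <- cls_map[result$universe]
  final_cls <- cls_map[result$candidates$gene]
  classes <- c("leydig", "sertoli", "gonocyte")
  counts <- data.frame(class = classes,
                       start = vapply(classes, function(cl)
                         sum(start_cls == cl, na.rm = TRUE), 0L),
                       final = vapply(classes, function(cl)
                         sum(final_cls == cl, na.rm = TRUE), 0L),
                       stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  known_leydig <- counts$start[counts$class == "leydig"]
  overlap <- counts$final[counts$class == "leydig"]
  p <- if (known_leydig == 0) 1
       else hypergeom_enrichment(length(result$universe), known_leydig,
                                 nrow(result$candidates), overlap)
  structure(list(counts = counts,
                 universe_n = length(result$universe),
                 candidates_n = nrow(result$candidates),
                 enrichment_p = p),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: %d-gene universe, %d candidates\n",
              x$universe_n, x$candidates_n))
  print(x$counts, row.names = FALSE)
  cat(sprintf("Leydig enrichment p = %.3g\n", x$enrichment_p))
  invisible(x)
}
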