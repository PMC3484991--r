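#' Expression dataset container
#'
#' Bundles a gene-by-sample signal matrix with its sample sheet and platform
#' identity. Signals are either linear-scale (raw Affymetrix-style
#' magnitudes, strictly positive) or log2, recorded in the `scale` tag so
#' every downstream stage knows what it is consuming.
#'
#' @param signal Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param sheet `data.frame` describing each array; must contain a
#'   `sample_id` column covering every matrix column, and typically
#'   `species`, `tissue`, `fraction`, `gonad`, `gestational_day`,
#'   `exposure`, `arm`, `replicate`.
#' @param platform Platform identifier string (e.g. `"mogene_1_0_st"`,
#'   `"mouse430_2"`, `"rat230a"`, `"rat230_2"`).
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `signal`, `sheet`, `platform`, `scale`.
#' @examples
#' m <- matrix(2^rnorm(6, 8), 3, 2,
#'             dimnames = list(c("CYP17A1", "STAR", "ACTB"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), gestational_day = 13)
#' ds <- expression_dataset(m, sheet, platform = "mogene_1_0_st",
#'                          scale = "linear")
#' @export
expression_dataset <- function(signal, sheet, platform, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix")
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("`signal` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(signal)))
    stop("duplicate gene symbols in signal matrix: ",
         paste(unique(rownames(signal)[duplicated(rownames(signal))]),
               collapse = ", "))
  if (!all(is.finite(signal)))
    stop("non-finite signal values at ",
         sum(!is.finite(signal)), " cells")
  if (scale == "linear" && any(signal <= 0))
    stop("linear-scale signals must be strictly positive; ",
         sum(signal <= 0), " offending cells")
  if (!is.data.frame(sheet) || is.null(sheet$sample_id))
    stop("`sheet` must be a data.frame with a sample_id column")
  missing_ids <- setdiff(colnames(signal), sheet$sample_id)
  if (length(missing_ids))
    stop("sample ids in matrix but not in sheet: ",
         paste(missing_ids, collapse = ", "))
  sheet <- sheet[match(colnames(signal), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  structure(list(signal = signal, sheet = sheet,
                 platform = as.character(platform), scale = scale),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples [%s, %s scale]\n",
              nrow(x$signal), ncol(x$signal), x$platform, x$scale))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$signal)

#' Read an expression dataset from TSV files
#'
#' The matrix file is tab-delimited with a first column named `gene` and one
#' column per sample; the sheet file is tab-delimited with one row per
#' sample. Validation mirrors [expression_dataset()].
#'
#' @param matrix_path,sheet_path Paths to the TSV files.
#' @inheritParams expression_dataset
#' @return An `expression_dataset`.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(matrix_path, sheet_path, platform,
                         scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  for (p in c(matrix_path, sheet_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene")
    stop("matrix file must have a first column named 'gene': ", matrix_path)
  if (anyDuplicated(tab$gene))
    stop("duplicate gene symbols in ", matrix_path, ": ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  sheet <- utils::read.delim(sheet_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  expression_dataset(m, sheet, platform, scale)
}

#' Write an expression dataset to TSV files
#'
#' @param ds An `expression_dataset`.
#' @param matrix_path,sheet_path Output paths.
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, matrix_path, sheet_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  tab <- data.frame(gene = rownames(ds$signal), ds$signal,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Gene annotation table
#'
#' One row per gene: harmonized symbol, known-marker class, and one logical
#' presence column per platform (`present_<platform>`). Symbols are
#' upper-cased so that rat and mouse orthologs sharing a symbol collapse to
#' one key.
#'
#' @param gene Character vector of gene symbols.
#' @param known_class Character vector in
#'   `c("leydig", "sertoli", "gonocyte", "none")`.
#' @param presence Named list of logical vectors (one per platform), or NULL.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene, known_class = "none", presence = NULL) {
  gene <- toupper(as.character(gene))
  if (anyDuplicated(gene))
    stop("duplicate gene symbols after case normalization: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  known_class <- rep_len(as.character(known_class), length(gene))
  bad <- !known_class %in% c("leydig", "sertoli", "gonocyte", "none")
  if (any(bad)) stop("invalid known_class values: ",
                     paste(unique(known_class[bad]), collapse = ", "))
  ann <- data.frame(gene = gene, known_class = known_class,
                    stringsAsFactors = FALSE)
  if (!is.null(presence)) {
    for (pf in names(presence)) {
      v <- presence[[pf]]
      stopifnot(is.logical(v), length(v) == length(gene))
      ann[[paste0("present_", pf)]] <- v
    }
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' @rdname gene_annotation
#' @param path TSV path.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  pres_cols <- grep("^present_", names(tab), value = TRUE)
  presence <- lapply(pres_cols, function(cn) as.logical(tab[[cn]]))
  names(presence) <- sub("^present_", "", pres_cols)
  gene_annotation(tab$gene, tab$known_class,
                  if (length(presence)) presence else NULL)
}

#' @rdname gene_annotation
#' @param annotation A `gene_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(annotation)
}

#' Presence flags for one platform
#'
#' @param annotation A `gene_annotation`.
#' @param platform Platform id.
#' @return Named logical vector over annotation genes. Platforms with no
#'   recorded presence column are taken as complete (all genes present).
#' @export
platform_presence <- function(annotation, platform) {
  col <- paste0("present_", platform)
  v <- if (col %in% names(annotation)) annotation[[col]]
       else rep(TRUE, nrow(annotation))
  stats::setNames(v, annotation$gene)
}

#' Harmonize gene symbols across datasets
#'
#' Upper-cases symbols (so rat `Cyp17a1` and mouse `Cyp17a1` meet at
#' `CYP17A1`), collapses genes represented by several rows to the single row
#' with the highest mean signal, checks every symbol against the annotation,
#' and records per-platform presence flags from observed membership.
#'
#' @param datasets Named list of `expression_dataset` objects.
#' @param annotation A `gene_annotation` covering the union of symbols.
#' @return List with elements `datasets` (harmonized) and `annotation`
#'   (presence flags refreshed for every platform seen).
#' @export
map_symbols <- function(datasets, annotation) {
  stopifnot(is.list(datasets), inherits(annotation, "gene_annotation"))
  harmonized <- lapply(datasets, function(ds) {
    m <- ds$signal
    rownames(m) <- toupper(rownames(m))
    if (anyDuplicated(rownames(m))) {
      means <- rowMeans(m)
      ord <- order(rownames(m), -means)   # best row first within each gene
      m <- m[ord, , drop = FALSE]
      m <- m[!duplicated(rownames(m)), , drop = FALSE]
      m <- m[order(rownames(m)), , drop = FALSE]
    }
    unknown <- setdiff(rownames(m), annotation$gene)
    if (length(unknown))
      stop("symbols not covered by annotation: ",
           paste(utils::head(unknown, 10), collapse = ", "),
           if (length(unknown) > 10) sprintf(" (+%d more)", length(unknown) - 10))
    expression_dataset(m, ds$sheet, ds$platform, ds$scale)
  })
  platforms <- unique(vapply(harmonized, `[[`, "", "platform"))
  for (pf in platforms) {
    seen <- unique(unlist(lapply(harmonized, function(ds)
      if (ds$platform == pf) rownames(ds$signal) else character(0))))
    annotation[[paste0("present_", pf)]] <- annotation$gene %in% seen
  }
  list(datasets = harmonized, annotation = annotation)
}

#' Select sample ids by sheet fields
#'
#' Convenience filter over the sample sheet: keeps samples whose sheet value
#' equals the given value for every named argument.
#'
#' @param ds An `expression_dataset`.
#' @param ... Named filters, e.g. `gestational_day = 13, fraction = "Mafb+"`.
#' @return Character vector of sample ids.
#' @export
select_samples <- function(ds, ...) {
  filters <- list(...)
  keep <- rep(TRUE, nrow(ds$sheet))
  for (nm in names(filters)) {
    if (is.null(ds$sheet[[nm]])) stop("no sheet column called ", nm)
    keep <- keep & ds$sheet[[nm]] %in% filters[[nm]]
  }
  ds$sheet$sample_id[keep]
}

#' Linear-scale group mean signals
#'
#' Arithmetic per-gene mean of linear-scale signals over the chosen samples
#' (log2 datasets are exponentiated first). This is the quantity compared
#' against the cascade's linear signal thresholds.
#'
#' @param ds An `expression_dataset`.
#' @param sample_ids Character vector of sample ids.
#' @return Named numeric vector over genes.
#' @export
group_mean_linear <- function(ds, sample_ids) {
  miss <- setdiff(sample_ids, colnames(ds$signal))
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  m <- ds$signal[, sample_ids, drop = FALSE]
  if (ds$scale == "log2") m <- 2^m
  rowMeans(m)
}
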