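#' Quantile normalization
#'
#' Forces every column onto the same distribution: the across-column mean of
#' order statistics. Ties within a column are resolved by averaging the tied
#' order-statistic means (average rank), so identical input values stay
#' identical.
#'
#' @param m Numeric matrix (genes x samples), linear or log2.
#' @return Matrix of the same shape; every column has the same sorted values.
#' @examples
#' quantile_normalize(cbind(a = c(2, 4, 6), b = c(1, 3, 5)))
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || length(m) == 0)
    stop("`m` must be a non-empty numeric matrix")
  if (!all(is.finite(m))) stop("non-finite values in matrix")
  if (ncol(m) == 1) return(m)
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)               # mean of order statistics
  out <- apply(m, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # non-integer ranks (ties) take the mean of the straddling reference values
    lo <- ref[floor(rk)]
    hi <- ref[ceiling(rk)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Flat background shift
#'
#' Subtracts a constant background floor from linear-scale signals,
#' truncating at epsilon = 1 linear unit so the subsequent log2 transform is
#' defined. A deliberate flat simplification of array background
#' correction for gene-level signal input.
#'
#' @param m Linear-scale numeric matrix.
#' @param floor Background level to subtract (linear units, >= 0).
#' @return Matrix `pmax(m - floor, 1)`.
#' @export
background_shift <- function(m, floor = 0) {
  stopifnot(is.numeric(m), floor >= 0)
  pmax(m - floor, 1)
}

#' Median polish decomposition
#'
#' Alternately sweeps row and column medians out of a log2 block until the
#' change in the median absolute residual drops below `tol` or `max_iter`
#' is reached. Used to summarize replicate probe rows per gene into
#' per-sample values `overall + col_effect`.
#'
#' @param m Numeric matrix (replicate probes x samples), log2 scale.
#' @param max_iter Maximum sweep iterations (>= 1).
#' @param tol Convergence tolerance on the median absolute residual change
#'   (log2 units, > 0).
#' @return List with `overall`, `row_effects`, `col_effects`, `residuals`,
#'   `summaries` (= overall + col_effects), `iterations`, `converged`.
#' @examples
#' median_polish(matrix(c(1, 3, 2, 4), 2, 2))
#' @export
median_polish <- function(m, max_iter = 10L, tol = 0.01) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  if (!all(is.finite(m))) stop("non-finite values in matrix")
  stopifnot(max_iter >= 1, tol > 0)
  overall <- 0
  row_eff <- numeric(nrow(m))
  col_eff <- numeric(ncol(m))
  res <- m
  prev_mad <- stats::median(abs(res))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rmed <- apply(res, 1, stats::median)
    row_eff <- row_eff + rmed
    res <- res - rmed
    cmed_of_row <- stats::median(row_eff)
    overall <- overall + cmed_of_row
    row_eff <- row_eff - cmed_of_row

    cmed <- apply(res, 2, stats::median)
    col_eff <- col_eff + cmed
    res <- sweep(res, 2, cmed)
    rmed_of_col <- stats::median(col_eff)
    overall <- overall + rmed_of_col
    col_eff <- col_eff - rmed_of_col

    mad_now <- stats::median(abs(res))
    if (abs(prev_mad - mad_now) < tol) { converged <- TRUE; break }
    prev_mad <- mad_now
  }
  names(row_eff) <- rownames(m)
  names(col_eff) <- colnames(m)
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = res, summaries = overall + col_eff,
       iterations = iter, converged = converged)
}

#' Normalize an expression dataset (simplified RMA)
#'
#' Linear-scale input passes through background shift, quantile
#' normalization across arrays, and log2 transform, in that order. When a
#' `probe_map` is supplied (gene -> several probe rows), replicate rows are
#' summarized per gene by [median_polish()]. Input already on the log2
#' scale triggers a warning and is passed through untransformed.
#'
#' @param ds An `expression_dataset`.
#' @param floor Background floor (linear units), default 0 (no shift).
#' @param quantile Apply quantile normalization (default TRUE).
#' @param probe_map Optional named factor/character vector mapping each
#'   matrix row to its gene; rows sharing a gene are median-polished into
#'   one summary row.
#' @return List with `dataset` (log2 `expression_dataset`) and `report`
#'   (per-array pre/post quartiles, floor used, polish iterations).
#' @export
normalize_dataset <- function(ds, floor = 0, quantile = TRUE,
                              probe_map = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$scale == "log2") {
    warning("dataset already log2; passing through without renormalization")
    return(list(dataset = ds,
                report = list(floor = floor, already_log2 = TRUE)))
  }
  pre <- apply(ds$signal, 2, stats::quantile, c(0.25, 0.5, 0.75))
  m <- background_shift(ds$signal, floor)
  if (quantile) m <- quantile_normalize(m)
  m <- log2(m)
  polish_iters <- NA_integer_
  if (!is.null(probe_map)) {
    stopifnot(length(probe_map) == nrow(m))
    genes <- unique(probe_map)
    iters <- integer(0)
    summ <- matrix(NA_real_, length(genes), ncol(m),
                   dimnames = list(genes, colnames(m)))
    for (g in genes) {
      block <- m[probe_map == g, , drop = FALSE]
      if (nrow(block) == 1) {
        summ[g, ] <- block
      } else {
        mp <- median_polish(block)
        summ[g, ] <- mp$summaries
        iters <- c(iters, mp$iterations)
      }
    }
    m <- summ
    polish_iters <- if (length(iters)) max(iters) else 0L
  }
  post <- apply(m, 2, stats::quantile, c(0.25, 0.5, 0.75))
  out <- expression_dataset(m, ds$sheet, ds$platform, "log2")
  list(dataset = out,
       report = list(pre_quartiles = pre, post_quartiles = post,
                     floor = floor, quantile = quantile,
                     polish_iterations = polish_iters,
                     already_log2 = FALSE))
}
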