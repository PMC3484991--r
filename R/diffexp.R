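#' Two-group per-gene fit
#'
#' Per-gene group means and pooled within-group variance for one two-group
#' contrast on a log2 dataset. The log fold change is
#' `mean(treatment) - mean(reference)`, so linear fold `2^logFC` is
#' treatment over reference (e.g. GD13 over GD11).
#'
#' @param ds A log2-scale `expression_dataset`.
#' @param reference,treatment Character vectors of sample ids (each >= 2).
#' @param contrast Optional label stored on the result.
#' @return `data.frame` of class `de_fit` with per-gene columns `gene`,
#'   `mean_ref`, `mean_trt` (log2), `mean_lin_ref`, `mean_lin_trt`
#'   (arithmetic means of linear signals), `logFC`, `fold`, `s2`
#'   (pooled variance), `df` (= n1 + n2 - 2); attributes `n_ref`, `n_trt`,
#'   `platform`, `contrast`.
#' @export
fit_two_group <- function(ds, reference, treatment, contrast = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$scale != "log2")
    stop("fit_two_group expects a log2-scale dataset; normalize first")
  for (nm in c("reference", "treatment")) {
    ids <- get(nm)
    if (length(ids) < 2)
      stop("group `", nm, "` has fewer than 2 samples")
    miss <- setdiff(ids, colnames(ds$signal))
    if (length(miss))
      stop("group `", nm, "` names unknown samples: ",
           paste(miss, collapse = ", "))
  }
  x1 <- ds$signal[, reference, drop = FALSE]
  x2 <- ds$signal[, treatment, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  fit <- data.frame(gene = rownames(ds$signal),
                    mean_ref = m1, mean_trt = m2,
                    mean_lin_ref = rowMeans(2^x1),
                    mean_lin_trt = rowMeans(2^x2),
                    logFC = m2 - m1, fold = 2^(m2 - m1),
                    s2 = s2, df = df,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(fit, class = c("de_fit", "data.frame"),
            n_ref = n1, n_trt = n2, platform = ds$platform,
            contrast = contrast)
}

#' Empirical-Bayes prior for gene variances
#'
#' Method-of-moments fit of a scaled inverse chi-square prior to the
#' observed per-gene variances, on the log scale: solves
#' `trigamma(d0/2) = var(log s2) - trigamma(df/2)` for the prior degrees of
#' freedom `d0`, then recovers the prior variance `s02` via the digamma
#' correction. When the observed dispersion of `log s2` does not exceed its
#' sampling component the prior is a point mass (`d0 = Inf`) and `s02` is
#' the mean observed variance.
#'
#' @param s2 Per-gene variances (>= 10 values).
#' @param df Residual degrees of freedom (scalar, >= 1).
#' @return List of class `ebayes_prior` with `d0` and `s02`.
#' @export
estimate_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 10) stop("need at least 10 finite gene variances")
  stopifnot(length(df) == 1, df >= 1)
  if (all(s2 == 0)) stop("all gene variances are zero; cannot fit a prior")
  pos <- s2[s2 > 0]
  z <- log(pos)
  rhs <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    d0 <- Inf
    s02 <- mean(s2)
  } else {
    f <- function(x) trigamma(x / 2) - rhs
    d0 <- stats::uniroot(f, lower = 1e-3, upper = 1e7, tol = 1e-10)$root
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02), class = "ebayes_prior")
}

#' Moderated t-statistics
#'
#' Shrinks each gene's variance toward the prior,
#' `s2_post = (d0 * s02 + df * s2) / (d0 + df)`, forms the moderated t
#' `logFC / sqrt(s2_post * (1/n1 + 1/n2))`, and tests it on `df + d0`
#' degrees of freedom. With `d0 = Inf` all genes share `s02`; with `d0 = 0`
#' the statistic is the ordinary pooled two-sample t. Genes with zero
#' pooled variance under `d0 = 0` are flagged degenerate (p = 0 when the
#' fold change is nonzero, p = 1 otherwise).
#'
#' @param fit A `de_fit` from [fit_two_group()].
#' @param prior An `ebayes_prior`, or NULL to estimate it from `fit`.
#' @return `data.frame` of class `de_result`: fit columns plus `s2_post`,
#'   `t`, `p`, `q` (BH FDR), `degenerate`; prior stored as attribute.
#' @export
moderate <- function(fit, prior = NULL) {
  stopifnot(inherits(fit, "de_fit"))
  if (is.null(prior)) prior <- estimate_prior(fit$s2, fit$df[1])
  stopifnot(inherits(prior, "ebayes_prior"))
  d0 <- prior$d0; s02 <- prior$s02
  n1 <- attr(fit, "n_ref"); n2 <- attr(fit, "n_trt")
  vunit <- 1 / n1 + 1 / n2
  if (is.infinite(d0)) {
    s2_post <- rep(s02, nrow(fit))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
    df_total <- fit$df + d0
  }
  degenerate <- s2_post == 0
  tstat <- ifelse(degenerate,
                  ifelse(fit$logFC == 0, 0, Inf * sign(fit$logFC)),
                  fit$logFC / sqrt(s2_post * vunit))
  p <- ifelse(is.infinite(tstat), 0, 2 * stats::pt(-abs(tstat), df_total))
  out <- fit
  out$s2_post <- s2_post
  out$t <- tstat
  out$p <- p
  out$q <- bh_fdr(p)
  out$degenerate <- degenerate
  structure(out, class = c("de_result", "de_fit", "data.frame"),
            n_ref = n1, n_trt = n2, platform = attr(fit, "platform"),
            contrast = attr(fit, "contrast"), prior = prior)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_{j>=i} p_(j) * m / j`, clipped at
#' 1 and mapped back to input order (delegates to
#' `stats::p.adjust(method = "BH")` after validation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-call two-group moderated differential expression
#'
#' [fit_two_group()] + [estimate_prior()] + [moderate()].
#'
#' @inheritParams fit_two_group
#' @return A `de_result`.
#' @export
de_two_group <- function(ds, reference, treatment, contrast = NULL) {
  fit <- fit_two_group(ds, reference, treatment, contrast = contrast)
  moderate(fit, estimate_prior(fit$s2, fit$df[1]))
}

#' Read / write a differential-expression result table
#'
#' TSV round trip for `de_result` tables, e.g. to replay a cascade from
#' externally computed statistics. The platform id is needed for the
#' cascade's carry-over rule and is stored as an attribute.
#'
#' @param path TSV path.
#' @param platform Platform id to attach on read.
#' @param contrast Optional contrast label.
#' @return A `de_result` data.frame.
#' @export
read_de_table <- function(path, platform, contrast = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "fold", "q")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("DE table ", path, " lacks required columns: ",
         paste(miss, collapse = ", "))
  structure(tab, class = c("de_result", "data.frame"),
            platform = platform, contrast = contrast)
}

#' @rdname read_de_table
#' @param de A `de_result`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}
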