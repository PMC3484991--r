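#' Relative quantification by the delta-delta Ct method
#'
#' Technical duplicates are averaged on the Ct scale; wells with Ct above
#' `nd_ct` (default 34 cycles) are non-detects and are excluded, never
#' imputed. For each sample and target,
#' `dCt = Ct(target) - Ct(control)`, `ddCt = dCt(sample) - dCt(calibrator)`
#' and the relative quantity is `2^(-ddCt)`.
#'
#' @param plate `data.frame` with columns `sample`, `target`, `ct` (NA for
#'   an undetermined well) and optionally `replicate`.
#' @param calibrator Sample id whose dCt anchors the comparison.
#' @param control_gene Endogenous control target (default `"Tbp"`).
#' @param nd_ct Non-detect cycle threshold; wells with `ct > nd_ct` are
#'   treated as not detectable.
#' @return `data.frame` with one row per sample x non-control target:
#'   `sample`, `target`, `ct_target`, `ct_control`, `delta_ct`,
#'   `delta_delta_ct`, `rel_quantity`, `detected`. Non-detect targets have
#'   `detected = FALSE` and NA quantities.
#' @examples
#' plate <- data.frame(sample = rep(c("ctrl", "trt"), each = 2),
#'                     target = rep(c("Tbp", "Crhr1"), 2),
#'                     ct = c(20, 26, 20, 25))
#' ddct_quantify(plate, calibrator = "ctrl")
#' @export
ddct_quantify <- function(plate, calibrator, control_gene = "Tbp",
                          nd_ct = 34) {
  stopifnot(is.data.frame(plate),
            all(c("sample", "target", "ct") %in% names(plate)))
  if (any(plate$ct <= 0, na.rm = TRUE))
    stop("Ct values must be positive")
  plate$detected_well <- !is.na(plate$ct) & plate$ct <= nd_ct
  # average detected technical replicates on the Ct scale
  agg <- do.call(rbind, lapply(
    split(plate, list(plate$sample, plate$target), drop = TRUE),
    function(d) data.frame(sample = d$sample[1], target = d$target[1],
                           ct = if (any(d$detected_well))
                             mean(d$ct[d$detected_well]) else NA_real_,
                           detected = any(d$detected_well),
                           stringsAsFactors = FALSE)))
  if (!calibrator %in% agg$sample)
    stop("calibrator sample not on plate: ", calibrator)
  ctrl <- agg[agg$target == control_gene, ]
  if (!nrow(ctrl)) stop("control gene not on plate: ", control_gene)
  samples <- unique(agg$sample)
  nd_ctrl <- setdiff(samples, ctrl$sample[ctrl$detected])
  if (length(nd_ctrl))
    stop("endogenous control `", control_gene,
         "` not detected in sample(s): ", paste(nd_ctrl, collapse = ", "))
  ctrl_ct <- stats::setNames(ctrl$ct, ctrl$sample)
  targ <- agg[agg$target != control_gene, ]
  targ$ct_control <- ctrl_ct[targ$sample]
  targ$delta_ct <- targ$ct - targ$ct_control
  cal_dct <- stats::setNames(targ$delta_ct[targ$sample == calibrator],
                             targ$target[targ$sample == calibrator])
  targ$delta_delta_ct <- targ$delta_ct - cal_dct[targ$target]
  targ$rel_quantity <- 2^(-targ$delta_delta_ct)
  # calibrator non-detect makes the whole target uncomputable
  bad_cal <- names(cal_dct)[is.na(cal_dct)]
  targ$rel_quantity[targ$target %in% bad_cal] <- NA_real_
  targ$delta_delta_ct[targ$target %in% bad_cal] <- NA_real_
  out <- data.frame(sample = targ$sample, target = targ$target,
                    ct_target = targ$ct, ct_control = targ$ct_control,
                    delta_ct = targ$delta_ct,
                    delta_delta_ct = targ$delta_delta_ct,
                    rel_quantity = targ$rel_quantity,
                    detected = targ$detected,
                    stringsAsFactors = FALSE)
  out <- out[order(out$target, out$sample), ]
  rownames(out) <- NULL
  out
}

#' Two-tailed unpaired pooled-variance t-test
#'
#' Classical two-sample t with pooled variance. With zero pooled variance
#' and equal means the statistic is 0 and p = 1; with zero variance and
#' unequal means the difference is deterministic (t infinite, p = 0).
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
two_group_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (s2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(b) - mean(a)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(b, a, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# max-|T| Dunnett null draws for k treatments vs one control,
# group sizes n (length k+1, control first), error df `df`
dunnett_maxt_draws <- function(k, n, df, nsim, seed) {
  set.seed(seed)
  zbar <- matrix(stats::rnorm(nsim * (k + 1)), nsim, k + 1)
  zbar <- sweep(zbar, 2, sqrt(n), "/")
  s <- sqrt(stats::rchisq(nsim, df) / df)
  tmat <- (zbar[, -1, drop = FALSE] - zbar[, 1]) /
    outer(s, sqrt(1 / n[-1] + 1 / n[1]))
  apply(abs(tmat), 1, max)
}

#' Dunnett two-sided critical value (Monte Carlo)
#'
#' The `1 - alpha` quantile of the null max-|T| distribution for `k`
#' treatment-vs-control comparisons with balanced group size `n_per` and
#' `df` error degrees of freedom, evaluated by seeded Monte Carlo.
#'
#' @param k Number of treatment groups.
#' @param df Error degrees of freedom.
#' @param n_per Per-group size (balanced; default 2 reproduces
#'   `df = (k + 1) * (n_per - 1)` designs but any df may be given).
#' @param alpha Familywise error rate (default 0.05).
#' @param nsim Monte Carlo draws (default 1e5).
#' @param seed RNG seed.
#' @return Critical value (scalar).
#' @export
dunnett_crit <- function(k, df, n_per = 2, alpha = 0.05, nsim = 1e5,
                         seed = 1) {
  draws <- dunnett_maxt_draws(k, rep(n_per, k + 1), df, nsim, seed)
  unname(stats::quantile(draws, 1 - alpha, type = 8))
}

#' One-way ANOVA with Dunnett's multiple comparisons
#'
#' One-way ANOVA F-test across all groups, then two-sided Dunnett
#' comparisons of each treatment against the control, with adjusted
#' p-values `P(max_j |T_j| >= |t_i|)` evaluated from the multivariate-t
#' null by seeded Monte Carlo.
#'
#' @param groups List of numeric measurement vectors (>= 3 groups, each
#'   >= 2 values). With exactly 2 groups the caller is directed to
#'   [two_group_ttest()].
#' @param control_index Which element of `groups` is the control (default 1).
#' @param nsim Monte Carlo draws for the adjustment (default 1e5).
#' @param seed RNG seed for the Monte Carlo draws.
#' @return List of class `anova_dunnett`: `F`, `df`, `p_anova`, and
#'   `comparisons` data.frame (group, estimate, t, p_raw, p_adj).
#' @export
anova_dunnett <- function(groups, control_index = 1, nsim = 1e5, seed = 1) {
  stopifnot(is.list(groups))
  if (length(groups) == 2)
    stop("two groups: use two_group_ttest() for a two-group comparison")
  if (length(groups) < 3) stop("need at least 3 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  gmeans <- vapply(groups, mean, 0)
  within_ss <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  if (within_ss == 0) {
    # degenerate: no replicate variance; differences are deterministic
    df_err <- length(y) - length(groups)
    s2 <- 0
    if (all(gmeans == gmeans[1])) { Fval <- 0; p_anova <- 1 }
    else { Fval <- Inf; p_anova <- 0 }
    av_df1 <- length(groups) - 1
  } else {
    fit <- stats::aov(y ~ g)
    av <- summary(fit)[[1]]
    Fval <- av$`F value`[1]
    p_anova <- av$`Pr(>F)`[1]
    s2 <- av$`Mean Sq`[2]
    df_err <- av$Df[2]
    av_df1 <- av$Df[1]
  }

  ctrl <- groups[[control_index]]
  trts <- groups[-control_index]
  n <- c(length(ctrl), vapply(trts, length, 0L))
  k <- length(trts)
  est <- vapply(trts, mean, 0) - mean(ctrl)
  se <- sqrt(s2 * (1 / n[-1] + 1 / n[1]))
  tstat <- if (s2 == 0) ifelse(est == 0, 0, Inf * sign(est)) else est / se
  p_raw <- ifelse(is.infinite(tstat), 0,
                  2 * stats::pt(-abs(tstat), df_err))
  if (s2 == 0) {
    p_adj <- ifelse(est == 0, 1, 0)
  } else {
    draws <- dunnett_maxt_draws(k, n, df_err, nsim, seed)
    p_adj <- vapply(abs(tstat), function(t0) mean(draws >= t0), 0)
    p_adj <- pmax(p_adj, p_raw)   # adjusted never below raw
  }
  comparisons <- data.frame(group = names(trts), estimate = est,
                            t = tstat, p_raw = p_raw, p_adj = p_adj,
                            row.names = NULL, stringsAsFactors = FALSE)
  structure(list(F = Fval, df = c(av_df1, df_err), p_anova = p_anova,
                 comparisons = comparisons),
            class = "anova_dunnett")
}

#' @export
print.anova_dunnett <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p_anova))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Four-parameter logistic standard curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x / c)^b)`: `a` is the
#' response at zero concentration, `d` the response at infinite
#' concentration, `c` the inflection concentration (same units as `x`,
#' typically pM) and `b` the slope.
#'
#' @param concentration Standard concentrations (>= 5, spanning `c`).
#' @param response Measured responses, same length.
#' @return List of class `fourpl` with `a`, `b`, `c`, `d`, `fitted`,
#'   `residuals`.
#' @export
fourpl_fit <- function(concentration, response) {
  stopifnot(length(concentration) == length(response),
            length(concentration) >= 5, all(concentration >= 0))
  ord <- order(concentration)
  r_ord <- response[ord]
  if (is.unsorted(r_ord) && is.unsorted(rev(r_ord)))
    warning("standard responses are not monotone in concentration")
  a0 <- r_ord[1]; d0 <- r_ord[length(r_ord)]
  pos <- concentration[concentration > 0]
  c0 <- exp(mean(log(range(pos))))
  dat <- data.frame(x = concentration, y = response)
  fit <- minpack.lm::nlsLM(
    y ~ d + (a - d) / (1 + (x / c)^b), data = dat,
    start = list(a = a0, d = d0, c = c0, b = 1),
    lower = c(a = -Inf, d = -Inf, c = 1e-12, b = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), d = unname(cf["d"]),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "fourpl")
}

#' @rdname fourpl_fit
#' @param model A `fourpl` fit.
#' @param response Response value(s) to invert to concentration.
#' @param sensitivity Optional assay sensitivity floor (e.g. 4.5 pM);
#'   estimates below it are flagged.
#' @return For `fourpl_invert`: `data.frame` with `response`,
#'   `concentration`, `below_sensitivity`.
#' @export
fourpl_invert <- function(model, response, sensitivity = NULL) {
  stopifnot(inherits(model, "fourpl"))
  lo <- min(model$a, model$d); hi <- max(model$a, model$d)
  if (any(response <= lo | response >= hi))
    stop("response outside the open curve range (",
         signif(lo, 6), ", ", signif(hi, 6), ")")
  conc <- model$c * ((model$a - model$d) / (response - model$d) - 1)^(1 / model$b)
  flag <- if (is.null(sensitivity)) rep(FALSE, length(conc))
          else conc < sensitivity
  data.frame(response = response, concentration = conc,
             below_sensitivity = flag)
}
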