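#' Per-animal mean index above and below the LLA
#'
#' Partitions the index epochs by the concurrent 10-s mean ABP relative to
#' the LLA and returns the two means. When one side has no epochs the
#' corresponding mean is NA and the result is flagged.
#'
#' @param index an `index_series`.
#' @param sw the recording's `slow_waves_df` (for concurrent ABP).
#' @param lla an `lla_estimate` or a number (mmHg).
#' @return list with `above`, `below` (means, possibly NA), `n_above`,
#'   `n_below`, and `complete` (TRUE when both sides have data).
#' @export
paired_above_below <- function(index, sw, lla) {
  lla_v <- if (inherits(lla, "lla_estimate")) lla$lla else as.numeric(lla)
  abp <- sw$abp[match(index$time_s, sw$time_s)]
  ok <- is.finite(index$value) & is.finite(abp)
  v <- index$value[ok]; a <- abp[ok]
  above <- v[a >= lla_v]; below <- v[a < lla_v]
  list(above = if (length(above)) mean(above) else NA_real_,
       below = if (length(below)) mean(below) else NA_real_,
       n_above = length(above), n_below = length(below),
       complete = length(above) > 0 && length(below) > 0)
}

# Mann-Whitney AUC and DeLong structural components.
# scores: numeric; labels: logical/0-1, TRUE = positive class.
.delong_components <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    stop("single-class input: both classes required", call. = FALSE)
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  list(auc = mean(cmp),
       v10 = rowMeans(cmp),   # one per positive
       v01 = colMeans(cmp))   # one per negative
}

#' ROC curve with Youden-optimal cutoff
#'
#' AUC by pairwise concordance (Mann-Whitney, half credit for ties —
#' identical to the trapezoidal ROC area), the cutoff maximizing
#' sensitivity + specificity (Youden J, predicting positive when
#' `score >= cutoff`), exact Clopper-Pearson 95% CIs for sensitivity and
#' specificity at the cutoff, and a z-test of AUC = 0.5 using the DeLong
#' variance.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1; TRUE/1 = positive class.
#' @return An `roc_result`: list with `auc`, `auc_se`, `p_vs_chance`,
#'   `cutoff`, `sensitivity`, `specificity`, `sens_ci`, `spec_ci`,
#'   `n_pos`, `n_neg`, and the full `operating_points` data.frame.
#' @export
roc_with_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  comp <- .delong_components(scores, labels)
  m <- sum(labels); n <- sum(!labels)

  cand <- sort(unique(scores))
  op <- data.frame(
    cutoff = cand,
    sensitivity = vapply(cand, function(c0) mean(scores[labels] >= c0), 0),
    specificity = vapply(cand, function(c0) mean(scores[!labels] < c0), 0)
  )
  j <- op$sensitivity + op$specificity - 1
  best <- which.max(j)
  sens_k <- round(op$sensitivity[best] * m)
  spec_k <- round(op$specificity[best] * n)
  sens_ci <- stats::binom.test(sens_k, m)$conf.int
  spec_ci <- stats::binom.test(spec_k, n)$conf.int

  var_auc <- stats::var(comp$v10) / m + stats::var(comp$v01) / n
  se <- sqrt(var_auc)
  p_chance <- if (se > 0) 2 * stats::pnorm(-abs((comp$auc - 0.5) / se)) else
    as.numeric(comp$auc == 0.5)

  structure(list(auc = comp$auc, auc_se = se, p_vs_chance = p_chance,
                 cutoff = op$cutoff[best],
                 sensitivity = op$sensitivity[best],
                 specificity = op$specificity[best],
                 sens_ci = as.numeric(sens_ci), spec_ci = as.numeric(spec_ci),
                 n_pos = m, n_neg = n, operating_points = op),
            class = "roc_result")
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same observations, using
#' the structural-components covariance estimator; two-sided p from the
#' normal approximation. Identical scores give difference 0 and p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels logical or 0/1 labels shared by both scores.
#' @return list with `auc_a`, `auc_b`, `diff`, `se`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) < 1e-12)
      return(list(auc_a = ca$auc, auc_b = cb$auc, diff = 0,
                  se = 0, z = 0, p = 1))
    stop("degenerate variance in DeLong test (AUCs differ but estimated ",
         "variance is zero)", call. = FALSE)
  }
  z <- d / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, diff = d,
       se = sqrt(var_diff), z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Paired t-test wrapper with explicit degeneracy handling
#'
#' Classical paired t on the differences, two-sided. Zero difference
#' variance is a defined error rather than a division by zero.
#'
#' @param x,y paired numeric vectors.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    if (abs(mean(d)) < 1e-12) return(list(t = 0, df = length(d) - 1, p = 1,
                                          mean_diff = 0))
    stop("degenerate paired t: zero difference variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b`; bias = mean(d); 95% limits of agreement
#' bias +/- 1.96 * SD(d).
#'
#' @param a,b paired numeric vectors (length >= 3 after removing incomplete
#'   pairs).
#' @return list with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `n`,
#'   and the Pearson `r`/`r_p` of a vs b.
#' @export
bland_altman <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    stop("input error: need at least 3 complete pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  ct <- if (stats::sd(a) > 0 && stats::sd(b) > 0)
    stats::cor.test(a, b) else NULL
  list(bias = bias, sd_diff = s,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       n = length(a),
       r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       r_p = if (is.null(ct)) NA_real_ else ct$p.value)
}
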