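#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank tie handling.
#' The two-sided p-value is exact — computed by enumerating the permutation
#' distribution of the rank sum (a subset-sum dynamic program over the
#' observed midranks, valid under ties) — when `n_x * n_y <= 400`; otherwise
#' the normal approximation with tie correction and continuity correction is
#' used. Two-sided p is `2 * min(tail, 0.5)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (statistic for `x`), `p`, and `method`
#'   (`"exact"`/`"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  .assert(length(x) > 0 && length(y) > 0, "empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 400) {
    p <- .u_exact_p(r, n1)
    list(U = U, p = p, method = "exact")
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

# Exact permutation distribution of the rank sum over all C(N, n1) subsets,
# via dynamic programming on doubled midranks (integers even with ties).
.u_exact_p <- function(r, n1) {
  r2 <- as.integer(round(2 * r))
  N <- length(r2)
  s_obs <- sum(r2[seq_len(n1)])
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[j+1, s+1] = number of j-subsets with doubled-rank sum s
  f <- matrix(0, n1 + 1, smax + 1)
  f[1, 1] <- 1
  for (item in r2) {
    jmax <- n1
    for (j in jmax:1) {
      nonzero <- which(f[j, ] > 0)
      nonzero <- nonzero[nonzero + item <= smax + 1]
      if (length(nonzero) > 0)
        f[j + 1, nonzero + item] <- f[j + 1, nonzero + item] + f[j, nonzero]
    }
  }
  dist <- f[n1 + 1, ]
  total <- sum(dist)
  lo <- sum(dist[seq_len(s_obs + 1)]) / total       # P(S <= s_obs)
  hi <- sum(dist[(s_obs + 1):(smax + 1)]) / total   # P(S >= s_obs)
  min(1, 2 * min(lo, hi, 0.5))
}

#' ROC analysis with Youden threshold selection
#'
#' Builds the ROC curve over thresholds at midpoints between sorted unique
#' scores (plus sentinels beyond the extremes), computes the trapezoidal AUC
#' (equal to the Mann-Whitney `U/(n1*n2)` under midrank tie handling), and
#' selects the operating threshold maximising the Youden index
#' `J = sensitivity + specificity - 1`, breaking ties toward higher
#' specificity (fewer false positives).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or two-level factor/character;
#'   the larger/`TRUE`/second level is the positive class unless `positive`
#'   names it).
#' @param positive_direction `"higher"` if larger scores indicate the
#'   positive class, `"lower"` otherwise.
#' @param positive Optional positive-class label.
#' @return An object of class `msti_roc`: thresholds, sensitivity,
#'   specificity, `auc`, `youden_threshold`, `youden_J`, `direction`.
#' @export
roc_analysis <- function(scores, labels, positive_direction = c("higher", "lower"),
                         positive = NULL) {
  positive_direction <- match.arg(positive_direction)
  .assert(length(scores) == length(labels), "length mismatch")
  y <- .as_binary(labels, positive)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  s <- if (positive_direction == "higher") scores else -scores
  u <- sort(unique(s))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(s > t & y == 1) / npos, numeric(1))
  spec <- vapply(thr, function(t) sum(s <= t & y == 0) / nneg, numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  J <- sens + spec - 1
  best <- which(J > max(J) - 1e-12)
  best <- best[which.max(spec[best])]
  youden_thr <- if (positive_direction == "higher") thr[best] else -thr[best]
  structure(list(
    thresholds = if (positive_direction == "higher") thr else rev(-thr),
    sensitivity = if (positive_direction == "higher") sens else rev(sens),
    specificity = if (positive_direction == "higher") spec else rev(spec),
    auc = auc, youden_threshold = youden_thr, youden_J = J[best],
    direction = positive_direction), class = "msti_roc")
}

.as_binary <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.numeric(labels)) {
    .assert(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    return(labels)
  }
  lab <- as.character(labels)
  lev <- sort(unique(lab))
  .assert(length(lev) <= 2, "labels must be binary")
  pos <- positive %||% (if ("lysed" %in% lev) "lysed" else lev[length(lev)])
  as.numeric(lab == pos)
}

#' Diagnostic performance metrics from binary calls
#'
#' @param calls Predicted classes.
#' @param truth True classes (same encoding).
#' @param positive Positive-class label (default `"lysed"`/`TRUE`-like, as
#'   in [roc_analysis()]).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` (NaN where
#'   the denominator is empty) and the `counts` (TP, FP, TN, FN).
#' @export
diagnostic_metrics <- function(calls, truth, positive = NULL) {
  .assert(length(calls) == length(truth), "length mismatch")
  keep <- !is.na(calls) & !is.na(truth)
  cb <- .as_binary(calls[keep], positive)
  tb <- .as_binary(truth[keep], positive)
  TP <- sum(cb == 1 & tb == 1); FP <- sum(cb == 1 & tb == 0)
  TN <- sum(cb == 0 & tb == 0); FN <- sum(cb == 0 & tb == 1)
  div <- function(a, b) if (b == 0) NaN else a / b
  list(sensitivity = div(TP, TP + FN), specificity = div(TN, TN + FP),
       ppv = div(TP, TP + FP), npv = div(TN, TN + FN),
       counts = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' Pearson correlation with t-distribution p-value
#'
#' Standard product-moment correlation; p from the t distribution with
#' `n - 2` degrees of freedom (delegated to `stats::cor.test`).
#'
#' @param x,y Paired numeric vectors, `n >= 3`, non-degenerate.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  .assert(length(x) == length(y), "length mismatch")
  .assert(length(x) >= 3, "need n >= 3")
  .assert(sd(x) > 0 && sd(y) > 0, "zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean paired difference `x - y`; limits of agreement are
#' `bias +/- 1.96 * sd(x - y)` with the sample (n-1) standard deviation.
#'
#' @param x,y Paired measurements (same length, n >= 2).
#' @return List with `bias`, `loa_lo`, `loa_hi`, `sd_diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("unpaired lengths", call. = FALSE)
  .assert(length(x) >= 2, "need n >= 2")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_lo = bias - 1.96 * s, loa_hi = bias + 1.96 * s,
       sd_diff = s)
}

#' Cohen's kappa for two categorical raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` from
#' the product of the marginal category proportions. Returns `NA` (with a
#' warning) when `p_e = 1` (both raters constant), where kappa is undefined.
#'
#' @param r1,r2 Paired categorical ratings (same length).
#' @return Numeric kappa.
#' @export
cohen_kappa <- function(r1, r2) {
  .assert(length(r1) == length(r2), "length mismatch")
  lev <- union(unique(as.character(r1)), unique(as.character(r2)))
  t1 <- factor(as.character(r1), levels = lev)
  t2 <- factor(as.character(r2), levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("expected agreement is 1; kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}
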