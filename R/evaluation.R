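#' DeLong AUC with standard error and confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic (ties
#' count 1/2), with the DeLong variance estimate and 95% CI; the paired
#' comparison of two score sets on the same cases uses the DeLong
#' covariance.
#'
#' @param scores numeric predictor (larger = more positive).
#' @param labels two-class factor/logical (positive = second level/TRUE).
#' @param conf_level confidence level (default 0.95).
#' @return List: `auc`, `se`, `ci` (length 2).
#' @export
roc_auc_delong <- function(scores, labels, conf_level = 0.95) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  r <- pROC::roc(response = pos, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                method = "delong"))
  se <- sqrt(pROC::var(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), se = se, ci = ci[c(1, 3)])
}

#' Paired DeLong comparison of two ROC curves
#'
#' @param scores1,scores2 two predictors measured on the same cases.
#' @param labels shared two-class labels.
#' @return List: `p`, `auc1`, `auc2`, `auc_diff`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  pos <- as_positive(labels)
  r1 <- pROC::roc(pos, scores1, levels = c(FALSE, TRUE), direction = "<",
                  quiet = TRUE)
  r2 <- pROC::roc(pos, scores2, levels = c(FALSE, TRUE), direction = "<",
                  quiet = TRUE)
  if (identical(scores1, scores2)) {
    return(list(p = 1, auc1 = as.numeric(pROC::auc(r1)),
                auc2 = as.numeric(pROC::auc(r2)), auc_diff = 0))
  }
  tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  list(p = tst$p.value, auc1 = as.numeric(pROC::auc(r1)),
       auc2 = as.numeric(pROC::auc(r2)),
       auc_diff = as.numeric(pROC::auc(r1)) - as.numeric(pROC::auc(r2)))
}

#' Confusion-matrix diagnostic metrics at a cut-off
#'
#' Standard 2x2 definitions; proportions are reported in percent.
#' Likelihood ratios: `+LR = sens / (1 - spec)`, `-LR = (1 - sens) / spec`
#' (on the proportion scale); infinite when the denominator is 0.
#' Metrics whose denominator class is empty are `NA`.
#'
#' @param scores numeric predictor (or probabilities).
#' @param labels two-class factor/logical.
#' @param cutoff decision threshold: `scores >= cutoff` calls positive.
#' @return List: `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (all percent), `plr`, `nlr`.
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  pos <- as_positive(labels)
  call_pos <- scores >= cutoff
  tp <- sum(call_pos & pos);  fn <- sum(!call_pos & pos)
  tn <- sum(!call_pos & !pos); fp <- sum(call_pos & !pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  acc <- (tp + tn) / length(pos)
  plr <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else Inf
  nlr <- if (!is.na(spec) && spec > 0) (1 - sens) / spec else Inf
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = 100 * acc, sensitivity = 100 * sens,
       specificity = 100 * spec, ppv = 100 * ppv, npv = 100 * npv,
       plr = plr, nlr = nlr)
}

#' Logistic-regression odds ratio, p-value and AIC
#'
#' Univariate logistic regression of the outcome on one predictor. For a
#' binary predictor the fitted odds ratio equals the cross-product ratio
#' `ad / bc` of the 2x2 table. Complete separation (a zero cell) is
#' flagged and the odds ratio reported as infinite (or, with
#' `haldane = TRUE`, from the table with 0.5 added to every cell).
#' A McFadden pseudo-R2 is reported alongside the AIC as a normalized
#' goodness-of-fit index.
#'
#' @param predictor numeric, logical or two-level factor.
#' @param labels two-class outcome.
#' @param haldane apply the Haldane-Anscombe +0.5 correction for zero
#'   cells of a binary predictor (default FALSE).
#' @return List: `odds_ratio`, `p`, `aic`, `pseudo_r2`, `separation`.
#' @export
logistic_or <- function(predictor, labels, haldane = FALSE) {
  y <- as_positive(labels)
  if (is.factor(predictor) || is.logical(predictor))
    predictor <- as.numeric(as_positive(predictor))
  binary <- length(unique(predictor)) == 2
  separation <- FALSE
  if (binary) {
    hi <- predictor == max(predictor)
    a <- sum(hi & y); b <- sum(hi & !y)
    c_ <- sum(!hi & y); d <- sum(!hi & !y)
    if (min(a, b, c_, d) == 0) {
      separation <- TRUE
      if (haldane) {
        or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      } else {
        or <- if (b == 0 || c_ == 0) Inf else 0
      }
      fit <- suppressWarnings(stats::glm(y ~ predictor, family = stats::binomial()))
      null_dev <- fit$null.deviance
      return(list(odds_ratio = or, p = NA_real_, aic = fit$aic,
                  pseudo_r2 = 1 - fit$deviance / null_dev,
                  separation = TRUE))
    }
  }
  fit <- stats::glm(y ~ predictor, family = stats::binomial())
  cf <- summary(fit)$coefficients
  list(odds_ratio = exp(cf[2, 1]), p = cf[2, 4], aic = fit$aic,
       pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
       separation = separation)
}

#' Concordance index for a binary outcome
#'
#' Fraction of positive/negative case pairs in which the positive case
#' scores higher, counting ties 1/2; identical to the AUC for binary
#' outcomes.
#'
#' @param scores numeric predictor.
#' @param labels two-class factor/logical.
#' @return Scalar in `[0, 1]`.
#' @export
concordance_index <- function(scores, labels) {
  pair_auc(scores, as_positive(labels))
}

#' Mann-Whitney U test
#'
#' Exact null distribution when both groups have 8 or fewer observations
#' and there are no ties; tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric group values.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `U` (statistic for group `a`), `p`.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !any(duplicated(c(a, b)))
  wt <- stats::wilcox.test(a, b, alternative = alternative,
                           exact = exact, correct = !exact)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; the null distribution is exact for up to
#' 12 nonzero untied differences and a normal approximation above. When
#' all differences are zero the test is uninformative and `p = 1` is
#' returned with a warning.
#'
#' @param differences numeric vector of paired differences.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `W`, `p`.
#' @export
wilcoxon_signed_rank <- function(differences, alternative = "two.sided") {
  nz <- differences[differences != 0]
  if (length(nz) == 0) {
    warning("all differences are zero; test uninformative")
    return(list(W = 0, p = 1))
  }
  exact <- length(nz) <= 12 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(differences, alternative = alternative,
                       exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Cohort contingency summary with per-category chi-square tests
#'
#' For a categories-by-outcome count table, reports row percentages
#' (within category), column percentages (within outcome), and a Pearson
#' chi-square test (1 df, no continuity correction) of each category
#' against the rest. Categories with a zero margin are skipped with a
#' warning.
#'
#' @param counts numeric matrix, rows = categories (named), 2 columns =
#'   outcomes (for example `VPI-`, `VPI+`).
#' @return data.frame: `category`, counts, row/column percentages
#'   (1 decimal place) and `chisq_p`.
#' @export
summarize_cohort <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) stop("need a categories x 2 count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  col_tot <- colSums(counts)
  out <- lapply(rownames(counts), function(cat) {
    row <- counts[cat, ]
    n <- sum(row)
    if (n == 0) {
      warning("skipping zero-margin category: ", cat)
      return(NULL)
    }
    rest <- col_tot - row
    p <- if (all(rest + row > 0) && sum(rest) > 0) {
      suppressWarnings(
        stats::chisq.test(rbind(row, rest), correct = FALSE)$p.value)
    } else NA_real_
    data.frame(category = cat,
               n = n,
               n_neg = row[1], n_pos = row[2],
               row_pct_neg = round(100 * row[1] / n, 1),
               row_pct_pos = round(100 * row[2] / n, 1),
               col_pct_neg = round(100 * row[1] / col_tot[1], 1),
               col_pct_pos = round(100 * row[2] / col_tot[2], 1),
               total_pct = round(100 * n / tot, 1),
               chisq_p = p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Full evaluation report of a signature on labelled cases
#'
#' Bundles the statistics reported for a diagnostic signature: DeLong
#' AUC/SE/CI, confusion metrics at the supplied (or Youden-optimal)
#' cut-off, the odds ratio / AIC / pseudo-R2 of the high-vs-low risk
#' logistic model, the concordance index, and the Mann-Whitney p-value
#' for the signature between classes.
#'
#' @param pi signature probabilities.
#' @param labels two-class labels.
#' @param pi_cutoff cut-off on the probability scale; `NULL` = derive the
#'   Youden-optimal cut-off from these data.
#' @return A list of class `evaluation_report`.
#' @export
evaluation_report <- function(pi, labels, pi_cutoff = NULL) {
  pos <- as_positive(labels)
  cut <- if (is.null(pi_cutoff)) roc_cutoff(pi, pos) else
    list(pi_cutoff = pi_cutoff, roc_cutoff = stats::qlogis(pi_cutoff),
         youden = NA_real_, informative = NA)
  roc <- roc_auc_delong(pi, pos)
  cm <- confusion_metrics(pi, pos, cut$pi_cutoff)
  risk <- stratify_risk(pi, cut$pi_cutoff)
  lr <- logistic_or(risk == "high", pos)
  mw <- mann_whitney(pi[!pos], pi[pos])
  structure(list(
    auc = roc$auc, auc_se = roc$se, auc_ci = roc$ci,
    cutoff = cut, confusion = cm,
    odds_ratio = lr$odds_ratio, or_p = lr$p, aic = lr$aic,
    pseudo_r2 = lr$pseudo_r2, or_separation = lr$separation,
    concordance_index = concordance_index(pi, pos),
    mann_whitney_p = mw$p,
    n = length(pi), n_pos = sum(pos), n_neg = sum(!pos)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Radiomic signature evaluation (n = %d: %d VPI-, %d VPI+)\n",
              x$n, x$n_neg, x$n_pos))
  cat(sprintf("  AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_se, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  cut-off Pi %.3f (decision scale %.3f)\n",
              x$cutoff$pi_cutoff, x$cutoff$roc_cutoff))
  cm <- x$confusion
  cat(sprintf("  accuracy %.1f%%  sens %.1f%%  spec %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
              cm$accuracy, cm$sensitivity, cm$specificity, cm$ppv, cm$npv))
  cat(sprintf("  +LR %.2f  -LR %.3f\n", cm$plr, cm$nlr))
  cat(sprintf("  odds ratio %.2f (p %.3g)  AIC %.1f  pseudo-R2 %.3f\n",
              x$odds_ratio, x$or_p, x$aic, x$pseudo_r2))
  cat(sprintf("  concordance index %.3f  Mann-Whitney p %.3g\n",
              x$concordance_index, x$mann_whitney_p))
  invisible(x)
}
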