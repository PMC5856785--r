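test_that("DeLong AUC equals exhaustive pair counting", {
  r <- roc_auc_delong(c(0.9, 0.6, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.875)   # 3.5 of 4 pairs, tie counts 1/2

  lab <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  # pROC warns that SE/CI are degenerate at AUC 1; only the AUC matters here
  expect_equal(suppressWarnings(roc_auc_delong(as.numeric(lab), lab)$auc), 1)

  set.seed(81)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    lb <- runif(n) < 0.5
    if (!any(lb) || all(lb)) next
    r <- roc_auc_delong(sc, lb)
    expect_equal(r$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    expect_gte(r$ci[1], 0); expect_lte(r$ci[2], 1)
    expect_gte(r$auc, r$ci[1] - 1e-9); expect_lte(r$auc, r$ci[2] + 1e-9)
  }
  expect_error(roc_auc_delong(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("paired DeLong comparison is null for identical curves", {
  set.seed(82)
  sc <- rnorm(40); lb <- runif(40) < 0.5
  lb[1:2] <- c(TRUE, FALSE)
  same <- delong_test(sc, sc, lb)
  expect_equal(same$p, 1)
  expect_equal(same$auc_diff, 0)
  other <- delong_test(sc, rnorm(40), lb)
  expect_true(other$p >= 0 && other$p <= 1)
})

test_that("confusion metrics follow the 2x2 definitions", {
  # TP 9, FN 1, TN 8, FP 2
  scores <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  labels <- c(rep(TRUE, 10), rep(FALSE, 10))
  m <- confusion_metrics(scores, labels, cutoff = 0.5)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 85)
  expect_equal(m$plr, 4.5)

  perfect <- confusion_metrics(as.numeric(labels), labels, 0.5)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$nlr, 0)
  expect_equal(perfect$plr, Inf)
})

test_that("confusion metrics satisfy the Bayes and accuracy identities", {
  set.seed(83)
  for (i in 1:1000) {
    tp <- sample(1:30, 1); fn <- sample(1:30, 1)
    tn <- sample(1:30, 1); fp <- sample(1:30, 1)
    scores <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
    labels <- c(rep(TRUE, tp + fn), rep(FALSE, tn + fp))
    m <- confusion_metrics(scores, labels, 0.5)
    sens <- m$sensitivity / 100; spec <- m$specificity / 100
    prev <- (tp + fn) / (tp + fn + tn + fp)
    ppv_bayes <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
    expect_equal(m$ppv / 100, ppv_bayes, tolerance = 1e-12)
    expect_equal(m$accuracy / 100,
                 (sens * (tp + fn) + spec * (tn + fp)) / (tp + fn + tn + fp),
                 tolerance = 1e-12)
  }
})

test_that("logistic odds ratio matches the cross-product ratio", {
  pred <- c(rep(1, 12), rep(0, 15))
  lab <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 5), rep(FALSE, 10))
  r <- logistic_or(pred, lab)
  expect_equal(r$odds_ratio, 10, tolerance = 1e-6)
  expect_false(r$separation)
  expect_equal(r$aic, 2 * 2 - 2 * as.numeric(
    logLik(glm(lab ~ pred, family = binomial()))), tolerance = 1e-8)

  # independence: a/b = c/d so OR = 1
  pred2 <- c(rep(1, 20), rep(0, 30))
  lab2 <- c(rep(TRUE, 8), rep(FALSE, 12), rep(TRUE, 12), rep(FALSE, 18))
  expect_equal(logistic_or(pred2, lab2)$odds_ratio, 1, tolerance = 1e-6)

  # separation flag and Haldane correction
  sep <- logistic_or(c(rep(1, 5), rep(0, 5)),
                     c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_true(sep$separation)
  expect_equal(sep$odds_ratio, Inf)
  hal <- logistic_or(c(rep(1, 5), rep(0, 5)),
                     c(rep(TRUE, 5), rep(FALSE, 5)), haldane = TRUE)
  expect_equal(hal$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
})

test_that("logistic regression recovers a known odds ratio", {
  set.seed(84)
  ok <- 0
  for (s in 1:40) {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    p <- plogis(-0.5 + log(3) * x)
    y <- runif(n) < p
    est <- logistic_or(x, y)$odds_ratio
    if (est >= 2.4 && est <= 3.75) ok <- ok + 1
  }
  expect_gte(ok, 36)   # ~90% coverage of the recovery interval
})

test_that("concordance index is the AUC and flips with score reversal", {
  set.seed(85)
  sc <- rnorm(40); lb <- runif(40) < 0.5
  lb[1:2] <- c(TRUE, FALSE)
  expect_equal(concordance_index(sc, lb), roc_auc_delong(sc, lb)$auc)
  expect_equal(concordance_index(-sc, lb), 1 - concordance_index(sc, lb))
  expect_equal(concordance_index(c(0.9, 0.6, 0.6, 0.1),
                                 c(TRUE, TRUE, FALSE, FALSE)), 0.875)
})

test_that("Mann-Whitney: exact small-sample null and oracle agreement", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 20)   # 1 of choose(6,3) orderings

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)

  # exact enumeration oracle for small untied samples
  set.seed(86)
  for (i in 1:5) {
    a <- sample(seq(0.1, 9.9, by = 0.1), 5)
    b <- setdiff(sample(seq(0.1, 9.9, by = 0.1), 11), a)[1:6]
    got <- mann_whitney(a, b)
    pool <- c(a, b)
    combos <- combn(11, 5)
    ustat <- function(ga) {
      sum(outer(ga, setdiff(pool, ga), ">")) }
    u_obs <- ustat(a)
    u_all <- apply(combos, 2, function(ix) ustat(pool[ix]))
    p_exact <- mean(abs(u_all - 15) >= abs(u_obs - 15))  # E[U]=n1*n2/2
    expect_equal(got$p, p_exact, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney p-values are uniform under the null", {
  set.seed(87)
  vals <- rnorm(40)
  ps <- replicate(2000, {
    idx <- sample(40, 20)
    mann_whitney(vals[idx], vals[-idx])$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Wilcoxon signed-rank: exact small-n null and approximation", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
  expect_equal(r$W, 15)
  expect_equal(r$p, 1 / 32)   # most extreme of 2^5 sign patterns

  expect_warning(z <- wilcoxon_signed_rank(rep(0, 4)), "zero")
  expect_equal(z$p, 1)

  # approximation at n = 13 close to the exact sign enumeration
  set.seed(88)
  for (i in 1:5) {
    d <- round(rnorm(13, 0.3), 3)
    d <- d[d != 0]; n <- length(d)
    got <- wilcoxon_signed_rank(d)$p
    rk <- rank(abs(d))
    w_obs <- sum(rk[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    w_all <- as.matrix(signs) %*% rk
    mu <- n * (n + 1) / 4
    p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    expect_lt(abs(got - p_exact), 0.02)
  }
})

test_that("cohort contingency summary reproduces printed percentages", {
  counts <- rbind(LPA = c(78, 22), MP = c(5, 17))
  s <- summarize_cohort(counts)
  expect_equal(s$row_pct_neg[s$category == "LPA"], 78.0)
  expect_equal(s$row_pct_pos[s$category == "MP"], 77.3)
  expect_true(all(s$chisq_p >= 0 & s$chisq_p <= 1))

  one_sided <- rbind(Solid = c(0, 9), Rest = c(100, 80))
  s2 <- summarize_cohort(one_sided)
  expect_equal(s2$row_pct_neg[1], 0)
  expect_equal(s2$row_pct_pos[1], 100)

  zero <- rbind(A = c(0, 0), B = c(5, 5))
  expect_warning(s3 <- summarize_cohort(zero), "zero-margin")
  expect_equal(nrow(s3), 1)
})
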