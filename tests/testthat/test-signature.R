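test_that("sigmoid probability follows its formula", {
  expect_equal(sigmoid_probability(0), 0.5)
  expect_equal(sigmoid_probability(2), 0.880797, tolerance = 1e-6)
  for (x in c(-5, -0.3, 0.7, 4))
    expect_equal(sigmoid_probability(x) + sigmoid_probability(-x), 1)
})

test_that("the RBF signature separates a separable toy problem", {
  set.seed(71)
  n <- 40
  tab <- data.frame(f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                    f2 = rnorm(n))
  lab <- factor(rep(c("VPI-", "VPI+"), each = n / 2),
                levels = c("VPI-", "VPI+"))
  m <- fit_signature(tab, lab, c("f1", "f2"), gamma = 0.1, cost = 10)
  pred <- predict_signature(m, tab)
  expect_equal(mean((pred$pi >= 0.5) == (lab == "VPI+")), 1)
  expect_true(all(pred$pi > 0 & pred$pi < 1))
  # Pi is a strictly monotone transform of the decision value
  expect_identical(order(pred$pi), order(pred$x))
  expect_error(fit_signature(tab[lab == "VPI+", ], lab[lab == "VPI+"],
                             c("f1", "f2")), "both classes")
})

test_that("duplicating every training row leaves the decision function unchanged", {
  set.seed(72)
  tab <- data.frame(f1 = c(rnorm(20, -3), rnorm(20, 3)),
                    f2 = rnorm(40))
  lab <- factor(rep(c("VPI-", "VPI+"), each = 20),
                levels = c("VPI-", "VPI+"))
  tab2 <- rbind(tab, tab)
  lab2 <- factor(c(as.character(lab), as.character(lab)),
                 levels = c("VPI-", "VPI+"))
  # with a separable problem and a cost high enough that no support
  # vector is at its box bound, the solution depends only on the set of
  # distinct training points, so duplication changes nothing
  m1 <- fit_signature(tab, lab, c("f1", "f2"), gamma = 0.1, cost = 100)
  m2 <- fit_signature(tab2, lab2, c("f1", "f2"), gamma = 0.1, cost = 100)
  grid <- data.frame(f1 = seq(-4, 4, length.out = 25), f2 = 0)
  expect_equal(predict_signature(m1, grid)$x,
               predict_signature(m2, grid)$x, tolerance = 1e-8)
})

test_that("cross-validation bookkeeping: one validation per case per repeat", {
  set.seed(73)
  spec <- feature_cohort_spec(n_vpi_neg = 25, n_vpi_pos = 20,
                              n_noise_features = 5, seed = 19)
  tab <- generate_feature_cohort(spec)
  plan <- cv_plan(n_repeats = 3, n_folds = 5, seed = 7)
  cv <- cross_validate(tab, plan, gamma = 0.01, cost = 10)
  counts <- table(cv$records$case_id)
  expect_true(all(counts == 3))
  expect_equal(nrow(cv$records), 45 * 3)
  # per repeat, folds partition the cases
  for (r in 1:3) {
    rr <- cv$records[cv$records$repeat_id == r, ]
    expect_setequal(rr$case_id, tab$case_id)
  }
  # mean aggregation
  one <- cv$records[cv$records$case_id == "case0001", "pi"]
  expect_equal(cv$case_pi$pi[cv$case_pi$case_id == "case0001"], mean(one))
  expect_error(cross_validate(tab, cv_plan(n_folds = 30)), "too small")
})

test_that("validation-fold labels never leak into training", {
  set.seed(74)
  spec <- feature_cohort_spec(n_vpi_neg = 20, n_vpi_pos = 20,
                              n_noise_features = 4, seed = 23)
  tab <- generate_feature_cohort(spec)
  folds <- list(rep_len(1:4, 40))
  plan <- cv_plan(n_repeats = 1, n_folds = 4, seed = 1)
  cv1 <- cross_validate(tab, plan, folds = folds, gamma = 0.01, cost = 10)
  # corrupt the labels of the cases validated in fold 1
  tab2 <- tab
  in_fold1 <- folds[[1]] == 1
  tab2$label[in_fold1] <-
    factor(ifelse(tab$label[in_fold1] == "VPI+", "VPI-", "VPI+"),
           levels = levels(tab$label))
  cv2 <- cross_validate(tab2, plan, folds = folds, gamma = 0.01, cost = 10)
  r1 <- cv1$records[cv1$records$fold == 1, ]
  r2 <- cv2$records[cv2$records$fold == 1, ]
  expect_equal(r1$x[order(r1$case_id)], r2$x[order(r2$case_id)],
               tolerance = 1e-12)
})

test_that("label shuffling destroys the cross-validated signal", {
  set.seed(75)
  spec <- feature_cohort_spec(n_vpi_neg = 30, n_vpi_pos = 30,
                              n_noise_features = 3, seed = 29)
  tab <- generate_feature_cohort(spec)
  aucs <- replicate(5, {
    tab$label <- sample(tab$label)
    cv <- cross_validate(tab, cv_plan(n_repeats = 1, n_folds = 5,
                                      seed = sample.int(1000, 1)),
                         gamma = 0.01, cost = 10)
    concordance_index(cv$case_pi$pi, cv$case_pi$label)
  })
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("repeat-averaged signatures vary less than single repeats", {
  set.seed(76)
  fp <- table2_feature_params()
  fp$mean_pos <- fp$mean_neg; fp$sd_pos <- fp$sd_neg  # null cohort
  tab <- generate_feature_cohort(
    feature_cohort_spec(n_vpi_neg = 25, n_vpi_pos = 25,
                        feature_params = fp, n_noise_features = 3,
                        seed = 31))
  cv <- cross_validate(tab, cv_plan(n_repeats = 4, n_folds = 5, seed = 3),
                       gamma = 0.01, cost = 10)
  per_case_sd <- aggregate(pi ~ case_id, data = cv$records, FUN = sd)
  expect_gt(mean(per_case_sd$pi), 0)   # repeats genuinely differ
  expect_lt(var(cv$case_pi$pi), var(cv$records$pi))
})

test_that("ROC cut-off maximizes Youden with ties to specificity", {
  cut <- roc_cutoff(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cut$pi_cutoff, 0.5)
  expect_equal(cut$youden, 1)
  expect_equal(sigmoid_probability(cut$roc_cutoff), cut$pi_cutoff)

  flat <- roc_cutoff(rep(0.4, 6), c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_false(flat$informative)
  expect_equal(flat$youden, 0)

  # exhaustive scan oracle on the 4-point toy: both candidate cut-offs
  # reach Youden 0.5; the tie goes to the higher cut-off
  toy <- roc_cutoff(c(0.9, 0.6, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(toy$youden, 0.5)
  expect_gt(toy$pi_cutoff, 0.6)

  expect_error(roc_cutoff(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
})

test_that("risk stratification is a monotone threshold rule", {
  pi <- c(0.1, 0.4, 0.6, 0.9)
  expect_identical(as.character(stratify_risk(pi, 0.5)),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(stratify_risk(pi, 0.05)), rep("high", 4))
  g1 <- stratify_risk(pi, 0.3); g2 <- stratify_risk(pi, 0.7)
  expect_true(all(!(g1 == "low" & g2 == "high")))

  # with a perfectly separated toy the groups recover the labels
  cut <- roc_cutoff(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  grp <- stratify_risk(c(0.9, 0.8, 0.2, 0.1), cut$pi_cutoff)
  expect_identical(grp == "high", c(TRUE, TRUE, FALSE, FALSE))
})

test_that("AUC is invariant under the sigmoid transform", {
  set.seed(77)
  x <- rnorm(60)
  lab <- runif(60) < 0.4
  if (!any(lab)) lab[1] <- TRUE
  expect_equal(concordance_index(x, lab),
               concordance_index(sigmoid_probability(x), lab))
})
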