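#' Sigmoid probability of a classifier decision value
#'
#' `Pi = 1 / (1 + exp(-x))`, mapping the raw SVM decision value to the
#' probability scale. `Pi` is the radiomic signature value of a case.
#'
#' @param x numeric decision value(s).
#' @return numeric in (0, 1), strictly increasing in `x`.
#' @export
#' @examples
#' sigmoid_probability(0)    # 0.5
sigmoid_probability <- function(x) {
  stats::plogis(x)
}

#' Cross-validation plan
#'
#' Repeated stratified k-fold cross-validation: per repeat every case
#' appears in exactly one validation fold.
#'
#' @param n_repeats number of repeats (default 10).
#' @param n_folds folds per repeat (default 10).
#' @param stratified keep class proportions within folds (default TRUE).
#' @param seed integer seed governing all fold assignments.
#' @return A list of class `cv_plan`.
#' @export
cv_plan <- function(n_repeats = 10L, n_folds = 10L, stratified = TRUE,
                    seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# decision values from an e1071 svm, oriented so larger = positive class
oriented_decision <- function(fit, x, positive) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  flip <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1] != positive
  if (flip) -dv[, 1] else dv[, 1]
}

# stratified k-fold assignment; returns integer fold id per case
fold_assignment <- function(labels, n_folds, stratified) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Fit the RBF-SVM radiomic signature model
#'
#' Trains a support-vector machine with radial basis kernel
#' `k(x, x') = exp(-gamma |x - x'|^2)` on the selected features.
#' Features are standardized with the training data's means and SDs
#' (stored in the model and re-applied at prediction). When `gamma`/`cost`
#' are not given they are chosen by an inner stratified 3-fold grid search
#' over `cost in {0.1, 1, 10, 100}` and `gamma in {0.001, 0.01, 0.1, 1}`,
#' maximizing inner-fold AUC.
#'
#' @param table data.frame with the feature columns.
#' @param labels two-class factor (positive class = second level).
#' @param features character vector of model features.
#' @param gamma,cost RBF kernel width and soft-margin parameter; `NULL`
#'   triggers the inner grid search.
#' @param inner_seed seed for the inner-search fold assignment.
#' @return A list of class `signature_model`: `features`, `center`,
#'   `scale`, `gamma`, `cost`, `fit`, `levels`, `n_support`.
#' @export
fit_signature <- function(table, labels, features, gamma = NULL,
                          cost = NULL, inner_seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("training data must contain both classes")
  x <- as.matrix(table[features])
  ctr <- colMeans(x)
  # population SD: standardization is then invariant to duplicating the
  # training rows, matching the package's population-moment convention
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  positive <- levels(labels)[2]

  if (is.null(gamma) || is.null(cost)) {
    grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                        gamma = c(0.001, 0.01, 0.1, 1))
    set.seed(inner_seed)
    fold <- fold_assignment(labels, n_folds = 3L, stratified = TRUE)
    auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      sc <- rep(NA_real_, length(labels))
      for (k in 1:3) {
        tr <- fold != k
        if (length(unique(labels[tr])) < 2) next
        fit <- e1071::svm(xs[tr, , drop = FALSE], labels[tr],
                          kernel = "radial", gamma = grid$gamma[g],
                          cost = grid$cost[g], scale = FALSE)
        sc[!tr] <- oriented_decision(fit, xs[!tr, , drop = FALSE],
                                     positive)
      }
      ok <- !is.na(sc)
      auc[g] <- if (length(unique(labels[ok])) == 2)
        pair_auc(sc[ok], labels[ok] == positive) else 0.5
    }
    best <- which.max(auc)
    cost <- grid$cost[best]
    gamma <- grid$gamma[best]
  }

  fit <- e1071::svm(xs, labels, kernel = "radial", gamma = gamma,
                    cost = cost, scale = FALSE)
  structure(list(features = features, center = ctr, scale = scl,
                 gamma = gamma, cost = cost, fit = fit,
                 levels = levels(labels), n_support = fit$tot.nSV),
            class = "signature_model")
}

#' Predict decision values and signature probabilities
#'
#' @param model a [fit_signature()] model.
#' @param table data.frame containing the model's feature columns.
#' @return data.frame with `x` (decision value, larger = positive class)
#'   and `pi` (sigmoid probability).
#' @export
predict_signature <- function(model, table) {
  xs <- scale(as.matrix(table[model$features]),
              center = model$center, scale = model$scale)
  dv <- oriented_decision(model$fit, xs, model$levels[2])
  data.frame(x = as.numeric(dv), pi = sigmoid_probability(as.numeric(dv)))
}

#' Repeated stratified cross-validation of the radiomic signature
#'
#' For every repeat, cases are assigned to stratified folds; within each
#' training split the features are re-standardized, re-selected
#' (redundancy pruning and SVM-RFE with the cumulative-weight stop) and
#' the RBF-SVM hyperparameters re-searched, so no information from a
#' validation fold leaks into its training split. Out-of-fold decision
#' values and sigmoid probabilities are recorded for every case in every
#' repeat; the final per-case signature is the mean `pi` over repeats.
#'
#' @param table feature table with `case_id` and `label` columns.
#' @param plan a [cv_plan()].
#' @param features candidate features (default: all numeric columns).
#' @param select run the in-fold feature selection (default TRUE; set
#'   FALSE to use `features` as-is in every fold).
#' @param ccc_values optional reproducibility values passed to the
#'   redundancy filter.
#' @param distance_threshold,stop selection parameters as in
#'   [select_features()].
#' @param gamma,cost fixed hyperparameters; `NULL` = in-fold grid search.
#' @param folds optional list of precomputed fold assignments (one
#'   integer vector per repeat), overriding the seeded stratified
#'   assignment.
#' @return A list of class `cv_result`: `records` (one row per case per
#'   repeat: `case_id`, `label`, `repeat_id`, `fold`, `x`, `pi`),
#'   `case_pi` (per-case mean `pi` with labels), `plan`,
#'   `selected_per_fold` (list of character vectors).
#' @export
cross_validate <- function(table, plan = cv_plan(), features = NULL,
                           select = TRUE, ccc_values = NULL,
                           distance_threshold = 0.05, stop = 0.80,
                           gamma = NULL, cost = NULL, folds = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  labels <- droplevels(as.factor(table$label))
  if (nlevels(labels) != 2) stop("need two classes")
  if (min(table(labels)) < plan$n_folds)
    stop("a class is too small for stratified ", plan$n_folds, "-fold CV")
  if (is.null(features)) {
    features <- setdiff(names(table), c("case_id", "label"))
    features <- features[vapply(table[features], is.numeric, logical(1))]
  }
  positive <- levels(labels)[2]

  records <- vector("list", plan$n_repeats * plan$n_folds)
  selected_per_fold <- vector("list", plan$n_repeats * plan$n_folds)
  ri <- 0L
  for (r in seq_len(plan$n_repeats)) {
    if (is.null(folds)) {
      set.seed(plan$seed + r)
      fold <- fold_assignment(labels, plan$n_folds, plan$stratified)
    } else {
      fold <- folds[[r]]
    }
    for (k in seq_len(plan$n_folds)) {
      ri <- ri + 1L
      tr <- fold != k
      train <- table[tr, , drop = FALSE]
      valid <- table[!tr, , drop = FALSE]
      if (length(unique(train$label)) < 2)
        stop("single-class training fold")
      feats <- features
      if (select) {
        kept <- redundancy_filter(train, feats, ccc_values = ccc_values,
                                  distance_threshold = distance_threshold)
        ranking <- svm_rfe_rank(train, train$label, kept)
        feats <- cumulative_weight_select(ranking, stop = stop)$selected
      }
      model <- fit_signature(train, train$label, feats,
                             gamma = gamma, cost = cost,
                             inner_seed = plan$seed + 1000L * r + k)
      pred <- predict_signature(model, valid)
      records[[ri]] <- data.frame(
        case_id = valid$case_id,
        label = valid$label,
        repeat_id = r, fold = k,
        x = pred$x, pi = pred$pi,
        stringsAsFactors = FALSE)
      selected_per_fold[[ri]] <- feats
    }
  }
  records <- do.call(rbind, records)
  agg <- stats::aggregate(pi ~ case_id, data = records, FUN = mean)
  lab <- table$label[match(agg$case_id, table$case_id)]
  case_pi <- data.frame(case_id = agg$case_id, label = lab,
                        pi = agg$pi, stringsAsFactors = FALSE)
  structure(list(records = records, case_pi = case_pi, plan = plan,
                 positive = positive,
                 selected_per_fold = selected_per_fold),
            class = "cv_result")
}

#' ROC-optimal cut-off of the signature (Youden index)
#'
#' Scans the midpoints between consecutive distinct signature values and
#' returns the cut-off maximizing the Youden index
#' (sensitivity + specificity - 1) for the rule `pi >= cutoff` = positive;
#' ties are broken toward the higher cut-off (higher specificity). The
#' cut-off is reported on both the probability scale (`pi_cutoff`) and
#' the decision scale (`roc_cutoff = logit(pi_cutoff)`).
#'
#' @param pi signature probabilities.
#' @param labels two-class factor/logical (positive = second level/TRUE).
#' @return List: `pi_cutoff`, `roc_cutoff`, `youden`, `informative`
#'   (FALSE when all values are identical and the Youden index is 0).
#' @export
roc_cutoff <- function(pi, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  u <- sort(unique(pi))
  if (length(u) == 1) {
    return(list(pi_cutoff = u, roc_cutoff = stats::qlogis(u),
                youden = 0, informative = FALSE))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  youden <- vapply(cand, function(cth) {
    sens <- mean(pi[pos] >= cth)
    spec <- mean(pi[!pos] < cth)
    sens + spec - 1
  }, numeric(1))
  best <- max(youden)
  cutoff <- max(cand[youden >= best - 1e-12])  # tie -> higher specificity
  list(pi_cutoff = cutoff, roc_cutoff = stats::qlogis(cutoff),
       youden = best, informative = best > 0)
}

#' Stratify cases into high- and low-risk groups
#'
#' @param pi signature probabilities.
#' @param pi_cutoff cut-off on the probability scale.
#' @return factor with levels `low`/`high`; `pi >= pi_cutoff` is high
#'   risk.
#' @export
stratify_risk <- function(pi, pi_cutoff) {
  factor(ifelse(pi >= pi_cutoff, "high", "low"), levels = c("low", "high"))
}

# interpret labels as logical positives (second factor level or TRUE)
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- droplevels(as.factor(labels))
  if (nlevels(f) > 2) stop("labels must be two-class")
  f == levels(f)[nlevels(f)]
}

# Mann-Whitney AUC with 1/2 for ties (shared by several modules)
pair_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
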