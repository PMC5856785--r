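#' Concordance correlation coefficient between two replicate measurements
#'
#' Agreement measure combining correlation with mean and scale shifts:
#' `ccc = 2 rho sigma_x sigma_y / (sigma_x^2 + sigma_y^2 + (mu_x - mu_y)^2)`.
#' Moments are population moments (divide by n), frozen for
#' reproducibility. Degenerate cases: zero variance in both replicates is
#' perfect agreement (ccc 1) when the means are equal and no agreement
#' (ccc 0) otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3 (replicate 1 and 2).
#' @return A list of class `ccc_result`: `ccc`, `mu_x`, `mu_y`, `sigma_x`,
#'   `sigma_y`, `rho`.
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))$ccc   # 4/7
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("replicates must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0) {
    rho <- NA_real_
    cc <- if (mx == my) 1 else 0
  } else if (vx == 0 || vy == 0) {
    rho <- NA_real_
    cc <- 0
  } else {
    rho <- sxy / sqrt(vx * vy)
    cc <- 2 * sxy / (vx + vy + (mx - my)^2)
  }
  structure(list(ccc = cc, mu_x = mx, mu_y = my,
                 sigma_x = sqrt(vx), sigma_y = sqrt(vy), rho = rho),
            class = "ccc_result")
}

#' Reproducibility filter: keep the most stable features by CCC
#'
#' Computes the concordance correlation coefficient of every feature
#' between two replicate extractions of the same cases (for example two
#' readers' independent segmentations) and keeps the features with
#' `ccc >= threshold`, ranked by ccc descending and truncated to `cap`.
#' Ties are broken by catalog (column) order.
#'
#' @param rep1,rep2 data.frames with identical feature columns, rows
#'   paired by position (same cases).
#' @param features character vector of feature columns to assess
#'   (default: all shared numeric columns except `case_id`/`label`).
#' @param cap maximum number of features kept (default 100).
#' @param threshold minimum ccc (default 0.9).
#' @return A list: `kept` (character), `ccc` (named numeric, all assessed
#'   features).
#' @export
reproducibility_filter <- function(rep1, rep2, features = NULL,
                                   cap = 100L, threshold = 0.9) {
  if (is.null(features)) {
    features <- setdiff(intersect(names(rep1), names(rep2)),
                        c("case_id", "label"))
    features <- features[vapply(rep1[features], is.numeric, logical(1))]
  }
  if (nrow(rep1) != nrow(rep2)) stop("replicate tables must be row-paired")
  cc <- vapply(features, function(f) ccc(rep1[[f]], rep2[[f]])$ccc,
               numeric(1))
  ord <- order(-cc, seq_along(cc))   # ccc descending, catalog order on ties
  kept <- features[ord][cc[ord] >= threshold]
  kept <- kept[seq_len(min(length(kept), cap))]
  list(kept = kept, ccc = cc)
}

#' Redundancy filter: prune near-duplicate features
#'
#' Features are standardized to zero mean and unit variance, pairwise
#' correlation distance `1 - |r|` is computed, and while any surviving
#' pair is closer than `distance_threshold` the member with the lower
#' reproducibility (CCC) is dropped; without CCC values, or on ties, the
#' feature later in catalog order is dropped. Constant features cannot be
#' standardized and are dropped with a warning.
#'
#' @param table data.frame containing the feature columns.
#' @param features character vector of candidate features (order = catalog
#'   order).
#' @param ccc_values optional named numeric used to decide which member of
#'   a redundant pair is dropped.
#' @param distance_threshold minimum allowed correlation distance
#'   (default 0.05).
#' @return Character vector of surviving features.
#' @export
redundancy_filter <- function(table, features, ccc_values = NULL,
                              distance_threshold = 0.05) {
  x <- as.matrix(table[features])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(features[sds == 0], collapse = ", "))
    features <- features[sds > 0]
    x <- x[, sds > 0, drop = FALSE]
  }
  if (length(features) < 2) return(features)
  d <- 1 - abs(stats::cor(x))
  diag(d) <- Inf
  alive <- rep(TRUE, length(features))
  prio <- if (is.null(ccc_values)) rep(0, length(features)) else
    ccc_values[features]
  repeat {
    dd <- d
    dd[!alive, ] <- Inf
    dd[, !alive] <- Inf
    if (min(dd) >= distance_threshold) break
    pair <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- pair[1]; j <- pair[2]
    # drop lower CCC; tie -> later catalog order
    drop <- if (prio[i] < prio[j]) i else if (prio[j] < prio[i]) j else
      max(i, j)
    alive[drop] <- FALSE
  }
  features[alive]
}

#' SVM-RFE feature ranking with contribution weights
#'
#' Recursive feature elimination with a linear maximum-margin classifier:
#' at each iteration a linear SVM is trained on the surviving features and
#' the feature with the smallest squared weight is eliminated. The
#' contribution weight `omega` of a feature is its squared weight at the
#' moment of elimination, normalized over all features to sum 1; the
#' ranking is the reverse elimination order (rank 1 = eliminated last).
#' Features are standardized internally on the supplied data.
#'
#' @param table data.frame containing the feature columns.
#' @param labels two-class factor, one entry per row.
#' @param features character vector of features to rank.
#' @param cost soft-margin parameter of the linear SVM. The default 0.01
#'   regularizes heavily, which keeps the weight ordering stable when the
#'   number of candidate features is comparable to the number of cases
#'   (with a small cost the margin direction shrinks toward the
#'   class-centroid difference, so weak but real effects are not knocked
#'   out by noise features early in the elimination).
#' @return A data.frame `rfe_ranking`: `feature`, `rank`, `omega`
#'   (ordered by rank).
#' @export
svm_rfe_rank <- function(table, labels, features, cost = 0.01) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if (min(table(labels)) < 2) stop("need >= 2 cases per class")
  x <- scale(as.matrix(table[features]))
  x[is.nan(x)] <- 0   # constant columns carry no margin information
  remaining <- features
  elim_w2 <- numeric(length(features))
  names(elim_w2) <- features
  elim_order <- character(0)
  while (length(remaining) > 1) {
    fit <- e1071::svm(x[, remaining, drop = FALSE], labels,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    w2 <- w^2
    worst <- remaining[which.min(w2)]
    elim_w2[worst] <- min(w2)
    elim_order <- c(elim_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  # last survivor: weight from the final one-feature model
  fit <- e1071::svm(x[, remaining, drop = FALSE], labels,
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)[1, ]
  elim_w2[remaining] <- w^2
  elim_order <- c(elim_order, remaining)

  omega <- elim_w2 / sum(elim_w2)
  ranked <- rev(elim_order)
  data.frame(feature = ranked,
             rank = seq_along(ranked),
             omega = unname(omega[ranked]),
             stringsAsFactors = FALSE)
}

#' Select the top-ranked features by cumulative contribution weight
#'
#' Takes the shortest prefix of the RFE ranking whose cumulative
#' contribution weight reaches the stop threshold.
#'
#' @param rfe_ranking data.frame from [svm_rfe_rank()].
#' @param stop cumulative-omega stop threshold in (0, 1] (default 0.80).
#' @param fixed_k optional integer: select exactly `k` top features
#'   instead of using the cumulative-weight rule.
#' @return A list: `selected` (character), `cumulative_weight`.
#' @export
cumulative_weight_select <- function(rfe_ranking, stop = 0.80,
                                     fixed_k = NULL) {
  if (nrow(rfe_ranking) == 0) stop("empty ranking")
  if (!is.null(fixed_k)) {
    k <- min(fixed_k, nrow(rfe_ranking))
  } else {
    cw <- cumsum(rfe_ranking$omega)
    k <- which(cw >= stop - 1e-12)[1]
    if (is.na(k)) k <- nrow(rfe_ranking)
  }
  list(selected = rfe_ranking$feature[seq_len(k)],
       cumulative_weight = sum(rfe_ranking$omega[seq_len(k)]))
}

#' Three-stage feature selection report
#'
#' Runs the full reduction used for the radiomic signature: CCC
#' reproducibility filter (when replicate tables are supplied), redundancy
#' pruning, SVM-RFE ranking and the cumulative-weight stop.
#'
#' @param table feature table with `label` column (and feature columns).
#' @param rep1,rep2 optional replicate tables for the CCC stage.
#' @param features candidate features (default: all numeric columns
#'   except `case_id`/`label`).
#' @param ccc_threshold,ccc_cap,distance_threshold,stop stage parameters,
#'   defaulting to ccc >= 0.9 capped at 100 features, correlation distance
#'   0.05, cumulative omega 0.80.
#' @return A list of class `selection_report` with `kept_after_ccc`,
#'   `kept_after_redundancy`, `rfe_ranking`, `selected`,
#'   `cumulative_weight`, `ccc`.
#' @export
select_features <- function(table, rep1 = NULL, rep2 = NULL,
                            features = NULL,
                            ccc_threshold = 0.9, ccc_cap = 100L,
                            distance_threshold = 0.05, stop = 0.80) {
  if (is.null(features)) {
    features <- setdiff(names(table), c("case_id", "label"))
    features <- features[vapply(table[features], is.numeric, logical(1))]
  }
  ccc_values <- NULL
  if (!is.null(rep1) && !is.null(rep2)) {
    rf <- reproducibility_filter(rep1, rep2, features = features,
                                 cap = ccc_cap, threshold = ccc_threshold)
    kept_ccc <- rf$kept
    ccc_values <- rf$ccc
  } else {
    kept_ccc <- features
  }
  kept_red <- redundancy_filter(table, kept_ccc, ccc_values = ccc_values,
                                distance_threshold = distance_threshold)
  ranking <- svm_rfe_rank(table, table$label, kept_red)
  sel <- cumulative_weight_select(ranking, stop = stop)
  structure(list(kept_after_ccc = kept_ccc,
                 kept_after_redundancy = kept_red,
                 rfe_ranking = ranking,
                 selected = sel$selected,
                 cumulative_weight = sel$cumulative_weight,
                 ccc = ccc_values),
            class = "selection_report")
}
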