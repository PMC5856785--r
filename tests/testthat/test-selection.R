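test_that("concordance correlation coefficient closed forms", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3))$ccc, 1)
  # rho = 1, equal spreads, mean gap 1: 2*(2/3) / (2/3 + 2/3 + 1) = 4/7
  r <- ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$ccc, 4 / 7)
  expect_equal(r$rho, 1)
  expect_equal(r$sigma_x^2, 2 / 3)
  x <- c(-2, 0, 2)
  expect_equal(ccc(x, -x)$ccc, -1)
  # degenerate spreads
  expect_equal(ccc(c(5, 5, 5), c(5, 5, 5))$ccc, 1)
  expect_equal(ccc(c(5, 5, 5), c(7, 7, 7))$ccc, 0)
  expect_error(ccc(1:3, 1:4), "equal length")
  expect_error(ccc(1:2, 1:2), "at least 3")
})

test_that("ccc is symmetric and invariant to a shared affine map", {
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(20); y <- x + rnorm(20, sd = 0.3)
    expect_equal(ccc(x, y)$ccc, ccc(y, x)$ccc)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(ccc(a * x + b, a * y + b)$ccc, ccc(x, y)$ccc,
                 tolerance = 1e-12)
    expect_lte(abs(ccc(x, y)$ccc), abs(ccc(x, y)$rho) + 1e-12)
  }
})

test_that("reproducibility filter keeps stable features only", {
  set.seed(62)
  n <- 500
  base <- data.frame(stable1 = rnorm(n), stable2 = rnorm(n),
                     noisefeat = rnorm(n))
  rep2 <- data.frame(stable1 = base$stable1 + rnorm(n, sd = 0.05),
                     stable2 = base$stable2 + rnorm(n, sd = 0.05),
                     noisefeat = rnorm(n))   # independent redraw
  rf <- reproducibility_filter(base, rep2)
  expect_true(all(c("stable1", "stable2") %in% rf$kept))
  expect_false("noisefeat" %in% rf$kept)
  expect_lt(rf$ccc["noisefeat"], 0.3)

  # identical tables: everything at ccc 1, cap and tie-break by order
  rf2 <- reproducibility_filter(base, base, cap = 2)
  expect_identical(rf2$kept, c("stable1", "stable2"))
  # unreachable threshold empties the set
  rf3 <- reproducibility_filter(base, rep2, threshold = 1.0)
  expect_length(rf3$kept, 0)
  # raising the threshold never enlarges the kept set
  rf_lo <- reproducibility_filter(base, rep2, threshold = 0.5)
  expect_true(all(rf$kept %in% rf_lo$kept))
})

test_that("redundancy filter prunes near-duplicates and only those", {
  set.seed(63)
  n <- 1000
  tab <- data.frame(a = rnorm(n))
  tab$b <- tab$a                      # duplicate
  tab$c <- -tab$a                     # negation: |r| = 1
  tab$d <- rnorm(n)                   # independent
  kept <- redundancy_filter(tab, c("a", "b", "c", "d"))
  expect_true("d" %in% kept)
  expect_length(intersect(kept, c("a", "b", "c")), 1)

  # independent features are untouched
  tab2 <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  kept2 <- redundancy_filter(tab2, names(tab2))
  expect_identical(kept2, names(tab2))

  # post-condition: no surviving pair closer than the threshold
  tab3 <- as.data.frame(matrix(rnorm(200 * 8), 200, 8))
  tab3$dup1 <- tab3$V1 + rnorm(200, sd = 0.01)
  kept3 <- redundancy_filter(tab3, names(tab3), distance_threshold = 0.05)
  d <- 1 - abs(cor(as.matrix(tab3[kept3])))
  diag(d) <- Inf
  expect_gte(min(d), 0.05)

  # CCC decides which member of a pair dies
  cccv <- c(a = 0.5, b = 0.99, c = 0.7, d = 0.9)
  kept4 <- redundancy_filter(tab, c("a", "b", "c", "d"), ccc_values = cccv)
  expect_true("b" %in% kept4)
  expect_false("a" %in% kept4)

  tab$e <- 1   # constant
  expect_warning(kept5 <- redundancy_filter(tab, c("d", "e")), "constant")
  expect_identical(kept5, "d")
})

test_that("SVM-RFE ranks an informative feature above pure noise", {
  set.seed(64)
  hits <- 0
  for (s in 1:20) {
    n <- 100
    lab <- factor(rep(c("VPI-", "VPI+"), each = n / 2),
                  levels = c("VPI-", "VPI+"))
    tab <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    tab$signal <- ifelse(lab == "VPI+", 2, -2) + rnorm(n, sd = 0.5)
    rk <- svm_rfe_rank(tab, lab, names(tab))
    expect_equal(sum(rk$omega), 1)
    expect_true(all(rk$omega >= 0))
    if (rk$feature[1] == "signal") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("duplicated informative features both outrank noise", {
  set.seed(65)
  n <- 120
  lab <- factor(rep(c("VPI-", "VPI+"), each = n / 2))
  tab <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  sig <- ifelse(lab == "VPI+", 1.5, -1.5) + rnorm(n, sd = 0.5)
  tab$sig1 <- sig + rnorm(n, sd = 0.2)
  tab$sig2 <- sig + rnorm(n, sd = 0.2)
  rk <- svm_rfe_rank(tab, lab, names(tab))
  expect_lte(max(match(c("sig1", "sig2"), rk$feature)), 4)
})

test_that("cumulative-weight selection takes the shortest qualifying prefix", {
  rk <- data.frame(feature = letters[1:4], rank = 1:4,
                   omega = c(0.5, 0.3, 0.1, 0.1))
  sel <- cumulative_weight_select(rk, stop = 0.80)
  expect_identical(sel$selected, c("a", "b"))
  expect_equal(sel$cumulative_weight, 0.8)

  expect_identical(cumulative_weight_select(rk, stop = 1.0)$selected,
                   letters[1:4])
  unif <- data.frame(feature = letters[1:10], rank = 1:10,
                     omega = rep(0.1, 10))
  expect_length(cumulative_weight_select(unif, stop = 0.80)$selected, 8)
  expect_length(cumulative_weight_select(rk, fixed_k = 3)$selected, 3)
  expect_error(cumulative_weight_select(rk[0, ]), "empty")
})
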