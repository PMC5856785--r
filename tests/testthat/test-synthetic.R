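test_that("feature cohort reproduces the specified per-class moments", {
  spec <- feature_cohort_spec(n_vpi_neg = 200, n_vpi_pos = 200,
                              n_noise_features = 2, seed = 101)
  tab <- generate_feature_cohort(spec)
  expect_equal(nrow(tab), 400)
  fp <- table2_feature_params()
  neg <- tab$label == "VPI-"
  for (k in seq_len(nrow(fp))) {
    f <- fp$feature[k]
    expect_lt(abs(mean(tab[[f]][neg]) - fp$mean_neg[k]),
              3 * fp$sd_neg[k] / sqrt(200))
    expect_lt(abs(mean(tab[[f]][!neg]) - fp$mean_pos[k]),
              3 * fp$sd_pos[k] / sqrt(200))
  }
})

test_that("per-class means and SDs converge to spec values at large n", {
  spec <- feature_cohort_spec(n_vpi_neg = 10000, n_vpi_pos = 10000,
                              n_noise_features = 0, seed = 7)
  tab <- generate_feature_cohort(spec)
  fp <- table2_feature_params()
  neg <- tab$label == "VPI-"
  n <- 10000
  for (k in seq_len(nrow(fp))) {
    f <- fp$feature[k]
    # mean: SE = sd/sqrt(n); sd: SE ~ sd/sqrt(2n)
    expect_lt(abs(mean(tab[[f]][neg]) - fp$mean_neg[k]),
              3 * fp$sd_neg[k] / sqrt(n))
    expect_lt(abs(sd(tab[[f]][neg]) - fp$sd_neg[k]),
              3 * fp$sd_neg[k] / sqrt(2 * n))
    expect_lt(abs(sd(tab[[f]][!neg]) - fp$sd_pos[k]),
              3 * fp$sd_pos[k] / sqrt(2 * n))
  }
})

test_that("noise features are class-blind and zero noise_sd gives constants", {
  spec <- feature_cohort_spec(n_vpi_neg = 50, n_vpi_pos = 50,
                              n_noise_features = 3, noise_sd = 0, seed = 5)
  tab <- generate_feature_cohort(spec)
  expect_true(all(tab$noise001 == tab$noise001[1]))
  expect_error(feature_cohort_spec(noise_sd = -1), "noise_sd")
})

test_that("generators are deterministic under a fixed seed", {
  s <- feature_cohort_spec(n_vpi_neg = 20, n_vpi_pos = 20, seed = 42)
  expect_identical(generate_feature_cohort(s), generate_feature_cohort(s))
  ispec <- image_cohort_spec(n_per_class = 2, grid_shape = c(24, 24, 16),
                             nodule_radius_range = c(3, 5), seed = 9)
  c1 <- generate_image_cohort(ispec)
  c2 <- generate_image_cohort(ispec)
  expect_identical(c1$vois[[1]]$image, c2$vois[[1]]$image)
  expect_identical(c1$vois[[2]]$mask, c2$vois[[2]]$mask)
})

test_that("invalid cohort parameters are rejected", {
  expect_error(feature_cohort_spec(n_vpi_neg = 1), "2 cases")
  fp <- table2_feature_params()
  fp$sd_neg[1] <- 0
  expect_error(feature_cohort_spec(feature_params = fp), "deviations")
  expect_error(image_cohort_spec(grid_shape = c(16, 16, 12),
                                 nodule_radius_range = c(20, 30)),
               "fit")
})

test_that("class intensity shift separates mean intensity; null does not", {
  base <- image_cohort_spec(n_per_class = 25, grid_shape = c(24, 24, 16),
                            nodule_radius_range = c(3, 5),
                            class_intensity_shift = 200,
                            class_texture_scale = c(1.5, 1.5), seed = 31)
  co <- generate_image_cohort(base)
  m <- vapply(co$vois, function(v) mean(voi_values(v)), numeric(1))
  expect_gt(oracle_auc(m, co$labels == "VPI+"), 0.9)

  null_spec <- image_cohort_spec(n_per_class = 25,
                                 grid_shape = c(24, 24, 16),
                                 nodule_radius_range = c(3, 5),
                                 class_intensity_shift = 0,
                                 class_texture_scale = c(1.5, 1.5),
                                 seed = 32)
  co0 <- generate_image_cohort(null_spec)
  m0 <- vapply(co0$vois, function(v) mean(voi_values(v)), numeric(1))
  auc0 <- oracle_auc(m0, co0$labels == "VPI+")
  expect_gt(auc0, 0.3)
  expect_lt(auc0, 0.7)
})

test_that("segmentation perturbation behaves like a second reader", {
  co <- generate_image_cohort(
    image_cohort_spec(n_per_class = 10, grid_shape = c(24, 24, 16),
                      nodule_radius_range = c(3, 5), seed = 21))
  v <- co$vois[[1]]

  ident <- perturb_segmentation(v, perturbation_spec(0L, 0, seed = 1))
  expect_identical(ident$mask, v$mask)
  expect_identical(ident$image, v$image)
  expect_equal(ccc(voi_values(v), voi_values(ident))$ccc, 1)

  dil <- perturb_segmentation(v, perturbation_spec(1L, 0, seed = 1))
  expect_gt(sum(dil$mask), sum(v$mask))
  ero <- perturb_segmentation(v, perturbation_spec(-1L, 0, seed = 1))
  expect_lt(sum(ero$mask), sum(v$mask))
  expect_error(perturb_segmentation(v, perturbation_spec(-50L, 0, seed = 1)),
               "degenerate")

  # histogram-feature agreement decays monotonically with intensity noise
  feat <- function(noise_sd, seed_off) {
    vapply(seq_along(co$vois), function(i) {
      p <- perturb_segmentation(co$vois[[i]],
                                perturbation_spec(0L, noise_sd,
                                                  seed = 100 + seed_off * 50 + i))
      histogram_features(p)[["Perc.10%"]]
    }, numeric(1))
  }
  orig <- vapply(co$vois, function(v) histogram_features(v)[["Perc.10%"]],
                 numeric(1))
  ccc_lo <- ccc(orig, feat(5, 1))$ccc
  ccc_mid <- ccc(orig, feat(60, 2))$ccc
  ccc_hi <- ccc(orig, feat(400, 3))$ccc
  expect_gt(ccc_lo, ccc_mid)
  expect_gt(ccc_mid, ccc_hi)
})
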