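test_that("deviation series implements the replicate-error formulas", {
  d <- deviation_series(c(10, 12, 14))
  expect_equal(d$random_error, c(-2, 0, 2))
  expect_equal(d$random_error_pct, c(-2, 0, 2) / 12 * 100)
  expect_equal(deviation_series(c(5, 5, 5))$random_error, c(0, 0, 0))
  expect_error(deviation_series(7), "at least 2")
  expect_error(deviation_series(c(-1, 1)), "zero")
  expect_silent(deviation_series(c(-1, 1), pct = FALSE))
})

test_that("deviations always sum to zero", {
  set.seed(15)
  for (i in 1:1000) {
    v <- rnorm(sample(2:10, 1), mean = runif(1, -50, 50),
               sd = runif(1, 0.1, 20))
    if (mean(v) == 0) next
    expect_lt(abs(sum(deviation_series(v)$random_error)), 1e-9)
  }
})

test_that("pooled summaries reconstruct concatenated samples exactly", {
  # pooling a group with an identical copy keeps the mean; the sample SD
  # contracts by sqrt(2(n-1)/(2n-1)) because the SS doubles while the
  # divisor grows from n-1 to 2n-1 (verified against direct pooling below)
  p <- pooled_group_stats(7.5, 2.25, 9, 7.5, 2.25, 9)
  expect_equal(p$mean, 7.5)
  expect_equal(p$sd, 2.25 * sqrt(16 / 17))
  expect_error(pooled_group_stats(1, 1, 1, 2, 1, 5), "sizes")
  expect_error(pooled_group_stats(1, -1, 5, 2, 1, 5), "nonnegative")
  set.seed(16)
  for (i in 1:1000) {
    x <- rnorm(sample(2:12, 1), runif(1, -100, 100), runif(1, 0.5, 30))
    y <- rnorm(sample(2:12, 1), runif(1, -100, 100), runif(1, 0.5, 30))
    p <- pooled_group_stats(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y))
    expect_equal(p$mean, mean(c(x, y)), tolerance = 1e-12)
    expect_equal(p$sd, sd(c(x, y)), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney matches enumeration for small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
  # identical multisets (fully tied): z = 0, two-sided p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "empty")
  set.seed(17)
  for (i in 1:30) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- round(rnorm(nx), 3); y <- round(rnorm(ny, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney(x, y)$p_value, enum_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("outlier screen removes exactly the mu +/- 3 sigma exceedances", {
  v <- c(0, 0, 0, 0, 100)
  o <- screen_outliers(v)
  expect_equal(o$mu, 20)
  expect_length(o$removed, 0)       # 100 < 20 + 3 * 44.7
  expect_length(screen_outliers(rep(3, 10))$removed, 0)  # sigma = 0
  set.seed(18)
  z <- rnorm(10000)
  o2 <- screen_outliers(z)
  frac <- length(o2$removed) / length(z)
  expect_lt(abs(frac - 0.0027), 0.002)  # 3-sigma two-tail mass
  # affine invariance: same indices removed after rescaling
  o3 <- screen_outliers(5 + 13 * z)
  expect_identical(o2$removed, o3$removed)
})

test_that("Kruskal-Wallis H matches hand computation and k = 2 reduces
           to the tie-corrected normal Mann-Whitney", {
  kw <- kruskal_wallis_posthoc(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6),
                                    g3 = c(7, 8, 9)))
  expect_equal(unname(kw$statistic), 7.2)
  expect_equal(unname(kw$df), 2)
  expect_true(all(kw$posthoc$p_adj <= 1))
  expect_true(all(kw$posthoc$p_adj >= kw$posthoc$p_raw))
  expect_error(kruskal_wallis_posthoc(list(1:3)), "at least 2")
  expect_error(kruskal_wallis_posthoc(list(1:3, numeric(0))), "empty")
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(9, 0.6)
    kw2 <- kruskal_wallis_posthoc(list(x = x, y = y))
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    expect_lt(abs(kw2$p_value - mw$p.value), 0.01)
  }
})

test_that("Bonferroni-adjusted post hoc p-values are capped at one", {
  set.seed(20)
  groups <- lapply(1:5, function(i) rnorm(6))
  kw <- kruskal_wallis_posthoc(groups)
  expect_equal(nrow(kw$posthoc), choose(5, 2))
  expect_true(all(kw$posthoc$p_adj <= 1))
  expect_true(all(kw$posthoc$p_adj >= 0))
})

test_that("method comparison measures deviation from the reference mean", {
  cb <- c(100, 102, 98)
  expect_equal(bland_altman_method_compare(rep(100, 3), cb)$deviation,
               rep(0, 3))
  r <- bland_altman_method_compare(c(90, 95), cb)
  expect_equal(r$deviation, c(-10, -5))
  expect_equal(r$deviation_pct, c(-10, -5))
  expect_error(bland_altman_method_compare(1, numeric(0)), "empty")
  cl <- bland_altman_method_compare(c(90, 95, 99), cb, classical = TRUE)
  expect_equal(cl$classical$bias, mean(c(90, 95, 99) - cb))
  expect_length(cl$classical$limits, 2)
})

test_that("erosion-biased sphere replicates show the shell-volume deficit", {
  r <- 8; delta <- 0.4
  s <- icosphere(r, 3)
  mri <- modality_model("mri_like", erosion_bias = delta,
                        boundary_noise_sd = 0.02, intensity_noise_sd = 5)
  v_mri <- vapply(1:3, function(seed)
    mesh_volume(segment_volume(voxelize(s, mri, seed = seed))), 1)
  cbct <- modality_model("cbct_like", boundary_noise_sd = 0.02,
                         intensity_noise_sd = 5)
  v_cb <- vapply(4:6, function(seed)
    mesh_volume(segment_volume(voxelize(s, cbct, seed = seed))), 1)
  cmp <- bland_altman_method_compare(v_mri, v_cb)
  expect_true(all(cmp$deviation < 0))
  # first-order shell: deficit ~ delta * S(sphere)
  expect_lt(abs(mean(-cmp$deviation) / (delta * 4 * pi * r^2) - 1), 0.15)
})

test_that("the report validates design completeness and summarises groups", {
  set.seed(21)
  tab <- expand.grid(operator = c("A", "B"), modality = c("CBCT", "MRI"),
                     side = c("L", "R"), replicate = 1:3,
                     stringsAsFactors = FALSE)
  tab$S_mm2 <- rnorm(24, 800, 10)
  tab$V_mm3 <- rnorm(24, 1400, 50)
  rep <- build_report(tab)
  expect_s3_class(rep, "condyle_report")
  expect_equal(nrow(rep$groups), 4)
  expect_equal(rep$groups$n, rep(6, 4))
  g <- rep$groups[rep$groups$operator == "A" &
                  rep$groups$modality == "CBCT", ]
  sub <- tab[tab$operator == "A" & tab$modality == "CBCT", ]
  expect_equal(g$S_mean, mean(sub$S_mm2))
  expect_equal(g$V_sd, sd(sub$V_mm3))
  expect_true(all(is.finite(rep$pooled$p_value)))
  bad <- tab[-1, ]
  expect_error(build_report(bad), "missing cells")
  expect_error(validate_measurement_table(tab[, -5]), "missing columns")
  # CSV round trip
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "group_summary.csv")))
  tab2 <- read_measurement_table(file.path(dir, "measurements.csv"))
  expect_equal(tab2$S_mm2, tab$S_mm2)
})

test_that("distance fields feed the KW post hoc through outlier screening", {
  set.seed(22)
  flds <- list(a = distance_field(rnorm(200, 0, 0.1)),
               b = distance_field(rnorm(200, 0, 0.1)),
               c = distance_field(rnorm(200, 0.3, 0.1)))
  tab <- expand.grid(operator = c("A", "B"), modality = c("CBCT", "MRI"),
                     side = c("L", "R"), replicate = 1:3,
                     stringsAsFactors = FALSE)
  tab$S_mm2 <- rnorm(24, 800, 10); tab$V_mm3 <- rnorm(24, 1400, 50)
  rep <- build_report(tab, distance_fields = flds)
  expect_false(is.null(rep$distance_tests))
  ph <- rep$distance_tests$posthoc
  expect_equal(nrow(ph), 3)
  # the shifted group differs from both unshifted ones
  expect_lt(ph$p_adj[ph$group1 == "a" & ph$group2 == "c"], 0.001)
  expect_gt(ph$p_adj[ph$group1 == "a" & ph$group2 == "b"], 0.05)
})
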