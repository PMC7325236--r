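test_that("target_count counts all entries and rounds half away from zero", {
  expect_equal(target_count(random_beta_matrix(10, 100), 0.03), 30L)
  expect_equal(target_count(random_beta_matrix(7, 7), 0.03), 1L)
  expect_error(target_count(random_beta_matrix(5, 5), 1.5),
               class = "methylmiss_config_error")
  all_missing <- methyl_matrix(matrix(NA_real_, 5, 5), scale = "beta")
  expect_error(target_count(all_missing, 0.03),
               class = "methylmiss_infeasible_error")
  # pre-existing missing entries count toward the size but not the pool
  v <- unclass(random_beta_matrix(10, 10))
  v[1:40] <- NA
  expect_equal(target_count(methyl_matrix(v, scale = "beta"), 0.5), 50L)
  expect_error(target_count(methyl_matrix(v, scale = "beta"), 0.7),
               class = "methylmiss_infeasible_error")
})

test_that("simulate_mcar masks the exact count, uniquely, and reversibly", {
  x <- random_beta_matrix(20, 200, seed = 21)
  md <- simulate_mcar(x, 0.03, seed = 1)
  expect_equal(nrow(md$positions), round(0.03 * 20 * 200))
  expect_false(anyDuplicated(md$positions[c("row", "col")]) > 0)
  # masked entries are NA; everything else untouched
  v <- unclass(md$matrix)
  expect_true(all(is.na(v[cbind(md$positions$row, md$positions$col)])))
  expect_equal(sum(is.na(v)), nrow(md$positions))
  # truth matches the original values and restores bit-exactly
  expect_identical(md$positions$truth_beta,
                   unclass(x)[cbind(md$positions$row, md$positions$col)])
  expect_identical(unclass(restore_truth(md)), unclass(x))
  # determinism
  md2 <- simulate_mcar(x, 0.03, seed = 1)
  expect_identical(md$positions, md2$positions)
  # never re-masks already-missing entries
  v0 <- unclass(x)
  v0[1, 1:100] <- NA
  x0 <- methyl_matrix(v0, scale = "beta")
  md3 <- simulate_mcar(x0, 0.03, seed = 2)
  pre <- md3$positions$row == 1 & md3$positions$col <= 100
  expect_false(any(pre))
  # masking demands the beta scale
  expect_error(simulate_mcar(convert_matrix(x, "M")),
               class = "methylmiss_config_error")
})

test_that("MCAR masked values mirror the overall distribution (KS)", {
  coh <- generate_cohort(cohort_config(n_samples = 100, seed = 22))
  md <- simulate_mcar(coh$data, 0.03, seed = 3)
  ks <- suppressWarnings(
    stats::ks.test(md$positions$truth_beta, as.numeric(unclass(coh$data)))
  )
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("estimate_mar_weights follows the pseudocount formula", {
  mask <- matrix(FALSE, 4, 3)
  w <- estimate_mar_weights(mask)
  expect_equal(w$weight, rep(1 / 3, 3))
  mask2 <- matrix(FALSE, 4, 2)
  mask2[1:3, 1] <- TRUE
  mask2[1, 2] <- TRUE
  w2 <- estimate_mar_weights(mask2)
  expect_equal(w2$weight, c(0.7, 0.3))
  set.seed(23)
  mask3 <- matrix(runif(200) < 0.2, 10, 20)
  expect_equal(sum(estimate_mar_weights(mask3)$weight), 1, tolerance = 1e-12)
})

test_that("simulate_mar respects CpG propensities", {
  x <- random_beta_matrix(30, 500, seed = 24)
  # degenerate uniform weights: indistinguishable from the overall distribution
  coh <- generate_cohort(cohort_config(n_samples = 100, seed = 25))
  mdu <- simulate_mar(coh$data, 0.03, weights = rep(1, 5000), seed = 4)
  ks <- suppressWarnings(
    stats::ks.test(mdu$positions$truth_beta, as.numeric(unclass(coh$data)))
  )
  expect_lt(unname(ks$statistic), 0.03)
  # all weight on a subset: every masked position lies in it
  w <- rep(0, 500)
  s_set <- c(2, 77, 300, 301)
  w[s_set] <- 1
  mds <- simulate_mar(x, 0.005, weights = w, seed = 5)
  expect_true(all(mds$positions$col %in% s_set))
  expect_equal(nrow(mds$positions), round(0.005 * 30 * 500))
  # determinism, exact count, restorability
  md <- simulate_mar(x, 0.03, weights = runif(500), seed = 6)
  md2 <- simulate_mar(x, 0.03, weights = NULL, seed = 6) |> try(silent = TRUE)
  expect_s3_class(md2, "try-error")
  expect_identical(unclass(restore_truth(md)), unclass(x))
  expect_error(simulate_mar(x, 0.03, weights = rep(0, 500), seed = 1),
               class = "methylmiss_config_error")
  expect_error(simulate_mar(x, 0.03, weights = rep(-1, 500), seed = 1),
               class = "methylmiss_config_error")
})

test_that("MAR per-CpG masked counts match the weighted design (chi-square)", {
  x <- random_beta_matrix(200, 50, seed = 26)
  set.seed(27)
  w <- runif(50, 1, 3)
  counts <- rep(0, 50)
  n_target <- round(0.03 * 200 * 50)
  for (s in 1:20) {
    md <- simulate_mar(x, 0.03, weights = w, seed = 100 + s)
    counts <- counts + tabulate(md$positions$col, nbins = 50)
  }
  expected <- 20 * n_target * w / sum(w)
  chi2 <- sum((counts - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = 49, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("simulate_mnar draws from the in-range pool at the stated rate", {
  x <- random_beta_matrix(30, 500, seed = 28)
  # in_range_prob = 1 with an ample pool: all masked values in range
  md1 <- simulate_mnar(x, 0.01, beta_range = c(0.4, 0.6), in_range_prob = 1,
                       seed = 7)
  expect_true(all(md1$positions$truth_beta >= 0.4 &
                  md1$positions$truth_beta <= 0.6))
  expect_equal(md1$mechanism$n_redirected, 0L)
  # empty in-range pool from the start: all redirected, counter = target
  v <- matrix(runif(600, 0.7, 0.9), 20, 30)
  xe <- methyl_matrix(v, scale = "beta")
  mde <- simulate_mnar(xe, 0.05, beta_range = c(0, 0.2), in_range_prob = 0.7,
                       seed = 8)
  expect_equal(mde$mechanism$n_redirected, nrow(mde$positions))
  expect_equal(nrow(mde$positions), round(0.05 * 600))
  # partial exhaustion: with in_range_prob = 1 and a pool of exactly 10,
  # the draws after the 10th are redirected
  v2 <- matrix(runif(400, 0.7, 0.9), 20, 20)
  v2[1, 1:10] <- runif(10, 0.05, 0.15)
  x2 <- methyl_matrix(v2, scale = "beta")
  md2 <- simulate_mnar(x2, 0.075, beta_range = c(0, 0.2), in_range_prob = 1,
                       seed = 9)
  expect_equal(nrow(md2$positions), 30)
  expect_equal(sum(md2$positions$truth_beta <= 0.2), 10)
  expect_equal(md2$mechanism$n_redirected, 20L)
  # determinism and restorability
  md3 <- simulate_mnar(x, 0.03, seed = 10)
  md4 <- simulate_mnar(x, 0.03, seed = 10)
  expect_identical(md3$positions, md4$positions)
  expect_identical(unclass(restore_truth(md3)), unclass(x))
  expect_error(simulate_mnar(x, 0.03, beta_range = c(0.6, 0.4)),
               class = "methylmiss_config_error")
  expect_error(simulate_mnar(x, 0.03, in_range_prob = 1.4),
               class = "methylmiss_config_error")
})

test_that("simulate_missingness dispatches the five named mechanisms", {
  x <- random_beta_matrix(20, 100, seed = 29)
  w <- runif(100)
  for (mech in c("MCAR", "MAR", "MNAR_LOW", "MNAR_MID", "MNAR_HIGH")) {
    md <- simulate_missingness(x, mech, 0.03, weights = w, seed = 11)
    expect_equal(md$mechanism$kind, mech)
    expect_equal(nrow(md$positions), round(0.03 * 2000))
  }
  expect_error(simulate_missingness(x, "MAR", 0.03),
               class = "methylmiss_config_error")
  lo <- simulate_missingness(x, "MNAR_LOW", 0.03, seed = 12)
  expect_equal(lo$mechanism$beta_range, c(0, 0.2))
  expect_equal(lo$mechanism$in_range_prob, 0.70)
})

test_that("masked datasets serialize and load faithfully", {
  x <- random_beta_matrix(10, 40, seed = 30)
  md <- simulate_mcar(x, 0.05, seed = 13)
  prefix <- file.path(withr::local_tempdir(), "mask")
  write_masked_dataset(md, prefix)
  back <- read_masked_dataset(prefix)
  expect_equal(back$mechanism$kind, "MCAR")
  expect_equal(nrow(back$positions), nrow(md$positions))
  ord <- order(md$positions$row, md$positions$col)
  ord2 <- order(back$positions$row, back$positions$col)
  expect_equal(back$positions$truth_beta[ord2],
               md$positions$truth_beta[ord])
  expect_equal(unclass(back$matrix), unclass(md$matrix), tolerance = 1e-12)
})
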