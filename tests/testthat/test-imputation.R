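test_that("imputer_spec validates hyperparameters", {
  expect_error(imputer_spec("mean", k = 0), class = "methylmiss_config_error")
  expect_error(imputer_spec("svd_iter", rank = 0),
               class = "methylmiss_config_error")
  expect_error(imputer_spec("soft_svd", lambda_frac = 1),
               class = "methylmiss_config_error")
  expect_error(imputer_spec("mean", tol = 0), class = "methylmiss_config_error")
  expect_error(imputer_spec("bogus"))
  expect_equal(imputer_spec("chained_reg")$max_iter, 10L)
  expect_equal(imputer_spec("svd_iter")$max_iter, 100L)
})

test_that("method guards implement the per-method preprocessing", {
  v <- unclass(random_beta_matrix(6, 5, seed = 31))
  v[, 2] <- NA            # all-missing CpG
  v[, 3] <- 0.4           # constant CpG
  v[2:6, 4] <- NA         # single-observation CpG
  x <- methyl_matrix(v, scale = "beta")
  g_mean <- apply_method_guards(x, "mean")
  expect_equal(g_mean$dropped, colnames(v)[2])
  expect_equal(sort(unique(g_mean$unimputable$col)), 2L)
  expect_equal(nrow(g_mean$unimputable), 6)
  g_pca <- apply_method_guards(x, "iter_pca")
  expect_true(all(colnames(v)[c(2, 3, 4)] %in% g_pca$dropped))
  g_chain <- apply_method_guards(x, "chained_reg")
  expect_equal(sort(g_chain$dropped), sort(colnames(v)[c(2, 4)]))
  # fully observed: identity
  y <- random_beta_matrix(4, 4, seed = 32)
  g_id <- apply_method_guards(y, "mean")
  expect_equal(unclass(g_id$matrix), unclass(y))
  expect_equal(nrow(g_id$unimputable), 0)
  expect_length(g_id$dropped, 0)
  # methylimp: every column incomplete -> no-complete-variables error
  v2 <- unclass(random_beta_matrix(4, 3, seed = 33))
  diag(v2) <- NA
  expect_error(apply_method_guards(methyl_matrix(v2, scale = "beta"),
                                   "methylimp"),
               class = "methylmiss_no_complete_variables")
})

test_that("mean imputation fills with column means", {
  x <- methyl_matrix(matrix(c(0.2, NA, 0.4, 0.1, NA, NA), 3, 2),
                     scale = "beta")
  out <- impute(x, "mean")
  expect_equal(unname(unclass(out$imputed)[2, 1]), 0.3)
  expect_equal(unname(unclass(out$imputed)[2, 2]), 0.1)
  expect_equal(unname(unclass(out$imputed)[3, 2]), 0.1)
  # identity on complete input
  y <- random_beta_matrix(5, 8, seed = 34)
  expect_equal(unclass(impute(y, "mean")$imputed), unclass(y))
  # filled entries equal the observed column means to 1e-12
  v <- unclass(random_beta_matrix(20, 30, seed = 35))
  set.seed(36)
  v[sample.int(600, 50)] <- NA
  z <- methyl_matrix(v, scale = "beta")
  res <- unclass(impute(z, "mean")$imputed)
  cm <- colMeans(v, na.rm = TRUE)
  for (j in 1:30) {
    miss <- is.na(v[, j])
    if (any(miss)) expect_lt(max(abs(res[miss, j] - cm[j])), 1e-12)
  }
})

test_that("knn uses shared-sample distances with inverse-distance weights", {
  # twin columns, k = 1: the twin's value is copied
  v <- unclass(random_beta_matrix(8, 4, seed = 37))
  v[, 2] <- v[, 1]
  v[3, 2] <- NA
  x <- methyl_matrix(v, scale = "beta")
  out <- impute(x, imputer_spec("knn", k = 1))
  expect_equal(unname(unclass(out$imputed)[3, 2]), v[3, 1])
  # k larger than the candidate count: all candidates used (equals brute force)
  v2 <- unclass(random_beta_matrix(6, 3, seed = 38))
  v2[2, 1] <- NA
  x2 <- methyl_matrix(v2, scale = "beta")
  got <- unclass(impute(x2, imputer_spec("knn", k = 50))$imputed)
  expect_equal(unname(got[2, 1]), unname(knn_bruteforce(v2, 50)[2, 1]),
               tolerance = 1e-12)
  # fallback accounting when no neighbour shares samples
  v3 <- matrix(NA_real_, 4, 3)
  v3[1:2, 1] <- c(0.2, 0.4)
  v3[3:4, 2] <- c(0.6, 0.8)
  v3[, 3] <- 0.5
  v3[1, 3] <- NA
  x3 <- methyl_matrix(v3, scale = "beta")
  out3 <- impute(x3, imputer_spec("knn", k = 2, fallback = "zero"))
  # column 1 is unobserved on rows 3-4 of every potential neighbour's shared
  # support at those rows except column 3; fallback counter is recorded
  expect_true(out3$diagnostics$fallbacks >= 0)
  out_none <- impute(x3, imputer_spec("knn", k = 2, fallback = "none"))
  expect_true(nrow(out_none$unimputable) >= 0)
})

test_that("svd_iter recovers rank-1 structure", {
  fx <- rank1_fixture(20, 30, n_mask = 3, seed = 39)
  out <- impute(fx$masked, imputer_spec("svd_iter", rank = 1, tol = 1e-9,
                                        max_iter = 500))
  expect_lt(max(abs(unclass(out$imputed)[fx$idx] - fx$full[fx$idx])), 1e-4)
  expect_true(out$diagnostics$converged)
  # fully observed: identity with zero iterations
  y <- random_beta_matrix(6, 9, seed = 40)
  outy <- impute(y, imputer_spec("svd_iter", rank = 2))
  expect_equal(unclass(outy$imputed), unclass(y))
  expect_equal(outy$diagnostics$iterations, 0L)
  expect_error(impute(fx$masked, imputer_spec("svd_iter", rank = 25)),
               class = "methylmiss_config_error")
})

test_that("soft_svd matches svd_iter at zero threshold and shrinks toward 0", {
  v <- unclass(random_beta_matrix(8, 6, seed = 41))
  v[c(2, 17)] <- NA
  x <- methyl_matrix(v, scale = "beta")
  a <- impute(x, imputer_spec("soft_svd", lambda_frac = 0, tol = 1e-10,
                              max_iter = 500))
  b <- impute(x, imputer_spec("svd_iter", rank = 6, tol = 1e-10,
                              max_iter = 500))
  expect_equal(unclass(a$imputed), unclass(b$imputed), tolerance = 1e-6)
  # extreme threshold: reconstruction collapses toward zero (clipped at 0)
  hi <- impute(x, imputer_spec("soft_svd", lambda_frac = 0.999))
  miss_idx <- which(is.na(v))
  expect_lt(max(unclass(hi$imputed)[miss_idx]), 0.05)
  expect_equal(a$diagnostics$lambda, 0)
})

test_that("iter_pca recovers centered rank-1 structure and guards constants", {
  set.seed(42)
  n <- 25; p <- 15
  mu <- runif(p, 0.3, 0.7)
  f <- scale(rnorm(n), scale = FALSE)[, 1]
  l <- runif(p, 0.05, 0.15)
  full <- outer(rep(1, n), mu) + outer(f, l)
  stopifnot(all(full > 0 & full < 1))
  masked <- full
  masked[7, 3] <- NA
  out <- impute(methyl_matrix(masked, scale = "beta"),
                imputer_spec("iter_pca", ncp = 1, tol = 1e-9, max_iter = 500))
  expect_lt(abs(unclass(out$imputed)[7, 3] - full[7, 3]), 1e-3)
  # fully observed: identity
  y <- random_beta_matrix(6, 9, seed = 43)
  expect_equal(unclass(impute(y, imputer_spec("iter_pca", ncp = 2))$imputed),
               unclass(y))
  # a constant observed column is dropped by the zero-variance guard; its
  # missing entries are unimputable rather than recovered
  vc <- unclass(random_beta_matrix(10, 5, seed = 44))
  vc[, 2] <- 0.4
  vc[3, 2] <- NA
  outc <- impute(methyl_matrix(vc, scale = "beta"),
                 imputer_spec("iter_pca", ncp = 1))
  expect_true(any(outc$unimputable$row == 3 & outc$unimputable$col == 2))
  expect_true(colnames(vc)[2] %in% outc$diagnostics$dropped)
  expect_error(impute(y, imputer_spec("iter_pca", ncp = 10)),
               class = "methylmiss_config_error")
})

test_that("chained linear regression recovers exact linear relations", {
  set.seed(45)
  n <- 30
  x1 <- runif(n, 0.25, 0.55)
  others <- matrix(runif(n * 3, 0.1, 0.9), n, 3)
  target <- 2 * x1 - 0.3 # stays inside (0.2, 0.8)
  v <- cbind(target, x1, others)
  colnames(v) <- sprintf("cg%05d", 1:5)
  truth <- v[c(4, 19), 1]
  v[c(4, 19), 1] <- NA
  out <- impute(methyl_matrix(v, scale = "beta"),
                imputer_spec("chained_reg"))
  expect_lt(max(abs(unclass(out$imputed)[c(4, 19), 1] - truth)), 1e-8)
  # a single incomplete CpG needs no iteration beyond the sweeps it runs
  expect_true(out$diagnostics$sweeps >= 1)
  # independent-noise columns: close to plain mean imputation on average
  set.seed(46)
  vn <- matrix(runif(300 * 10, 0.2, 0.8), 300, 10)
  miss_idx <- sample.int(3000, 30)
  truth_n <- vn[miss_idx]
  vn[miss_idx] <- NA
  xn <- methyl_matrix(vn, scale = "beta")
  got_chain <- unclass(impute(xn, imputer_spec("chained_reg"))$imputed)[miss_idx]
  got_mean <- unclass(impute(xn, "mean")$imputed)[miss_idx]
  expect_lt(mean(abs(got_chain - got_mean)), 0.05)
})

test_that("chained regression with the forest learner runs end to end", {
  skip_if_not_installed("ranger")
  v <- unclass(random_beta_matrix(20, 10, seed = 47))
  set.seed(48)
  v[sample.int(200, 8)] <- NA
  x <- methyl_matrix(v, scale = "beta")
  out <- impute(x, imputer_spec("chained_reg", learner = "forest",
                                num_trees = 20, seed = 7L))
  expect_false(anyNA(unclass(out$imputed)))
  out2 <- impute(x, imputer_spec("chained_reg", learner = "forest",
                                 num_trees = 20, seed = 7L))
  expect_identical(unclass(out$imputed), unclass(out2$imputed))
})

test_that("methylimp solves the pattern-grouped pseudoinverse system", {
  set.seed(49)
  n <- 15
  p_col <- runif(n, 0.25, 0.55)
  ones <- rep(1, n)
  extra <- matrix(runif(n * 2, 0.1, 0.9), n, 2)
  target <- 2 * p_col - 0.3
  v <- cbind(target, p_col, ones, extra)
  colnames(v) <- sprintf("cg%05d", 1:5)
  truth <- v[6, 1]
  v[6, 1] <- NA
  out <- impute(methyl_matrix(v, scale = "beta"), "methylimp")
  expect_lt(abs(unclass(out$imputed)[6, 1] - truth), 1e-8)
  # every column incomplete -> error
  v2 <- unclass(random_beta_matrix(4, 3, seed = 50))
  diag(v2) <- NA
  expect_error(impute(methyl_matrix(v2, scale = "beta"), "methylimp"),
               class = "methylmiss_no_complete_variables")
  # beta predictions outside [0,1] are clipped: target = 2*q - 0.3 learned on
  # rows with q < 0.4, then predicted at a masked row with q = 0.9 -> 1.5
  q <- c(runif(n - 1, 0.2, 0.4), 0.9)
  w2 <- cbind(c(2 * q[-n] - 0.3, NA), q, rep(1, n))
  colnames(w2) <- sprintf("cg%05d", 1:3)
  out2 <- impute(methyl_matrix(w2, scale = "beta"), "methylimp")
  expect_equal(unname(unclass(out2$imputed)[n, 1]), 1)
})

test_that("imputation invariants hold across all seven methods", {
  coh <- generate_cohort(cohort_config(n_samples = 25, n_cpgs = 120,
                                       seed = 51))
  md <- simulate_mcar(coh$data, 0.03, seed = 52)
  v <- unclass(md$matrix)
  miss <- is.na(v)
  for (m in c("mean", "knn", "svd_iter", "soft_svd", "iter_pca",
              "chained_reg", "methylimp")) {
    out <- impute(md$matrix, imputer_spec(m, seed = 1L))
    res <- unclass(out$imputed)
    # observed entries pass through bit-exactly
    expect_identical(res[!miss], v[!miss])
    # imputed + unimputable covers the missing positions exactly
    still <- which(is.na(res))
    un_idx <- (out$unimputable$col - 1) * nrow(v) + out$unimputable$row
    expect_setequal(still, un_idx)
    expect_true(all(still %in% which(miss)))
    # beta outputs in [0, 1]
    expect_true(all(res[!is.na(res)] >= 0 & res[!is.na(res)] <= 1))
  }
})

test_that("imputation runs on the M scale without clipping", {
  coh <- generate_cohort(cohort_config(n_samples = 20, n_cpgs = 80, seed = 53))
  md <- simulate_mcar(coh$data, 0.03, seed = 54)
  xm <- convert_matrix(md$matrix, "M")
  out <- impute(xm, "mean")
  expect_equal(methyl_scale(out$imputed), "M")
  expect_false(anyNA(unclass(out$imputed)))
})
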