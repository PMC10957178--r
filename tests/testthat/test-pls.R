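test_that("cross-correlation matches hand Pearson and flags degenerate input", {
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3), 4, 2)
  Y <- matrix(c(1, 3, 2, 4), 4, 1)
  R <- cross_correlation(X, Y)
  expect_equal(dim(R), c(2, 1))
  expect_equal(R[1, 1], cor(X[, 1], Y[, 1]), tolerance = 1e-12)
  expect_equal(R[2, 1], cor(X[, 2], Y[, 1]), tolerance = 1e-12)

  # duplicated column appears as a perfect correlation
  X2 <- cbind(X, Y)
  expect_equal(cross_correlation(X2, Y)[3, 1], 1)

  withr::with_seed(1, {
    Xg <- matrix(rnorm(10000 * 20), 10000)
    Yg <- matrix(rnorm(10000 * 8), 10000)
  })
  expect_lt(max(abs(cross_correlation(Xg, Yg))), 0.05)

  expect_error(cross_correlation(cbind(X, 1), Y), "constant")
  expect_error(cross_correlation(X[1:2, ], Y[1:2, , drop = FALSE]), "3 subjects")
})

test_that("the decomposition satisfies its algebraic invariants", {
  expect_equal(pls_decompose(diag(3))$delta, c(1, 1, 1))
  expect_equal(pls_decompose(diag(3))$explained_variance, rep(1 / 3, 3))

  # construct R with known singular values (2, 1, 1)
  withr::with_seed(2, {
    A <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:3]
    B <- qr.Q(qr(matrix(rnorm(9), 3)))
  })
  R <- A %*% diag(c(2, 1, 1)) %*% t(B)
  dec <- pls_decompose(R)
  expect_equal(dec$explained_variance, c(4, 1, 1) / 6, tolerance = 1e-10)

  withr::with_seed(3, R2 <- matrix(rnorm(120), 12, 10))
  d2 <- pls_decompose(R2)
  k <- 10
  expect_equal(crossprod(d2$U), diag(k), tolerance = 1e-8)
  expect_equal(crossprod(d2$V), diag(k), tolerance = 1e-8)
  expect_equal(d2$U %*% diag(d2$delta) %*% t(d2$V), R2, tolerance = 1e-8)
  expect_equal(sum(d2$explained_variance), 1, tolerance = 1e-10)
  expect_true(all(diff(d2$delta) <= 1e-12))
  # independent eigen-oracle of R'R
  expect_equal(d2$delta^2, eigen(crossprod(R2), symmetric = TRUE)$values,
               tolerance = 1e-8)
  # sign convention: dominant clinical weight positive
  for (j in seq_len(k))
    expect_gt(d2$V[which.max(abs(d2$V[, j])), j], 0)
  expect_error(pls_decompose(matrix(c(1, NA), 1)), "finite")
})

test_that("flipping an input column's sign flips only the matching loadings", {
  withr::with_seed(4, {
    X <- matrix(rnorm(100 * 6), 100)
    Y <- matrix(rnorm(100 * 4), 100)
  })
  Y[, 1] <- 0.5 * X[, 1] + rnorm(100, sd = 0.5)
  base <- pls_decompose(cross_correlation(X, Y))
  Yf <- Y; Yf[, 2] <- -Yf[, 2]
  flip <- pls_decompose(cross_correlation(X, Yf))
  expect_equal(flip$delta, base$delta, tolerance = 1e-10)
  expect_equal(flip$explained_variance, base$explained_variance, tolerance = 1e-10)
  expect_equal(abs(flip$V), abs(base$V), tolerance = 1e-8)
})

test_that("permutation p-values are minimal for a strongly coupled cohort", {
  co <- gen_cohort(cohort_spec(1000, 20, 8, coupling_strength = 0.8,
                               noise_sd = 0.5, seed = 21))
  X <- zscore_columns(co$morph)
  Y <- zscore_columns(co$clinical)
  p <- permutation_pvalues(X, Y, n_perm = 99, seed = 1)
  expect_equal(p[1], 1 / 100)
  expect_error(permutation_pvalues(X, Y, n_perm = 0), "n_perm")
})

test_that("bootstrap ratios separate planted from null regions", {
  u <- c(rep(1, 5), rep(0, 15)); u <- u / sqrt(sum(u^2))
  co <- gen_cohort(cohort_spec(1500, 20, 8, coupling_strength = 0.8,
                               noise_sd = 0.5, latent_loadings_u = u, seed = 22))
  X <- zscore_columns(co$morph)
  Y <- zscore_columns(co$clinical)
  bs <- bootstrap_stability(X, Y, n_boot = 150, seed = 2)
  br <- abs(bs$boot_ratio[, 1])
  expect_true(all(br[1:5] > 1.96))
  expect_lt(mean(br[6:20] > 1.96), 0.25)
  # clinical CIs on LV1 exclude zero for the planted loadings
  v_signif <- sign(bs$v_ci[, 1, "lower"]) == sign(bs$v_ci[, 1, "upper"])
  expect_gt(mean(v_signif), 0.5)
})

test_that("subject scores are exact projections with bounded norm", {
  t_lat <- rnorm(50)
  X <- matrix(t_lat, 50, 1)
  sc <- subject_scores(X, X, matrix(1), matrix(1))
  expect_equal(drop(sc$scores_imaging), t_lat)

  withr::with_seed(6, {
    X2 <- matrix(rnorm(40 * 8), 40)
    Y2 <- matrix(rnorm(40 * 5), 40)
  })
  dec <- pls_decompose(cross_correlation(X2, Y2))
  sc2 <- subject_scores(X2, Y2, dec$U, dec$V)
  expect_lte(norm(sc2$scores_imaging, "F"), norm(X2, "F") + 1e-10)
  expect_error(subject_scores(X2, Y2, dec$U[1:3, ], dec$V), "dimension")
})

test_that("cross-validation finds coupling when present and not under the null", {
  co <- gen_cohort(cohort_spec(600, 20, 8, coupling_strength = 0.8,
                               noise_sd = 0.5, seed = 23))
  cv <- cross_validate(zscore_columns(co$morph), zscore_columns(co$clinical),
                       k = 10, seed = 3)
  expect_true(all(cv$fold_spearman[, 1] > 0))

  co0 <- gen_cohort(cohort_spec(1000, 20, 8, coupling_strength = 0, seed = 24))
  cv0 <- cross_validate(zscore_columns(co0$morph), zscore_columns(co0$clinical),
                        k = 10, seed = 4)
  expect_lt(abs(cv0$mean_spearman[1]), 0.08)
  expect_error(cross_validate(matrix(rnorm(30), 10), matrix(rnorm(20), 10), k = 10),
               "n >= 2k")
})

test_that("pls_fit assembles a coherent result object", {
  co <- gen_cohort(cohort_spec(300, 10, 6, coupling_strength = 0.8,
                               noise_sd = 0.5, seed = 25))
  fit <- pls_fit(zscore_columns(co$morph), zscore_columns(co$clinical),
                 n_perm = 50, n_boot = 50, cv_folds = 5, seed = 9)
  expect_s3_class(fit, "pls_result")
  expect_equal(length(fit$perm_p), 6)
  expect_equal(dim(fit$boot_ratio), c(10, 6))
  expect_equal(nrow(fit$scores_imaging), 300)
  expect_equal(sum(fit$explained_variance), 1, tolerance = 1e-10)
})
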