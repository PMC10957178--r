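test_that("k-NN imputation reproduces the hand-computed group-restricted mean", {
  tb <- data.frame(hdl = c(NA, 40, 50, 60, 70),
                   ldl = c(130, 131, 132, 133, 134),
                   chol = c(200, 201, 202, 203, 204),
                   tg = c(150, 151, 152, 153, 154))
  gr <- c(hdl = "lipids", ldl = "lipids", chol = "lipids", tg = "lipids")
  out <- impute_knn(tb, gr, k = 4)
  expect_equal(out$hdl[1], mean(c(40, 50, 60, 70)))
  expect_equal(out[-1, ], tb[-1, ], ignore_attr = TRUE)

  expect_identical(impute_knn(tb[-1, ], gr), tb[-1, ])  # nothing missing
  expect_equal(eval(formals(impute_knn)$k), 4L)
})

test_that("imputation distances respect the variable group", {
  # lipid-block neighbours of subject 1 are subjects 2:5; the obesity block
  # would instead rank subjects 6:9 closest. The imputed HDL must come from
  # the lipid-block neighbours.
  tb <- data.frame(
    hdl = c(NA, 10, 20, 30, 40, 100, 200, 300, 400),
    ldl = c(0, 0.1, -0.1, 0.2, -0.2, 50, 60, 70, 80),
    waist = c(100, 50, 60, 70, 80, 100.1, 99.9, 100.2, 99.8),
    bmi = c(30, 10, 12, 14, 16, 30.1, 29.9, 30.2, 29.8))
  gr <- c(hdl = "lipids", ldl = "lipids", waist = "obesity", bmi = "obesity")
  out <- impute_knn(tb, gr, k = 4)
  expect_equal(out$hdl[1], mean(c(10, 20, 30, 40)))
})

test_that("a fully missing group falls back to all clinical variables with a warning", {
  tb <- data.frame(hdl = c(NA, 40, 50, 60, 70), ldl = c(NA, 1, 2, 3, 4),
                   waist = c(100, 99, 101, 98, 102))
  gr <- c(hdl = "lipids", ldl = "lipids", waist = "obesity")
  expect_warning(out <- impute_knn(tb, gr, k = 2), "entirely missing")
  expect_false(anyNA(out))
})

test_that("k-NN beats mean imputation when variable groups are correlated", {
  # risk-factor variables within a group share a subject-level factor
  # (waist, hip, BMI move together), which is exactly the structure the
  # group-restricted k-NN exploits
  groups <- mets_variable_groups()
  errs <- sapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      n <- 400
      fac <- sapply(unique(groups), function(gr) rnorm(n))
      full <- sapply(names(groups), function(v)
        fac[, groups[[v]]] + 0.5 * rnorm(n))
      mask <- matrix(runif(length(full)) < 0.1, n)
    })
    obs <- full
    obs[mask] <- NA
    imp <- suppressWarnings(as.matrix(
      impute_knn(as.data.frame(obs), groups)[, colnames(full)]))
    mimp <- obs
    for (j in seq_len(ncol(mimp))) mimp[is.na(mimp[, j]), j] <- mean(mimp[, j], na.rm = TRUE)
    c(knn = sqrt(mean((imp[mask] - full[mask])^2)),
      mean = sqrt(mean((mimp[mask] - full[mask])^2)))
  })
  expect_true(all(errs["knn", ] < errs["mean", ]))
})

test_that("confound residualization matches OLS and is idempotent", {
  conf <- data.frame(age = c(1, 2, 3, 4, 5))
  y <- c(2, 1, 4, 3, 6)
  res <- residualize_confounds(matrix(y), conf)
  # normal-equations oracle
  dm <- cbind(1, conf$age)
  beta <- solve(t(dm) %*% dm, t(dm) %*% y)
  expect_equal(drop(res), drop(y - dm %*% beta), tolerance = 1e-12)

  withr::with_seed(5, {
    cf <- data.frame(age = rnorm(40), sex = rbinom(40, 1, 0.5),
                     education = sample(1:5, 40, TRUE), cohort = rbinom(40, 1, 0.5))
    x <- matrix(rnorm(40 * 6), 40)
  })
  x[, 1] <- 2 * cf$age
  r <- residualize_confounds(x, cf)
  expect_lt(max(abs(r[, 1])), 1e-10)
  # exact orthogonality to every confound
  expect_lt(max(abs(crossprod(scale(as.matrix(cf)), r))), 1e-8)
  # idempotence
  expect_equal(residualize_confounds(r, cf), r, tolerance = 1e-10)
  # a centered column orthogonal to all confounds passes through
  q <- qr.Q(qr(cbind(1, as.matrix(cf))))
  ortho <- x[, 2] - q %*% crossprod(q, x[, 2])
  r2 <- residualize_confounds(matrix(ortho), cf)
  expect_equal(drop(r2), drop(ortho), tolerance = 1e-10)

  cf_bad <- cbind(cf, age2 = cf$age * 1)
  expect_error(residualize_confounds(x, cf_bad), "rank deficient")
})

test_that("z-scoring uses sample SD and rejects constant columns", {
  expect_equal(drop(zscore_columns(matrix(1:3))), c(-1, 0, 1))
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(drop(zscore_columns(matrix(v))), (v - mean(v)) / sd(v))
  z <- zscore_columns(matrix(rnorm(20)))
  expect_equal(zscore_columns(z), z, tolerance = 1e-10)
  m <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(zscore_columns(m), "b")
})

test_that("cohort harmonization removes per-cohort location and scale", {
  v <- rnorm(30)
  expect_equal(harmonize_across_cohorts(v, rep("A", 30)),
               drop(scale(v)), ignore_attr = TRUE)
  vals <- c(10, 20, 30, 100, 200, 300)
  coh <- rep(c("A", "B"), each = 3)
  h1 <- harmonize_across_cohorts(vals, coh)
  h2 <- harmonize_across_cohorts(c(10, 20, 30, 1000, 2000, 3000), coh)
  expect_equal(h1, h2, tolerance = 1e-12)
  for (g in c("A", "B")) {
    step1 <- harmonize_across_cohorts(vals, coh)
    expect_equal(mean(scale(vals[coh == g])), 0, tolerance = 1e-12)
  }
  expect_error(harmonize_across_cohorts(c(1, 1, 1, 2, 3, 4), coh), "constant")
})

test_that("metabolic-syndrome labels match the brute-force rule on all criterion patterns", {
  th <- mets_thresholds()
  grid <- expand.grid(ob = 0:1, tg = 0:1, hdl = 0:1, bp = 0:1, glu = 0:1)
  tb <- data.frame(
    sex = 1,
    waist = ifelse(grid$ob == 1, th$waist_male + 5, th$waist_male - 5),
    tg = ifelse(grid$tg == 1, th$tg + 10, th$tg - 10),
    hdl = ifelse(grid$hdl == 1, th$hdl_male - 5, th$hdl_male + 5),
    sbp = ifelse(grid$bp == 1, th$sbp + 5, th$sbp - 5),
    dbp = th$dbp - 10,
    glucose = ifelse(grid$glu == 1, th$glucose + 5, th$glucose - 5))
  labels <- classify_mets(tb)
  oracle <- grid$ob == 1 & (grid$tg + grid$hdl + grid$bp + grid$glu) >= 2
  expect_identical(labels, oracle)
  expect_false(labels[1])                      # below every threshold
  expect_true(labels[nrow(grid)])              # above every threshold
  expect_error(classify_mets(tb[, -2]), "waist")
})

test_that("treatment flags satisfy their criterion regardless of measurements", {
  th <- mets_thresholds()
  tb <- data.frame(sex = 0, waist = th$waist_female + 1, tg = th$tg + 1,
                   hdl = th$hdl_female + 5, sbp = 100, dbp = 60,
                   glucose = 80, bp_treatment = TRUE, glucose_treatment = FALSE)
  expect_true(classify_mets(tb))  # obesity + high TG + treated hypertension
})

test_that("case-control matching recovers exact copies and the greedy oracle", {
  withr::with_seed(2, {
    cov_cases <- data.frame(age = rnorm(5, 60, 5), sex = rbinom(5, 1, .5),
                            education = sample(1:5, 5, TRUE))
  })
  covs <- rbind(cov_cases, cov_cases)
  covs$subject_id <- c(paste0("case", 1:5), paste0("ctrl", 1:5))
  res <- match_cases_controls(paste0("case", 1:5), paste0("ctrl", 1:5), covs, seed = 1)
  expect_equal(res$pairs$control, paste0("ctrl", 1:5))
  expect_true(all(res$pairs$distance < 1e-8))
  expect_true(all(abs(res$balance$smd_after) < 1e-10))

  # 3 cases, distinct ages: enumerate the greedy pairing by hand
  covs2 <- data.frame(subject_id = c("a", "b", "c", "x", "y", "z"),
                      age = c(50, 60, 70, 52, 59, 71))
  res2 <- match_cases_controls(c("a", "b", "c"), c("x", "y", "z"), covs2, seed = 3)
  order_cases <- withr::with_seed(3, sample(c("a", "b", "c")))
  avail <- c("x", "y", "z")
  expected <- character(3); names(expected) <- order_cases
  for (cs in order_cases) {
    d <- abs(covs2$age[match(avail, covs2$subject_id)] -
               covs2$age[covs2$subject_id == cs])
    expected[cs] <- avail[which.min(d)]
    avail <- setdiff(avail, expected[cs])
  }
  expect_equal(res2$pairs$control, unname(expected[c("a", "b", "c")]))
  expect_identical(res2, match_cases_controls(c("a", "b", "c"), c("x", "y", "z"),
                                              covs2, seed = 3))
  expect_error(match_cases_controls(c("a", "b"), "x", covs2), "smaller")
})

test_that("group-difference t-maps match hand OLS and stay null for identical groups", {
  withr::with_seed(7, {
    morph <- matrix(rnorm(60 * 5), 60)
    conf <- data.frame(age = rnorm(60), sex = rbinom(60, 1, .5))
    labels <- rep(0:1, each = 30)
  })
  # literally identical groups: the group coefficient vanishes
  res0 <- group_difference_map(rbind(morph, morph), rep(0:1, each = 60),
                               rbind(conf, conf))
  expect_true(all(abs(res0$t) < 1e-8))
  expect_true(all(res0$q > 0.05))

  # single-parcel hand OLS
  y <- morph[, 1]
  dm <- cbind(1, labels, conf$age, conf$sex)
  beta <- solve(crossprod(dm), crossprod(dm, y))
  resid <- y - dm %*% beta
  s2 <- sum(resid^2) / (60 - 4)
  se <- sqrt(s2 * solve(crossprod(dm))[2, 2])
  t_hand <- beta[2] / se
  res <- group_difference_map(morph, labels, conf)
  expect_equal(res$t[1], drop(t_hand), tolerance = 1e-10)
})

test_that("planted group shifts are detected with FDR control", {
  hits <- sapply(1:5, function(s) {
    withr::with_seed(1000 + s, {
      morph <- matrix(rnorm(400 * 100), 400)
      labels <- rep(0:1, each = 200)
      conf <- data.frame(age = rnorm(400), sex = rbinom(400, 1, .5))
      morph[labels == 1, 1:10] <- morph[labels == 1, 1:10] + 1
    })
    res <- group_difference_map(morph, labels, conf)
    sum(res$q[1:10] < 0.05)
  })
  expect_true(all(hits >= 8))
})
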