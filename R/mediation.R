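#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with input validation, kept as the
#' single FDR entry point used across the mediation and contextualization
#' stages.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_invalid("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

ols_fit <- function(y, design) {
  qr_ <- qr(design)
  coef <- qr.coef(qr_, y)
  res <- qr.resid(qr_, y)
  df <- length(y) - qr_$rank
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qr_))))
  t <- coef / se
  list(coef = coef, se = se, t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Single-mediator bootstrap mediation
#'
#' Estimates the standardized paths of an x -> m -> y mediation model with
#' covariate adjustment: `a` from `m ~ x + covs`, `b` and the direct effect
#' `c'` from `y ~ x + m + covs`, and the total effect `c` from
#' `y ~ x + covs`; the indirect effect is `ab = a * b` and satisfies
#' `ab + c' = c` exactly (OLS identity on a common sample). Inference for
#' `ab` comes from a subject-level percentile bootstrap with a two-tailed
#' sign-crossing p-value (add-one corrected); the remaining path p-values are
#' OLS t-tests. Inputs `x`, `m`, `y` are z-scored after listwise deletion so
#' all paths are in standardized units.
#'
#' @param x predictor (e.g. clinical latent score).
#' @param m mediator (e.g. imaging latent score).
#' @param y outcome (e.g. cognitive test score).
#' @param covariates optional data.frame of adjustment variables
#'   (conventionally age, sex, education).
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @return object of class `mediation_result` with paths `a`, `b`, `ab`,
#'   `c_prime`, `c`, bootstrap CI `ci_ab`, p-values `p_a`, `p_b`, `p_ab`,
#'   `p_c_prime`, `p_c`, `n`, `n_boot`, `seed`.
#' @export
fit_single_mediator <- function(x, m, y, covariates = NULL, n_boot = 5000L,
                                seed = 1L) {
  cv <- if (is.null(covariates)) NULL else as.matrix(drop_id(covariates))
  keep <- stats::complete.cases(x, m, y, if (is.null(cv)) rep(0, length(x)) else cv)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  cv <- if (is.null(cv)) NULL else cv[keep, , drop = FALSE]
  n <- length(x)
  ncv <- if (is.null(cv)) 0L else ncol(cv)
  if (n <= ncv + 3) stop_invalid("need n > n_covariates + 3 complete cases")
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop_invalid("constant input variable")
    (v - mean(v)) / s
  }
  x <- zs(x); m <- zs(m); y <- zs(y)
  if (abs(stats::cor(x, m)) > 0.999)
    stop_invalid("mediator is collinear with the predictor (|r| > 0.999)")
  paths <- function(x, m, y, cv) {
    d_a <- cbind(intercept = 1, x = x, cv)
    d_b <- cbind(intercept = 1, x = x, m = m, cv)
    f_a <- ols_fit(m, d_a)
    f_b <- ols_fit(y, d_b)
    f_c <- ols_fit(y, d_a)
    c(a = unname(f_a$coef["x"]), b = unname(f_b$coef["m"]),
      c_prime = unname(f_b$coef["x"]), c = unname(f_c$coef["x"]),
      p_a = unname(f_a$p["x"]), p_b = unname(f_b$p["m"]),
      p_c_prime = unname(f_b$p["x"]), p_c = unname(f_c$p["x"]))
  }
  est <- paths(x, m, y, cv)
  ab_boot <- numeric(n_boot)
  with_seed_(seed, {
    for (bb in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- paths(x[idx], m[idx], y[idx],
                  if (is.null(cv)) NULL else cv[idx, , drop = FALSE])
      ab_boot[bb] <- pb[["a"]] * pb[["b"]]
    }
  })
  ci_ab <- unname(stats::quantile(ab_boot, c(0.025, 0.975)))
  p_ab <- 2 * min((1 + sum(ab_boot <= 0)) / (1 + n_boot),
                  (1 + sum(ab_boot >= 0)) / (1 + n_boot))
  p_ab <- min(1, p_ab)
  out <- list(a = est[["a"]], b = est[["b"]], ab = est[["a"]] * est[["b"]],
              c_prime = est[["c_prime"]], c = est[["c"]],
              ci_ab = ci_ab, p_a = est[["p_a"]], p_b = est[["p_b"]],
              p_ab = p_ab, p_c_prime = est[["p_c_prime"]], p_c = est[["p_c"]],
              n = n, n_boot = n_boot, seed = seed)
  class(out) <- "mediation_result"
  out
}

#' Classify a mediation result
#'
#' Applies the decision rule: no mediation unless the indirect effect `ab`
#' and both constituent paths `a`, `b` are significant; given mediation,
#' "full" when the direct effect `c'` is non-significant, "partial" when `c'`
#' remains significant but is smaller in magnitude than the total effect `c`.
#' Uses FDR-adjusted q-values when present (fields `q_*`), raw p-values
#' otherwise.
#'
#' @param result a `mediation_result` (optionally with `q_a`, `q_b`, `q_ab`,
#'   `q_c_prime` fields added after batch FDR correction).
#' @param alpha significance level (default 0.05).
#' @return one of `"full"`, `"partial"`, `"none"`.
#' @export
classify_mediation <- function(result, alpha = 0.05) {
  g <- function(qname, pname) result[[qname]] %||% result[[pname]]
  q_ab <- g("q_ab", "p_ab"); q_a <- g("q_a", "p_a"); q_b <- g("q_b", "p_b")
  q_cp <- g("q_c_prime", "p_c_prime")
  if (q_ab >= alpha || q_a >= alpha || q_b >= alpha) return("none")
  if (q_cp >= alpha) return("full")
  if (abs(result$c_prime) < abs(result$c)) return("partial")
  "none"
}

#' Batch mediation over cognition columns
#'
#' Runs one single-mediator model per cognition column, FDR-corrects each
#' path's p-values across tests (within path type), and classifies each test.
#'
#' @param x,m predictor and mediator vectors.
#' @param cognition data.frame of outcome columns (a `subject_id` column is
#'   ignored); listwise deletion is applied per test.
#' @param covariates optional covariate data.frame.
#' @param n_boot,seed bootstrap settings.
#' @param alpha significance level for classification.
#' @return data.frame with one row per test: paths, CI, q-values, class.
#' @export
mediate_batch <- function(x, m, cognition, covariates = NULL,
                          n_boot = 5000L, seed = 1L, alpha = 0.05) {
  cog <- drop_id(cognition)
  fits <- lapply(seq_along(cog), function(j)
    fit_single_mediator(x, m, cog[[j]], covariates,
                        n_boot = n_boot, seed = seed + j))
  tab <- data.frame(
    test = names(cog),
    a = vapply(fits, `[[`, numeric(1), "a"),
    b = vapply(fits, `[[`, numeric(1), "b"),
    ab = vapply(fits, `[[`, numeric(1), "ab"),
    c_prime = vapply(fits, `[[`, numeric(1), "c_prime"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    ci_ab_lower = vapply(fits, function(f) f$ci_ab[1], numeric(1)),
    ci_ab_upper = vapply(fits, function(f) f$ci_ab[2], numeric(1)),
    stringsAsFactors = FALSE
  )
  for (path in c("a", "b", "ab", "c_prime", "c")) {
    pcol <- vapply(fits, `[[`, numeric(1), paste0("p_", path))
    tab[[paste0("q_", path)]] <- fdr_adjust(pcol)
  }
  tab$class <- vapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    for (path in c("a", "b", "ab", "c_prime"))
      f[[paste0("q_", path)]] <- tab[[paste0("q_", path)]][i]
    classify_mediation(f, alpha)
  }, character(1))
  tab
}
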