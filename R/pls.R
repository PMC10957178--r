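#' Cross-block correlation matrix
#'
#' Pearson correlation of every morphometric region with every clinical
#' variable; the matrix that is subsequently decomposed by SVD.
#'
#' @param X subjects x regions matrix (deconfounded, z-scored).
#' @param Y subjects x clinical-variables matrix (same subjects).
#' @return regions x clinical correlation matrix.
#' @export
cross_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_invalid("X and Y must share subjects")
  if (nrow(X) < 3) stop_invalid("need at least 3 subjects")
  sx <- apply(X, 2, stats::sd); sy <- apply(Y, 2, stats::sd)
  if (any(sx == 0) || any(sy == 0))
    stop_invalid("constant column(s): %s",
                 paste(c(colnames(X)[sx == 0], colnames(Y)[sy == 0]), collapse = ", "))
  stats::cor(X, Y)  # ncol(X) x ncol(Y) = regions x clinical
}

#' Singular value decomposition of the cross-correlation matrix
#'
#' Decomposes `R = U diag(delta) V'` into latent variables. The number of
#' latent variables equals `min(n_regions, n_clinical)` (in typical use, the
#' number of clinical variables). Explained variance per latent variable is
#' its squared singular value over the total sum of squared singular values.
#' A deterministic sign convention flips each latent variable so that the
#' largest-magnitude element of its clinical vector `V` is positive.
#'
#' @param R regions x clinical correlation matrix.
#' @return list of class `pls_decomposition`: `R`, `U`, `V`, `delta`,
#'   `explained_variance`.
#' @export
pls_decompose <- function(R) {
  R <- as.matrix(R)
  if (any(!is.finite(R))) stop_invalid("R must be finite")
  k <- min(dim(R))
  s <- svd(R, nu = k, nv = k)
  delta <- s$d[seq_len(k)]
  U <- s$u; V <- s$v
  for (j in seq_len(k)) {
    if (V[which.max(abs(V[, j])), j] < 0) {
      V[, j] <- -V[, j]; U[, j] <- -U[, j]
    }
  }
  rownames(U) <- rownames(R); rownames(V) <- colnames(R)
  out <- list(R = R, U = U, V = V, delta = delta,
              explained_variance = delta^2 / sum(delta^2))
  class(out) <- "pls_decomposition"
  out
}

# Align a permuted/resampled decomposition to a reference via orthogonal
# Procrustes on the clinical-side singular vectors; the rotation is applied
# jointly to U, V and (through column norms of V diag(delta) Q) the singular
# values, resolving the arbitrary order/rotation of resampled latent
# variables.
align_decomposition <- function(ref_V, dec) {
  Q <- procrustes_rotation(dec$V, ref_V)
  d_rot <- sqrt(colSums((dec$V %*% diag(dec$delta, length(dec$delta)) %*% Q)^2))
  list(U = dec$U %*% Q, V = dec$V %*% Q, delta = d_rot)
}

#' Permutation test for latent-variable significance
#'
#' Shuffles the subject order of `X` only, recomputes the full decomposition,
#' and compares per-latent-variable explained variance between the permuted
#' and observed solutions. P-values use the add-one formula
#' `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' Two ways of pairing permuted with observed latent variables are provided.
#' The default, `align = "rank"`, compares the j-th largest permuted
#' explained variance with the j-th observed one; under the null the ranked
#' statistics are exchangeable, so the resulting p-values are calibrated
#' (uniform for LV1, conservative for later LVs). `align = "procrustes"`
#' instead rotates each permuted solution onto the observed clinical
#' singular vectors before reading off per-LV explained variance; this
#' matches permuted LVs to observed ones by profile rather than by rank, but
#' the rotation spreads permuted singular-value mass across components and
#' makes the test anti-conservative, so it is not the default.
#'
#' @param X,Y preprocessed data blocks.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param decomposition optional precomputed [pls_decompose()] of `cor(X, Y)`.
#' @param align `"rank"` (default) or `"procrustes"`, see Details.
#' @return numeric vector of p-values per latent variable.
#' @export
permutation_pvalues <- function(X, Y, n_perm = 5000L, seed = 1L,
                                decomposition = NULL,
                                align = c("rank", "procrustes")) {
  align <- match.arg(align)
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- decomposition %||% pls_decompose(cross_correlation(X, Y))
  k <- length(obs$delta)
  exceed <- numeric(k)
  with_seed_(seed, {
    for (b in seq_len(n_perm)) {
      Xp <- X[sample.int(nrow(X)), , drop = FALSE]
      dp <- pls_decompose(stats::cor(Xp, Y))
      stat <- if (align == "procrustes") {
        al <- align_decomposition(obs$V, dp)
        al$delta^2 / sum(dp$delta^2)
      } else {
        dp$explained_variance
      }
      exceed <- exceed + (stat >= obs$explained_variance)
    }
  })
  (1 + exceed) / (1 + n_perm)
}

#' Bootstrap stability of singular-vector weights
#'
#' Resamples subjects with replacement jointly from both blocks, recomputes
#' the decomposition, aligns it to the original by Procrustes rotation of the
#' clinical vectors, and summarises the sampling distributions: the bootstrap
#' ratio (original region weight / bootstrap SD of aligned weights; z-like,
#' conventionally thresholded at |1.96|) per region, and 95% percentile
#' confidence intervals per clinical loading.
#'
#' @param X,Y preprocessed data blocks.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param decomposition optional precomputed decomposition.
#' @return list: `boot_ratio` (regions x LVs), `v_ci` (clinical x LVs x 2),
#'   `u_sd`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_stability <- function(X, Y, n_boot = 5000L, seed = 1L,
                                decomposition = NULL) {
  if (n_boot < 1) stop_invalid("n_boot must be >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- decomposition %||% pls_decompose(cross_correlation(X, Y))
  k <- length(obs$delta)
  n <- nrow(X)
  u_sum <- matrix(0, nrow(obs$U), k)
  u_sq <- matrix(0, nrow(obs$U), k)
  v_draws <- array(NA_real_, c(nrow(obs$V), k, n_boot))
  n_redrawn <- 0L
  with_seed_(seed, {
    for (b in seq_len(n_boot)) {
      for (try in 1:11) {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        ok <- all(apply(Xb, 2, stats::sd) > 0) && all(apply(Yb, 2, stats::sd) > 0)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (try == 11) stop_invalid("resample produced constant columns after 10 retries")
      }
      db <- pls_decompose(stats::cor(Xb, Yb))
      al <- align_decomposition(obs$V, db)
      u_sum <- u_sum + al$U
      u_sq <- u_sq + al$U^2
      v_draws[, , b] <- al$V
    }
  })
  u_sd <- sqrt(pmax(0, (u_sq - u_sum^2 / n_boot) / (n_boot - 1)))
  boot_ratio <- obs$U / u_sd
  v_ci <- array(NA_real_, c(nrow(obs$V), k, 2),
                dimnames = list(rownames(obs$V), NULL, c("lower", "upper")))
  for (j in seq_len(k)) {
    v_ci[, j, "lower"] <- apply(v_draws[, j, , drop = FALSE], 1, stats::quantile, probs = 0.025)
    v_ci[, j, "upper"] <- apply(v_draws[, j, , drop = FALSE], 1, stats::quantile, probs = 0.975)
  }
  dimnames(boot_ratio) <- dimnames(obs$U)
  if (n_redrawn > 0)
    message(sprintf("%d bootstrap resample(s) redrawn due to constant columns", n_redrawn))
  list(boot_ratio = boot_ratio, v_ci = v_ci, u_sd = u_sd,
       n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Subject-specific latent-variable scores
#'
#' Projects each subject's data onto the singular vectors: imaging score
#' `X U` and clinical score `Y V`. The per-latent-variable Spearman
#' correlation between the two score sets measures how strongly expression of
#' the clinical profile tracks expression of the morphometric profile.
#'
#' @param X,Y data blocks.
#' @param U,V singular vector matrices.
#' @return list: `scores_imaging`, `scores_clinical` (subjects x LVs),
#'   `score_spearman` per LV.
#' @export
subject_scores <- function(X, Y, U, V) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != nrow(U) || ncol(Y) != nrow(V) || nrow(X) != nrow(Y))
    stop_invalid("dimension mismatch between data blocks and singular vectors")
  si <- X %*% U
  sc <- Y %*% V
  rho <- vapply(seq_len(ncol(si)), function(j)
    stats::cor(si[, j], sc[, j], method = "spearman"), numeric(1))
  list(scores_imaging = si, scores_clinical = sc, score_spearman = rho)
}

#' K-fold cross-validated score correlation
#'
#' For each fold, the decomposition is fit on the training subjects and the
#' held-out subjects are projected with the training singular vectors; the
#' Spearman correlation of the out-of-sample imaging and clinical scores is
#' returned per fold and latent variable.
#'
#' @param X,Y preprocessed data blocks.
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return list: `fold_spearman` (folds x LVs), `mean_spearman` per LV.
#' @export
cross_validate <- function(X, Y, k = 10L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 2 * k) stop_invalid("need n >= 2k subjects for %d folds", k)
  folds <- with_seed_(seed, sample(rep_len(seq_len(k), n)))
  if (min(table(folds)) < 3) stop_invalid("a fold has fewer than 3 subjects")
  nlv <- min(ncol(X), ncol(Y))
  fold_rho <- matrix(NA_real_, k, nlv)
  for (f in seq_len(k)) {
    tr <- folds != f
    dec <- pls_decompose(stats::cor(X[tr, , drop = FALSE], Y[tr, , drop = FALSE]))
    si <- X[!tr, , drop = FALSE] %*% dec$U
    sc <- Y[!tr, , drop = FALSE] %*% dec$V
    fold_rho[f, ] <- vapply(seq_len(nlv), function(j)
      stats::cor(si[, j], sc[, j], method = "spearman"), numeric(1))
  }
  list(fold_spearman = fold_rho, mean_spearman = colMeans(fold_rho))
}

#' Full PLS correlation analysis
#'
#' Convenience wrapper chaining [cross_correlation()], [pls_decompose()],
#' [permutation_pvalues()], [bootstrap_stability()], [subject_scores()] and
#' [cross_validate()] into one result object.
#'
#' @param X,Y preprocessed (deconfounded, z-scored) data blocks.
#' @param n_perm,n_boot,cv_folds resampling settings (defaults 5000, 5000, 10).
#' @param seed integer master seed for the three resampling stages.
#' @param run_cv logical; skip cross-validation when `FALSE`.
#' @return object of class `pls_result`.
#' @export
pls_fit <- function(X, Y, n_perm = 5000L, n_boot = 5000L, cv_folds = 10L,
                    seed = 1L, run_cv = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  dec <- pls_decompose(cross_correlation(X, Y))
  perm_p <- permutation_pvalues(X, Y, n_perm = n_perm, seed = seed,
                                decomposition = dec)
  boot <- bootstrap_stability(X, Y, n_boot = n_boot, seed = seed + 1L,
                              decomposition = dec)
  sc <- subject_scores(X, Y, dec$U, dec$V)
  cv <- if (run_cv) cross_validate(X, Y, k = cv_folds, seed = seed + 2L) else NULL
  out <- c(dec, list(perm_p = perm_p, boot_ratio = boot$boot_ratio,
                     v_ci = boot$v_ci,
                     scores_imaging = sc$scores_imaging,
                     scores_clinical = sc$scores_clinical,
                     score_spearman = sc$score_spearman,
                     cv = cv, n_perm = n_perm, n_boot = n_boot, seed = seed))
  class(out) <- "pls_result"
  out
}
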