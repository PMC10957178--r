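# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @importFrom withr with_seed
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Euclidean distance matrix between rows of a coordinate matrix.
pairwise_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

check_square_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_invalid("%s must be a square matrix", name)
  if (max(abs(m - t(m))) > tol)
    stop_invalid("%s must be symmetric", name)
  invisible(TRUE)
}

# Orthogonal Procrustes rotation T minimising ||target - source %*% T||_F.
procrustes_rotation <- function(source, target) {
  s <- svd(crossprod(source, target))
  s$u %*% t(s$v)
}

# Column-wise z-scoring returning a plain matrix; sd uses ddof = 1.
scale_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
}

# Fisher z with clipping so perfect correlations stay finite.
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

# Spearman correlation of a vector against each column of a pre-ranked matrix.
# `ranked_mat` must already contain column ranks; used in surrogate loops
# where re-ranking the gene matrix every time would dominate the cost.
spearman_vs_ranked <- function(x, ranked_mat) {
  rx <- rank(x)
  drop(stats::cor(rx, ranked_mat))
}

rank_columns <- function(m) {
  apply(as.matrix(m), 2, rank)
}

# Binned semivariogram. `pair_idx` is a precomputed list(i, j, bin, nbins)
# so repeated calls on the same geometry are cheap.
variogram_pairs <- function(dmat, nbins = 25L, max_quantile = 0.25) {
  n <- nrow(dmat)
  ut <- which(upper.tri(dmat))
  d <- dmat[ut]
  dmax <- stats::quantile(d, max_quantile, names = FALSE)
  keep <- d <= dmax & d > 0
  ut <- ut[keep]
  d <- d[keep]
  bin <- pmin(nbins, pmax(1L, ceiling(d / dmax * nbins)))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  cnt <- tabulate(bin, nbins)
  list(i = i, j = j, bin = bin, nbins = nbins, counts = cnt,
       centers = (seq_len(nbins) - 0.5) / nbins * dmax)
}

binned_variogram <- function(x, vp) {
  sq <- 0.5 * (x[vp$i] - x[vp$j])^2
  sums <- rep(0, vp$nbins)
  agg <- rowsum(sq, vp$bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  ifelse(vp$counts > 0, sums / pmax(vp$counts, 1L), NA_real_)
}

# Map the rank order of `x` onto the empirical value distribution of `values`.
rank_remap <- function(x, values) {
  sort(values)[rank(x, ties.method = "first")]
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}
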