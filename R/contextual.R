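#' Weighted degree-centrality ranks
#'
#' Node strength (sum of connection weights) per parcel, returned as
#' ascending ranks (average rank on ties); a larger rank marks a stronger
#' hub. Negative weights are rejected: functional matrices must be
#' preprocessed to non-negative weights before use.
#'
#' @param connectome symmetric non-negative weighted matrix.
#' @return numeric vector of ranks named by parcel.
#' @export
degree_centrality_rank <- function(connectome) {
  check_square_symmetric(connectome, "connectome")
  if (any(connectome < 0))
    stop_invalid("connectome has negative weights; preprocess to non-negative")
  strength <- rowSums(connectome)
  r <- rank(strength)
  names(r) <- rownames(connectome)
  r
}

#' Connectivity-weighted neighborhood abnormality
#'
#' For each node i, the average of the effect statistic over its connected
#' neighbours, weighted by connection strength and normalized by the number
#' of connections: `A_i = (1/N_i) * sum_{j in N_i} C_j w_ij`. The 1/N_i term
#' corrects for nodal degree. Isolated nodes get `NA` and are excluded from
#' downstream correlations.
#'
#' @param connectome symmetric weighted matrix.
#' @param map effect statistic per node (aligned to the connectome).
#' @return numeric vector `A_i` (NA for isolated nodes).
#' @export
neighborhood_abnormality <- function(connectome, map) {
  check_square_symmetric(connectome, "connectome")
  x <- as.numeric(map)
  if (length(x) != nrow(connectome))
    stop_invalid("map length must match connectome size")
  n_i <- rowSums(connectome != 0)
  if (all(n_i == 0)) stop_invalid("all nodes are isolated")
  a <- drop(connectome %*% x) / n_i
  a[n_i == 0] <- NA_real_
  names(a) <- rownames(connectome)
  a
}

#' Diffusion-map connectivity gradients
#'
#' Low-dimensional embedding of a connectivity matrix: rows are sparsified
#' to their top 10% entries, a cosine-similarity affinity is built (negative
#' similarities clipped to zero), and diffusion-map embedding with
#' anisotropic normalization (alpha = 0.5) and diffusion time 0 returns the
#' leading non-trivial eigenvector maps, scaled by lambda / (1 - lambda) and
#' ordered by eigenvalue. Gradient 1 is the principal axis of
#' connectivity-profile variation.
#'
#' @param fc square connectivity matrix (rows not all zero).
#' @param n_components number of gradients (default 2).
#' @param sparsity fraction of largest row entries kept (default 0.10).
#' @return matrix (nodes x n_components) of gradient values.
#' @export
connectivity_gradients <- function(fc, n_components = 2L, sparsity = 0.10) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc)) stop_invalid("fc must be square")
  n <- nrow(fc)
  keep <- max(1L, ceiling(sparsity * n))
  sp <- fc
  for (i in seq_len(n)) {
    thr <- sort(fc[i, ], decreasing = TRUE)[keep]
    sp[i, fc[i, ] < thr] <- 0
  }
  norms <- sqrt(rowSums(sp^2))
  if (any(norms == 0)) stop_invalid("row(s) with no retained connectivity")
  aff <- tcrossprod(sp / norms)
  aff[aff < 0] <- 0
  comp <- graph_components(aff > 1e-12)
  if (max(comp) > 1)
    stop_invalid("affinity graph is disconnected (%d components; sizes %s)",
                 max(comp), paste(tabulate(comp), collapse = ", "))
  # anisotropic diffusion operator, alpha = 0.5
  d <- rowSums(aff)
  l <- aff / sqrt(outer(d, d))
  d2 <- rowSums(l)
  sym <- l / sqrt(outer(d2, d2))
  eig <- eigen(sym, symmetric = TRUE)
  psi <- eig$vectors / sqrt(d2)
  lam <- eig$values
  idx <- 1L + seq_len(n_components)
  grads <- sweep(psi[, idx, drop = FALSE], 2, lam[idx] / (1 - lam[idx]), "*")
  rownames(grads) <- rownames(fc)
  colnames(grads) <- sprintf("gradient_%d", seq_len(n_components))
  grads
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[i, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Spatially constrained correlation of two parcel maps
#'
#' Spearman correlation between two parcel maps, with significance assessed
#' against spatially constrained null models: surrogates of `map_a` by spin
#' or variogram matching, or, for connectome-derived maps, recomputation of
#' the neighborhood-abnormality statistic on degree-preserving rewired
#' connectomes. Parcels with `NA` in either map are dropped (at least 10
#' must remain).
#'
#' @param map_a,map_b numeric parcel maps (aligned). For the `rewire` null,
#'   `map_a` is replaced per-null by `neighborhood_abnormality(rewired, base_map)`.
#' @param nulls character subset of `c("spin", "variogram", "rewire")`.
#' @param n_null surrogates per null (default 1000).
#' @param geometry `parcel_geometry`, required for the spin null.
#' @param distances distance matrix, required for the variogram null
#'   (computed from geometry centroids when omitted).
#' @param connectome,base_map connectome and raw effect map, required for the
#'   rewire null.
#' @param seed integer seed.
#' @param spin_perms optional precomputed spin index matrix.
#' @return list: `rsp`, `n_parcels`, and `p_<null>` per requested null.
#' @export
spatial_correlation <- function(map_a, map_b, nulls = "spin", n_null = 1000L,
                                geometry = NULL, distances = NULL,
                                connectome = NULL, base_map = NULL,
                                seed = 1L, spin_perms = NULL) {
  a <- as.numeric(map_a); b <- as.numeric(map_b)
  if (length(a) != length(b)) stop_invalid("maps must be aligned")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 10) stop_invalid("fewer than 10 parcels in common")
  rsp <- stats::cor(a[ok], b[ok], method = "spearman")
  out <- list(rsp = rsp, n_parcels = sum(ok))
  rb <- rank(b[ok])
  null_rho <- function(mat) {
    apply(mat[, ok, drop = FALSE], 1, function(s) stats::cor(rank(s), rb))
  }
  for (nl in nulls) {
    nulls_rho <- switch(
      nl,
      spin = {
        if (is.null(geometry)) stop_invalid("spin null requires geometry")
        ens <- spin_surrogates(a, geometry, n = n_null, seed = seed,
                               perms = spin_perms)
        null_rho(ens$values)
      },
      variogram = {
        if (is.null(distances)) {
          if (is.null(geometry)) stop_invalid("variogram null requires distances or geometry")
          distances <- pairwise_dist(geometry_centroids(geometry))
        }
        ens <- variogram_surrogates(a, distances, n = n_null, seed = seed)
        null_rho(ens$values)
      },
      rewire = {
        if (is.null(connectome) || is.null(base_map))
          stop_invalid("rewire null requires connectome and base_map")
        vapply(seq_len(n_null), function(s) {
          rw <- rewire_connectome(connectome, seed = seed + s)
          am <- neighborhood_abnormality(rw, base_map)
          keep <- ok & !is.na(am)
          stats::cor(am[keep], b[keep], method = "spearman")
        }, numeric(1))
      },
      stop_invalid("unknown null model '%s'", nl)
    )
    out[[paste0("p_", nl)]] <- empirical_pvalue(rsp, nulls_rho)
  }
  out
}

#' Cell-type density maps from gene expression
#'
#' Z-scores each gene's expression map across parcels, then averages the
#' member genes within each category, yielding one density proxy map per
#' cell population.
#'
#' @param expression parcels x genes matrix (rownames = parcel ids).
#' @param catalog data.frame with columns `gene`, `category`.
#' @return parcels x categories matrix.
#' @export
cell_density_maps <- function(expression, catalog) {
  expr <- as.matrix(expression)
  cats <- split(catalog$gene, catalog$category)
  missing <- setdiff(unlist(cats), colnames(expr))
  if (length(missing))
    message(sprintf("%d catalog gene(s) absent from expression matrix; skipped",
                    length(missing)))
  z <- scale_cols(expr)
  maps <- vapply(names(cats), function(cc) {
    genes <- intersect(cats[[cc]], colnames(expr))
    if (!length(genes)) return(rep(NA_real_, nrow(expr)))
    rowMeans(z[, genes, drop = FALSE])
  }, numeric(nrow(expr)))
  empty <- colSums(!is.na(maps)) == 0
  if (any(empty)) {
    warning("category(ies) with zero present genes excluded: ",
            paste(colnames(maps)[empty], collapse = ", "), call. = FALSE)
    maps <- maps[, !empty, drop = FALSE]
  }
  rownames(maps) <- rownames(expr)
  maps
}

#' Ensemble gene-category enrichment against an effect map
#'
#' For every gene category: Spearman-correlate the effect map with each
#' member gene's expression map, Fisher-z transform, and average to the
#' aggregate statistic Z(rsp). Null distributions are built by recomputing
#' Z(rsp) with spatial-lag surrogates of the effect map (preserving its
#' spatial autocorrelation), giving a two-tailed empirical p per category;
#' Benjamini-Hochberg FDR across categories. The alternative aggregation
#' (average the category's gene maps first, then correlate once) is
#' available via `aggregation = "category_mean"`.
#'
#' @param effect numeric effect map (e.g. bootstrap ratios) per parcel.
#' @param expression parcels x genes matrix.
#' @param catalog data.frame `gene`, `category`.
#' @param n_surrogates surrogate maps for the null (default 1000).
#' @param seed integer seed.
#' @param distances inter-parcel distance matrix for the spatial-lag fit
#'   (computed from `geometry` when supplied instead).
#' @param geometry optional `parcel_geometry`.
#' @param aggregation `"gene_z"` (Fisher-z average, default) or
#'   `"category_mean"`.
#' @return data.frame: category, n_genes, z_rsp, p, q.
#' @export
gcea_cell_types <- function(effect, expression, catalog, n_surrogates = 1000L,
                            seed = 1L, distances = NULL, geometry = NULL,
                            aggregation = c("gene_z", "category_mean")) {
  aggregation <- match.arg(aggregation)
  expr <- as.matrix(expression)
  x <- as.numeric(effect)
  if (length(x) != nrow(expr)) stop_invalid("effect map must align with expression rows")
  if (is.null(distances)) {
    if (is.null(geometry)) stop_invalid("supply distances or geometry")
    distances <- pairwise_dist(geometry_centroids(geometry))
  }
  cats <- split(catalog$gene, catalog$category)
  cats <- lapply(cats, intersect, colnames(expr))
  small <- vapply(cats, length, integer(1)) < 2
  if (any(small)) {
    warning("category(ies) with fewer than 2 genes skipped: ",
            paste(names(cats)[small], collapse = ", "), call. = FALSE)
    cats <- cats[!small]
  }
  if (!length(cats)) stop_invalid("no category with >= 2 genes")
  cat_stat <- if (aggregation == "gene_z") {
    ranked_genes <- rank_columns(expr)
    function(v) {
      r <- spearman_vs_ranked(v, ranked_genes)
      names(r) <- colnames(expr)
      vapply(cats, function(g) mean(fisher_z(r[g])), numeric(1))
    }
  } else {
    density <- cell_density_maps(expr[, unlist(cats), drop = FALSE],
                                 catalog[catalog$gene %in% unlist(cats), ])
    ranked_density <- rank_columns(density)
    function(v) {
      r <- spearman_vs_ranked(v, ranked_density)
      names(r) <- colnames(density)
      fisher_z(r[names(cats)])
    }
  }
  obs <- cat_stat(x)
  ens <- spatial_lag_surrogates(x, distances, n = n_surrogates, seed = seed)
  null_z <- t(apply(ens$values, 1, cat_stat))
  p <- vapply(seq_along(cats), function(j)
    empirical_pvalue(obs[j], null_z[, j]), numeric(1))
  data.frame(category = names(cats),
             n_genes = vapply(cats, length, integer(1)),
             z_rsp = unname(obs), p = p, q = fdr_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
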