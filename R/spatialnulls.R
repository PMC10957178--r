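new_surrogate_ensemble <- function(values, method, seed, extra = list()) {
  stopifnot(is.matrix(values))
  dimnames(values) <- NULL
  out <- c(list(values = values, method = method, seed = seed), extra)
  class(out) <- "surrogate_ensemble"
  out
}

# One-to-one nearest-neighbour reassignment of parcels to rotated positions.
# Targets are processed in random order; each takes the nearest *unused*
# source parcel, so every assignment is an exact permutation.
assign_rotation <- function(coords, rotation, order_idx) {
  rotated <- coords %*% t(rotation)
  d2 <- outer(rowSums(coords^2), rowSums(rotated^2), "+") -
    2 * coords %*% t(rotated)
  n <- nrow(coords)
  used <- logical(n)
  idx <- integer(n)
  for (i in order_idx) {
    cand <- d2[i, ]
    cand[used] <- Inf
    src <- which.min(cand)
    idx[i] <- src
    used[src] <- TRUE
  }
  idx
}

# Precompute spin permutation index matrix (n x n_cortical). The indices
# depend only on geometry, rotations and seed, never on map values, so one
# set can be reused across maps on the same parcellation.
spin_permutation_indices <- function(geometry, n = 1000L, seed = 1L) {
  cortical <- geometry$structure_class == "cortical"
  if (!all(c("L", "R") %in% geometry$hemisphere[cortical]))
    stop_invalid("both hemispheres must be present")
  sphere <- geometry_sphere_xyz(geometry)
  if (anyNA(sphere)) stop_invalid("missing sphere coordinates")
  li <- which(cortical & geometry$hemisphere == "L")
  ri <- which(cortical & geometry$hemisphere == "R")
  p <- sum(cortical)
  mir <- diag(c(-1, 1, 1))
  perms <- matrix(NA_integer_, n, p)
  with_seed_(seed, {
    for (s in seq_len(n)) {
      rot_l <- random_rotation()
      rot_r <- mir %*% rot_l %*% mir
      ord_l <- sample.int(length(li))
      ord_r <- sample.int(length(ri))
      out <- integer(p)
      out[li] <- li[assign_rotation(sphere[li, , drop = FALSE], rot_l, ord_l)]
      out[ri] <- ri[assign_rotation(sphere[ri, , drop = FALSE], rot_r, ord_r)]
      perms[s, ] <- out
    }
  })
  perms
}

#' Spin-permutation surrogate maps
#'
#' Generates spatially constrained surrogates by rotating the spherical
#' parcel coordinates (one uniform random rotation for the left hemisphere,
#' its x-mirrored twin for the right) and reassigning parcels one-to-one to
#' their nearest rotated neighbours, so each surrogate is an exact
#' permutation of the original values. Subcortical parcels are excluded.
#'
#' @param map numeric parcel map aligned to `geometry`.
#' @param geometry a `parcel_geometry` with unit-sphere coordinates.
#' @param n number of surrogates (default 1000).
#' @param seed integer seed.
#' @param perms optional precomputed index matrix from repeated use on the
#'   same geometry (internal `spin_permutation_indices()`).
#' @return a `surrogate_ensemble` (n x n_cortical matrix).
#' @export
spin_surrogates <- function(map, geometry, n = 1000L, seed = 1L, perms = NULL) {
  cortical <- geometry$structure_class == "cortical"
  x <- as.numeric(map)[cortical]
  if (is.null(perms)) perms <- spin_permutation_indices(geometry, n, seed)
  vals <- matrix(x[perms], nrow(perms), length(x))
  new_surrogate_ensemble(vals, "spin", seed)
}

# Smoothing kernel bank: row-normalized exponential kernels at radii spanning
# the short-range distance percentiles (the range over which the variogram is
# matched; long radii only over-smooth).
kernel_bank <- function(distances, n_radii = 5L, radii_range = c(0.05, 0.5)) {
  d <- distances[upper.tri(distances)]
  radii <- stats::quantile(d[d > 0], seq(radii_range[1], radii_range[2],
                                         length.out = n_radii),
                           names = FALSE)
  lapply(radii, function(r) {
    k <- exp(-distances / r)
    k / rowSums(k)
  })
}

#' Variogram-matched surrogate maps
#'
#' Surrogates preserving the empirical spatial autocorrelation structure:
#' each surrogate is a random permutation of the map, smoothed with the
#' distance kernel (from a bank of radii) whose linearly rescaled binned
#' variogram best matches the original's, plus a fitted white-noise nugget,
#' and finally rank-remapped to the original value distribution (so the
#' value multiset is preserved exactly).
#'
#' @param map numeric parcel map.
#' @param distances symmetric inter-parcel distance matrix (mm, zero diag).
#' @param n number of surrogates (default 1000).
#' @param seed integer seed.
#' @param nbins variogram bins (default 12).
#' @param max_quantile distance quantile at which the variogram is truncated.
#' @param n_radii size of the smoothing-kernel bank (default 5).
#' @param n_pilot pilot surrogates used to select the kernel radius and
#'   nugget rescaling for the map; the remaining surrogates reuse that
#'   selection with a per-surrogate linear variogram fit.
#' @return a `surrogate_ensemble`.
#' @export
variogram_surrogates <- function(map, distances, n = 1000L, seed = 1L,
                                 nbins = 12L, n_radii = 5L,
                                 max_quantile = 0.6, n_pilot = 5L) {
  x <- as.numeric(map)
  check_square_symmetric(distances, "distances")
  d_off <- distances[upper.tri(distances)]
  if (stats::sd(d_off) == 0) stop_invalid("degenerate distance matrix (all distances equal)")
  vp <- variogram_pairs(distances, nbins = nbins, max_quantile = max_quantile)
  gamma_obs <- binned_variogram(x, vp)
  ok_bins <- !is.na(gamma_obs)
  wts <- vp$counts[ok_bins]
  kernels <- kernel_bank(distances, n_radii)
  bscales <- c(0, 0.5, 1, 2, 4)
  p <- length(x)
  vals <- matrix(NA_real_, n, p)
  # one candidate surrogate for a given smoothing kernel: least-squares
  # match of gamma_obs ~ alpha * gamma_kernel + beta, the white-noise nugget
  # rescaled by bscale because the final rank remap (which restores the
  # value distribution) compresses the noise contribution nonlinearly
  make_cand <- function(K, xp, noise, bscale) {
    yk <- drop(K %*% xp)
    gk <- binned_variogram(yk, vp)
    fit <- stats::lm.wfit(cbind(1, gk[ok_bins]), gamma_obs[ok_bins], wts)
    alpha <- abs(fit$coefficients[2]); beta <- abs(fit$coefficients[1])
    rank_remap(sqrt(alpha) * yk + sqrt(beta * bscale) * noise, x)
  }
  cand_sse <- function(cand)
    sum(wts * (binned_variogram(cand, vp)[ok_bins] - gamma_obs[ok_bins])^2)
  with_seed_(seed, {
    # pilot phase: full search over (kernel, nugget scale), judged by the
    # variogram of the finished surrogate; votes select the map-wide choice
    n_pilot <- min(n_pilot, n)
    votes <- matrix(0, length(kernels), length(bscales))
    for (s in seq_len(n_pilot)) {
      xp <- x[sample.int(p)]
      noise <- stats::rnorm(p)
      best <- NULL
      for (ki in seq_along(kernels)) for (bi in seq_along(bscales)) {
        cand <- make_cand(kernels[[ki]], xp, noise, bscales[bi])
        sse <- cand_sse(cand)
        if (is.null(best) || sse < best$sse)
          best <- list(cand = cand, sse = sse, ki = ki, bi = bi)
      }
      votes[best$ki, best$bi] <- votes[best$ki, best$bi] + 1
      vals[s, ] <- best$cand
    }
    pick <- which(votes == max(votes), arr.ind = TRUE)[1, ]
    K_sel <- kernels[[pick[1]]]; b_sel <- bscales[pick[2]]
    for (s in seq.int(n_pilot + 1L, length.out = n - n_pilot)) {
      xp <- x[sample.int(p)]
      noise <- stats::rnorm(p)
      vals[s, ] <- make_cand(K_sel, xp, noise, b_sel)
    }
  })
  new_surrogate_ensemble(vals, "variogram", seed)
}

# ML fit of the simultaneous-autoregressive model y = rho W(d0) y + eps over
# a log-spaced grid of decay scales d0, with W row-normalized exp(-d/d0).
fit_spatial_lag <- function(x, distances, n_d0 = 8L, rho_cap = 0.99) {
  y <- x - mean(x)
  n <- length(y)
  # decay scales from below the typical nearest-neighbour spacing up to the
  # median distance; long scales only wash the autoregression out
  nn <- apply(distances + diag(Inf, nrow(distances)), 1, min)
  d_off <- distances[upper.tri(distances)]
  d0_grid <- exp(seq(log(stats::median(nn) / 4),
                     log(stats::quantile(d_off[d_off > 0], 0.5)),
                     length.out = n_d0))
  best <- NULL
  for (d0 in d0_grid) {
    k <- exp(-distances / d0)
    diag(k) <- 0
    rs <- rowSums(k)
    w <- k / rs
    # W is similar to a symmetric matrix, so its spectrum is real
    sym <- k / sqrt(outer(rs, rs))
    lam <- eigen(sym, symmetric = TRUE, only.values = TRUE)$values
    wy <- drop(w %*% y)
    loglik <- function(rho) {
      sum(log(pmax(1 - rho * lam, 1e-12))) -
        n / 2 * log(sum((y - rho * wy)^2) / n)
    }
    lo <- if (min(lam) < 0) 1 / min(lam) + 1e-6 else -rho_cap
    opt <- stats::optimize(loglik, c(max(lo, -rho_cap), rho_cap), maximum = TRUE)
    if (is.null(best) || opt$objective > best$loglik) {
      rho <- opt$maximum
      best <- list(rho = rho, d0 = d0, W = w, loglik = opt$objective,
                   sigma = sqrt(sum((y - rho * wy)^2) / n))
    }
  }
  if (best$rho >= rho_cap - 1e-9)
    warning("estimated rho at the stability cap; clipped to ", rho_cap, call. = FALSE)
  best
}

#' Spatial-lag-model surrogate maps
#'
#' Fits the autoregressive spatial lag model `y = rho W(d0) y + eps` (W =
#' row-normalized exponential distance decay; maximum likelihood over a grid
#' of decay scales d0 and the autoregression parameter rho), then draws
#' surrogates `(I - rho W)^-1 eps` with white Gaussian innovations and
#' rank-remaps them to the original value distribution.
#'
#' @inheritParams variogram_surrogates
#' @param n_d0 size of the log-spaced d0 grid (default 8).
#' @return a `surrogate_ensemble` with `rho` and `d0` fields.
#' @export
spatial_lag_surrogates <- function(map, distances, n = 1000L, seed = 1L,
                                   n_d0 = 8L) {
  x <- as.numeric(map)
  check_square_symmetric(distances, "distances")
  fit <- fit_spatial_lag(x, distances, n_d0 = n_d0)
  p <- length(x)
  m <- solve(diag(p) - fit$rho * fit$W)
  vals <- with_seed_(seed, {
    eps <- matrix(stats::rnorm(p * n, sd = fit$sigma), p, n)
    t(m %*% eps)
  })
  for (s in seq_len(n)) vals[s, ] <- rank_remap(vals[s, ], x)
  new_surrogate_ensemble(vals, "spatial_lag", seed,
                         extra = list(rho = fit$rho, d0 = fit$d0))
}

#' Degree-preserving connectome rewiring
#'
#' Randomizes the binary topology by Maslov-Sneppen double-edge swaps,
#' carrying each edge's weight along with it. The binary degree sequence and
#' the edge count (hence density) are exactly preserved; proposed swaps that
#' would create self-loops or multi-edges are rejected.
#'
#' @param connectome symmetric weighted matrix with zero diagonal.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return rewired matrix; attribute `rewired` is `FALSE` when no legal swap
#'   exists (input returned with a warning).
#' @export
rewire_connectome <- function(connectome, n_swaps_per_edge = 10L, seed = 1L) {
  check_square_symmetric(connectome, "connectome")
  if (any(diag(connectome) != 0)) stop_invalid("connectome must have zero diagonal")
  n <- nrow(connectome)
  ut <- which(upper.tri(connectome) & connectome > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2) {
    warning("graph too small for any legal swap; returning input", call. = FALSE)
    out <- connectome
    attr(out, "rewired") <- FALSE
    return(out)
  }
  edges <- ut  # column 1 = i, column 2 = j, i < j
  weights <- connectome[ut]
  adj <- connectome > 0
  n_attempts <- n_swaps_per_edge * m
  any_swap <- FALSE
  with_seed_(seed, {
    pick <- matrix(sample.int(m, 2 * n_attempts, replace = TRUE), ncol = 2)
    flip <- stats::runif(n_attempts) < 0.5
    for (t in seq_len(n_attempts)) {
      e1 <- pick[t, 1]; e2 <- pick[t, 2]
      if (e1 == e2) next
      a <- edges[e1, 1]; b <- edges[e1, 2]
      c_ <- edges[e2, 1]; d_ <- edges[e2, 2]
      if (flip[t]) { tmp <- c_; c_ <- d_; d_ <- tmp }
      # propose (a,d) and (c,b)
      if (a == d_ || c_ == b) next
      if (length(unique(c(a, b, c_, d_))) < 4) next
      if (adj[a, d_] || adj[c_, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c_, d_] <- adj[d_, c_] <- FALSE
      adj[a, d_] <- adj[d_, a] <- TRUE
      adj[c_, b] <- adj[b, c_] <- TRUE
      edges[e1, ] <- c(min(a, d_), max(a, d_))
      edges[e2, ] <- c(min(c_, b), max(c_, b))
      any_swap <- TRUE
    }
  })
  if (!any_swap)
    warning("no legal swap found; topology unchanged", call. = FALSE)
  out <- matrix(0, n, n, dimnames = dimnames(connectome))
  out[edges] <- weights
  out[edges[, c(2, 1), drop = FALSE]] <- weights
  attr(out, "rewired") <- any_swap
  out
}

#' Empirical p-value against a null distribution
#'
#' Add-one empirical p: two-tailed
#' `(1 + #{|null| >= |obs|}) / (1 + n_null)`, or one-tailed
#' `(1 + #{null >= obs}) / (1 + n_null)`.
#'
#' @param observed observed statistic (scalar).
#' @param null_values numeric vector of null statistics.
#' @param two_tailed logical (default `TRUE`).
#' @return p-value.
#' @export
empirical_pvalue <- function(observed, null_values, two_tailed = TRUE) {
  if (!length(null_values)) stop_invalid("null_values must be non-empty")
  if (anyNA(null_values) || anyNA(observed)) stop_invalid("NaN/NA in inputs")
  if (two_tailed) {
    (1 + sum(abs(null_values) >= abs(observed))) / (1 + length(null_values))
  } else {
    (1 + sum(null_values >= observed)) / (1 + length(null_values))
  }
}
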