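#' Quasi-uniform spherical parcellation
#'
#' Places parcels on a unit sphere per hemisphere using a Fibonacci lattice,
#' mirrored across the midline, and derives volumetric centroids by scaling
#' to a 100 mm sphere with the hemispheres offset along x. This supplies the
#' geometric substrate (sphere coordinates for spin nulls, centroid distances
#' for variogram / spatial-lag nulls and connectome generation) that a real
#' cortical parcellation would provide.
#'
#' @param n_parcels total parcel count, even and >= 4 (split across L/R).
#' @param seed integer; a seeded random rotation is applied to the lattice
#'   (mirrored between hemispheres) so different seeds give distinct but
#'   reproducible geometries.
#' @return A `parcel_geometry` data.frame with columns `parcel_id`,
#'   `hemisphere`, `sx, sy, sz` (unit sphere), `cx, cy, cz` (mm) and
#'   `structure_class`.
#' @export
gen_sphere_parcellation <- function(n_parcels, seed = 1L) {
  if (n_parcels < 4 || n_parcels %% 2 != 0)
    stop_invalid("n_parcels must be an even count >= 4, got %s", n_parcels)
  n_h <- n_parcels %/% 2
  i <- seq_len(n_h) - 0.5
  z <- 1 - 2 * i / n_h
  phi <- (seq_len(n_h) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  rot <- with_seed_(seed, random_rotation())
  mir <- diag(c(-1, 1, 1))
  left <- pts %*% t(rot)
  right <- (pts %*% diag(c(-1, 1, 1))) %*% t(mir %*% rot %*% mir)
  sphere <- rbind(left, right)
  hemi <- rep(c("L", "R"), each = n_h)
  cent <- sphere * 100
  cent[, 1] <- cent[, 1] + ifelse(hemi == "L", -110, 110)
  out <- data.frame(
    parcel_id = sprintf("%s_parcel_%03d", hemi, rep(seq_len(n_h), 2)),
    hemisphere = hemi,
    sx = sphere[, 1], sy = sphere[, 2], sz = sphere[, 3],
    cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
    structure_class = "cortical",
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcel_geometry", "data.frame")
  out
}

# Uniform random rotation (Haar) via QR of a Gaussian matrix, det +1.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

geometry_sphere_xyz <- function(geometry) {
  as.matrix(geometry[, c("sx", "sy", "sz")])
}

geometry_centroids <- function(geometry) {
  as.matrix(geometry[, c("cx", "cy", "cz")])
}

#' Spatially autocorrelated parcel map
#'
#' Draws a zero-mean, unit-variance map from a Gaussian process with
#' exponential covariance `exp(-d / lengthscale)` on centroid distances,
#' independently per hemisphere. These maps carry the spatial autocorrelation
#' that the spin/variogram/spatial-lag null models are designed to respect.
#'
#' @param geometry a `parcel_geometry`.
#' @param lengthscale correlation length in mm (> 0).
#' @param seed integer seed.
#' @return numeric vector named by `parcel_id` (empirically standardized).
#' @export
gen_smooth_map <- function(geometry, lengthscale, seed = 1L) {
  if (!is.numeric(lengthscale) || lengthscale <= 0)
    stop_invalid("lengthscale must be > 0")
  cent <- geometry_centroids(geometry)
  x <- numeric(nrow(geometry))
  with_seed_(seed, {
    for (h in unique(geometry$hemisphere)) {
      idx <- which(geometry$hemisphere == h)
      d <- pairwise_dist(cent[idx, , drop = FALSE])
      k <- exp(-d / lengthscale)
      ch <- chol(k + diag(1e-8, nrow(k)))
      x[idx] <- drop(t(ch) %*% stats::rnorm(length(idx)))
    }
  })
  x <- (x - mean(x)) / stats::sd(x)
  names(x) <- geometry$parcel_id
  x
}

#' Distance-decaying modular connectome
#'
#' Samples a symmetric weighted graph whose edge probability decays as
#' `exp(-d / decay)` and is boosted by `module_boost` within planted modules
#' (contiguous index blocks, recorded in the `"modules"` attribute). Edge
#' weights are uniform in (0, 1]. The expected edge count is calibrated to the
#' requested density.
#'
#' @param geometry a `parcel_geometry`.
#' @param decay distance decay scale (mm, > 0).
#' @param density target edge density in (0, 1].
#' @param n_modules number of planted modules (>= 1).
#' @param seed integer seed.
#' @param module_boost multiplicative within-module boost of edge probability.
#' @return symmetric matrix with zero diagonal, attributes `modules`
#'   (integer labels) and `connected` (logical).
#' @export
gen_connectome <- function(geometry, decay = 60, density = 0.2, n_modules = 1L,
                           seed = 1L, module_boost = 5) {
  if (density <= 0 || density > 1) stop_invalid("density must be in (0, 1]")
  if (decay <= 0) stop_invalid("decay must be > 0")
  n <- nrow(geometry)
  modules <- sort(rep_len(seq_len(n_modules), n))
  d <- pairwise_dist(geometry_centroids(geometry))
  same <- outer(modules, modules, "==")
  base <- exp(-d / decay) * ifelse(same, module_boost, 1)
  diag(base) <- 0
  ut <- upper.tri(base)
  npairs <- sum(ut)
  target <- density * npairs
  if (density >= 1) {
    p <- ifelse(ut, 1, 0)
  } else {
    b <- base[ut]
    c0 <- target / sum(b)
    for (it in 1:25) {
      exp_edges <- sum(pmin(1, c0 * b))
      if (abs(exp_edges - target) < 1e-9 * target) break
      c0 <- c0 * target / exp_edges
    }
    p <- matrix(0, n, n)
    p[ut] <- pmin(1, c0 * b)
  }
  w <- matrix(0, n, n)
  with_seed_(seed, {
    edge <- ut & (matrix(stats::runif(n * n), n, n) < p)
    w[edge] <- stats::runif(sum(edge), min = .Machine$double.eps, max = 1)
  })
  w <- w + t(w)
  dimnames(w) <- list(geometry$parcel_id, geometry$parcel_id)
  connected <- is_connected_adj(w)
  if (!connected)
    warning("generated connectome is disconnected", call. = FALSE)
  attr(w, "modules") <- modules
  attr(w, "connected") <- connected
  w
}

is_connected_adj <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(w[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Cell-category-structured expression matrix
#'
#' Generates a parcels-by-genes expression matrix where every gene map is
#' smooth spatial noise and genes belonging to `signal_categories`
#' additionally load on `signal_map` with weight `signal_weight`. Used to
#' test gene-category enrichment with known planted categories.
#'
#' @param geometry a `parcel_geometry`.
#' @param n_categories number of gene categories (>= 1).
#' @param genes_per_category genes per category (>= 1).
#' @param signal_map numeric parcel map added to signal genes.
#' @param signal_categories character vector of category names that receive
#'   the signal (subset of the generated categories).
#' @param lengthscale spatial correlation length of the per-gene noise (mm).
#' @param seed integer seed.
#' @param signal_weight weight of `signal_map` in signal genes.
#' @param noise_sd standard deviation of the smooth noise component.
#' @return list with `expression` (parcels x genes matrix) and `mapping`
#'   (data.frame gene, category).
#' @export
gen_expression <- function(geometry, n_categories, genes_per_category,
                           signal_map = NULL, signal_categories = character(),
                           lengthscale = 40, seed = 1L,
                           signal_weight = 1, noise_sd = 1) {
  if (n_categories < 1 || genes_per_category < 1)
    stop_invalid("n_categories and genes_per_category must be >= 1")
  categories <- sprintf("Cat%02d", seq_len(n_categories))
  if (length(signal_categories) && !all(signal_categories %in% categories))
    stop_invalid("signal_categories must be a subset of the generated categories")
  n_genes <- n_categories * genes_per_category
  mapping <- data.frame(
    gene = sprintf("%s_G%02d", rep(categories, each = genes_per_category),
                   rep(seq_len(genes_per_category), n_categories)),
    category = rep(categories, each = genes_per_category),
    stringsAsFactors = FALSE
  )
  cent <- geometry_centroids(geometry)
  n <- nrow(geometry)
  expr <- matrix(0, n, n_genes, dimnames = list(geometry$parcel_id, mapping$gene))
  with_seed_(seed, {
    for (h in unique(geometry$hemisphere)) {
      idx <- which(geometry$hemisphere == h)
      d <- pairwise_dist(cent[idx, , drop = FALSE])
      ch <- chol(exp(-d / lengthscale) + diag(1e-8, length(idx)))
      expr[idx, ] <- t(ch) %*% matrix(stats::rnorm(length(idx) * n_genes),
                                      length(idx), n_genes)
    }
  })
  expr <- expr * noise_sd
  if (length(signal_categories)) {
    if (is.null(signal_map))
      stop_invalid("signal_map required when signal_categories is non-empty")
    sig <- mapping$category %in% signal_categories
    expr[, sig] <- expr[, sig] + signal_weight * as.numeric(signal_map)
  }
  list(expression = expr, mapping = mapping)
}

mets_variable_names <- function() {
  c("waist", "hip", "whr", "bmi", "sbp", "dbp",
    "hdl", "ldl", "chol", "tg", "hba1c", "glucose")
}

mets_variable_groups <- function() {
  c(waist = "obesity", hip = "obesity", whr = "obesity", bmi = "obesity",
    sbp = "blood_pressure", dbp = "blood_pressure",
    hdl = "lipids", ldl = "lipids", chol = "lipids", tg = "lipids",
    hba1c = "glycemic", glucose = "glycemic")
}

#' Specification for a synthetic cohort
#'
#' Bundles and validates the generative parameters for [gen_cohort()]: a
#' rank-one latent coupling between the clinical and morphometric blocks,
#' linear confound contamination, MCAR missingness in the clinical block, and
#' a planted mediation chain (clinical latent -> imaging latent -> cognition)
#' on standardized latents.
#'
#' @param n_subjects,n_regions,n_clinical dimensions of the cohort.
#' @param coupling_strength latent coupling scale in `[0, 1]`.
#' @param noise_sd per-block residual standard deviation.
#' @param missing_rate MCAR missingness fraction in `[0, 1)` (clinical only).
#' @param mediation_effects named vector `c(a=, b=, c_prime=)` of standardized
#'   slopes; `a = 1` collapses the imaging latent onto the clinical latent
#'   (the shared-latent model used for latent-recovery experiments).
#' @param confound_effects either `NULL` (no contamination), `"default"`
#'   (reproducible moderate slopes), or a list with matrices `clinical`
#'   (4 x n_clinical) and `morph` (4 x n_regions) of slopes on the z-scored
#'   confounds (age, sex, education, cohort).
#' @param latent_loadings_u,latent_loadings_v optional unit-norm loading
#'   vectors; drawn uniformly on the sphere from `seed` if omitted.
#' @param n_cognition number of cognition columns (independent noise, shared
#'   mediation slopes).
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_subjects, n_regions, n_clinical,
                        coupling_strength = 0.8, noise_sd = 0.5,
                        missing_rate = 0,
                        mediation_effects = c(a = 1, b = 0, c_prime = 0),
                        confound_effects = NULL,
                        latent_loadings_u = NULL, latent_loadings_v = NULL,
                        n_cognition = 2L, seed = 1L) {
  if (coupling_strength < 0 || coupling_strength > 1)
    stop_invalid("coupling_strength must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_invalid("missing_rate must be in [0, 1)")
  me <- mediation_effects
  if (!all(c("a", "b", "c_prime") %in% names(me)))
    stop_invalid("mediation_effects must name a, b and c_prime")
  if (abs(me[["a"]]) > 1) stop_invalid("mediation a path must be in [-1, 1]")
  unitize <- function(x, n, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != n) stop_invalid("%s must have length %d", what, n)
    x / sqrt(sum(x^2))
  }
  spec <- list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_clinical = as.integer(n_clinical),
    coupling_strength = coupling_strength, noise_sd = noise_sd,
    missing_rate = missing_rate, mediation_effects = me,
    confound_effects = confound_effects,
    latent_loadings_u = unitize(latent_loadings_u, n_regions, "latent_loadings_u"),
    latent_loadings_v = unitize(latent_loadings_v, n_clinical, "latent_loadings_v"),
    n_cognition = as.integer(n_cognition), seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a clinical latent `t_clin ~ N(0,1)` per subject and an imaging
#' latent `t_img = a t_clin + sqrt(1-a^2) eta`; the clinical block is
#' `coupling * t_clin * v' + B_c z(confounds) + noise`, the morphometric block
#' `coupling * t_img * u' + B_m z(confounds) + noise` (thickness-scaled so
#' values stay positive); cognition is `b t_img + c' t_clin + sigma eps` on
#' standardized latents. The planted loadings, latent scores and mediation
#' slopes are returned in `$truth`.
#'
#' @param spec a [cohort_spec()].
#' @return A `synthetic_cohort` list: `clinical`, `morph`, `confounds`,
#'   `cognition` data.frames sharing `subject_id`; `clinical_groups` (named
#'   character); `truth`; `spec`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- spec$n_regions
  q <- spec$n_clinical
  me <- spec$mediation_effects
  a <- me[["a"]]; b <- me[["b"]]; cp <- me[["c_prime"]]
  with_seed_(spec$seed, {
    u <- spec$latent_loadings_u %||% local({
      z <- stats::rnorm(p); z / sqrt(sum(z^2))
    })
    v <- spec$latent_loadings_v %||% local({
      z <- stats::rnorm(q); z / sqrt(sum(z^2))
    })
    t_clin <- stats::rnorm(n)
    t_img <- a * t_clin + sqrt(max(0, 1 - a^2)) * stats::rnorm(n)
    age <- stats::runif(n, 45, 80)
    sex <- stats::rbinom(n, 1, 0.5)
    education <- sample(1:5, n, replace = TRUE)
    cohort <- stats::rbinom(n, 1, 0.5)
    conf_raw <- cbind(age, sex, education, cohort)
    conf_z <- scale_cols(conf_raw)
    ce <- spec$confound_effects
    if (identical(ce, "default")) {
      ce <- list(clinical = matrix(stats::rnorm(4 * q, sd = 0.3), 4, q),
                 morph = matrix(stats::rnorm(4 * p, sd = 0.3), 4, p))
    }
    clin_conf <- if (is.null(ce)) 0 else conf_z %*% ce$clinical
    morph_conf <- if (is.null(ce)) 0 else conf_z %*% ce$morph
    clinical <- spec$coupling_strength * tcrossprod(t_clin, v) + clin_conf +
      spec$noise_sd * matrix(stats::rnorm(n * q), n, q)
    morph_raw <- spec$coupling_strength * tcrossprod(t_img, u) + morph_conf +
      spec$noise_sd * matrix(stats::rnorm(n * p), n, p)
    morph <- 2.5 + 0.2 * morph_raw  # thickness-like scale (mm), positive w.h.p.
    sigma_y <- sqrt(max(1 - (b^2 + cp^2 + 2 * a * b * cp), 0.05))
    cognition <- sapply(seq_len(spec$n_cognition), function(k)
      b * t_img + cp * t_clin + sigma_y * stats::rnorm(n))
    cognition <- matrix(cognition, n, spec$n_cognition)
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(n * q) < spec$missing_rate, n, q)
      clinical[mask] <- NA_real_
    }
  })
  ids <- sprintf("S%05d", seq_len(n))
  clin_names <- if (q == 12L) mets_variable_names() else sprintf("clin_%02d", seq_len(q))
  groups <- if (q == 12L) mets_variable_groups() else {
    g <- rep_len(c("obesity", "blood_pressure", "lipids", "glycemic"), q)
    stats::setNames(g, clin_names)
  }
  region_names <- sprintf("region_%03d", seq_len(p))
  colnames(clinical) <- clin_names
  colnames(morph) <- region_names
  cog_names <- sprintf("cog_test_%d", seq_len(spec$n_cognition))
  colnames(cognition) <- cog_names
  out <- list(
    clinical = data.frame(subject_id = ids, clinical, stringsAsFactors = FALSE),
    morph = data.frame(subject_id = ids, morph, stringsAsFactors = FALSE),
    confounds = data.frame(subject_id = ids, age = age, sex = sex,
                           education = education, cohort = cohort,
                           stringsAsFactors = FALSE),
    cognition = data.frame(subject_id = ids, cognition, stringsAsFactors = FALSE),
    clinical_groups = groups,
    truth = list(u = stats::setNames(u, region_names),
                 v = stats::setNames(v, clin_names),
                 t_clin = t_clin, t_img = t_img,
                 a = a, b = b, c_prime = cp,
                 coupling_strength = spec$coupling_strength,
                 noise_sd = spec$noise_sd),
    spec = spec
  )
  class(out) <- "synthetic_cohort"
  out
}
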