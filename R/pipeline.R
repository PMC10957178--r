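#' Pipeline configuration
#'
#' Validated container for every numeric constant and path the pipeline
#' uses. Defaults are the analysis constants: k = 4 imputation neighbours,
#' 5000 permutations, 5000 bootstrap resamples, 1000 spin permutations,
#' 10 cross-validation folds, alpha = 0.05, bootstrap-ratio threshold 1.96.
#' Unknown keys are rejected.
#'
#' @param input_dir directory holding the input bundle (see
#'   [write_bundle()] for the layout).
#' @param output_dir directory for stage outputs.
#' @param ... overrides of the defaults listed above (`stages`, `k_impute`,
#'   `n_perm`, `n_boot`, `n_spin`, `n_gcea`, `cv_folds`, `alpha`,
#'   `br_threshold`, `seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, ...) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir,
    stages = c("preprocess", "pls", "mediation", "context"),
    k_impute = 4L, n_perm = 5000L, n_boot = 5000L, n_spin = 1000L,
    n_gcea = 1000L, cv_folds = 10L, alpha = 0.05, br_threshold = 1.96,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  bad_stage <- setdiff(cfg$stages, c("preprocess", "pls", "mediation", "context"))
  if (length(bad_stage))
    stop_invalid("unknown stage(s): %s", paste(bad_stage, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

# Per-stage seeds derived from the master seed and the stage name, kept
# below 2^31 so they are valid R integer seeds.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  json_write(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Generate a complete synthetic study bundle
#'
#' One call producing every input the pipeline consumes, with consistent
#' parcel geometry: cohort tables ([gen_cohort()]), spherical parcellation,
#' functional and structural connectomes, and a cell-category expression
#' matrix whose signal categories load on a smooth map.
#'
#' @param n_subjects,n_parcels,n_clinical cohort dimensions (`n_parcels`
#'   doubles as the morphometric region count).
#' @param seed master seed; component seeds are derived from it.
#' @param n_categories,genes_per_category expression layout.
#' @param signal_categories categories that receive the smooth signal map.
#' @param ... further arguments to [cohort_spec()].
#' @return list: `cohort`, `geometry`, `connectome_functional`,
#'   `connectome_structural`, `expression`, `catalog`, `signal_map`.
#' @export
gen_study_bundle <- function(n_subjects = 500L, n_parcels = 100L,
                             n_clinical = 12L, seed = 1L,
                             n_categories = 10L, genes_per_category = 20L,
                             signal_categories = c("Cat01", "Cat02"), ...) {
  geometry <- gen_sphere_parcellation(n_parcels, seed = stage_seed(seed, "geometry"))
  signal_map <- gen_smooth_map(geometry, lengthscale = 50,
                               seed = stage_seed(seed, "signal_map"))
  expr <- gen_expression(geometry, n_categories, genes_per_category,
                         signal_map = signal_map,
                         signal_categories = signal_categories,
                         seed = stage_seed(seed, "expression"))
  dots <- list(...)
  if (is.null(dots$latent_loadings_u)) {
    # the planted morphometric loading pattern is the same smooth map the
    # signal gene categories express, so the latent effect map is spatially
    # autocorrelated and genuinely coupled to expression and connectome
    # neighbourhoods -- the regime the contextualization stage targets
    dots$latent_loadings_u <- as.numeric(signal_map)
  }
  cohort <- gen_cohort(do.call(cohort_spec, c(
    list(n_subjects, n_regions = n_parcels, n_clinical = n_clinical,
         seed = stage_seed(seed, "cohort")), dots)))
  list(
    cohort = cohort, geometry = geometry,
    connectome_functional = gen_connectome(geometry, n_modules = 4L,
                                           seed = stage_seed(seed, "fc")),
    connectome_structural = gen_connectome(geometry, decay = 40,
                                           density = 0.15, n_modules = 4L,
                                           seed = stage_seed(seed, "sc")),
    expression = expr$expression, catalog = expr$mapping,
    signal_map = signal_map
  )
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a study bundle as delimited text
#'
#' Emits the same formats the pipeline reads: CSV tables with header rows
#' (empty field = missing) plus a JSON sidecar holding the generator truth,
#' kept separate from the data tables.
#'
#' @param bundle a [gen_study_bundle()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- bundle$cohort
  utils::write.csv(co$clinical, file.path(dir, "clinical.csv"), row.names = FALSE, na = "")
  utils::write.csv(co$morph, file.path(dir, "morph.csv"), row.names = FALSE)
  utils::write.csv(co$confounds, file.path(dir, "confounds.csv"), row.names = FALSE)
  utils::write.csv(co$cognition, file.path(dir, "cognition.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = names(co$clinical_groups),
                              group = unname(co$clinical_groups)),
                   file.path(dir, "clinical_groups.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$geometry),
                   file.path(dir, "geometry.csv"), row.names = FALSE)
  write_matrix_csv(bundle$connectome_functional, file.path(dir, "connectome_functional.csv"))
  write_matrix_csv(bundle$connectome_structural, file.path(dir, "connectome_structural.csv"))
  write_matrix_csv(bundle$expression, file.path(dir, "expression.csv"))
  utils::write.csv(bundle$catalog, file.path(dir, "gene_catalog.csv"), row.names = FALSE)
  json_write(list(u = as.list(co$truth$u), v = as.list(co$truth$v),
                  a = co$truth$a, b = co$truth$b, c_prime = co$truth$c_prime,
                  coupling_strength = co$truth$coupling_strength,
                  noise_sd = co$truth$noise_sd),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Load and validate a study bundle
#'
#' Reads the delimited-text bundle, aligns subjects across tables by inner
#' join on `subject_id` (sorted), aligns morphometry columns to the geometry
#' parcel order, and emits a validation report (subject counts, per-column
#' missingness, constant columns). Duplicate subject ids and parcel
#' mismatches are errors.
#'
#' @param input_dir bundle directory.
#' @return list: `clinical`, `morph`, `confounds`, `cognition` (aligned
#'   data.frames), `clinical_groups`, `geometry`, connectomes, `expression`,
#'   `catalog`, `validation`.
#' @export
load_inputs <- function(input_dir) {
  rd <- function(f) utils::read.csv(file.path(input_dir, f),
                                    check.names = FALSE, stringsAsFactors = FALSE)
  clinical <- rd("clinical.csv"); morph <- rd("morph.csv")
  confounds <- rd("confounds.csv"); cognition <- rd("cognition.csv")
  groups_df <- rd("clinical_groups.csv")
  geometry <- rd("geometry.csv")
  class(geometry) <- c("parcel_geometry", "data.frame")
  for (tb in list(clinical = clinical, morph = morph, confounds = confounds,
                  cognition = cognition)) {
    dup <- tb$subject_id[duplicated(tb$subject_id)]
    if (length(dup))
      stop_invalid("duplicated subject_id: %s", paste(unique(dup), collapse = ", "))
  }
  common <- sort(Reduce(intersect, list(clinical$subject_id, morph$subject_id,
                                        confounds$subject_id, cognition$subject_id)))
  if (length(common) < 3) stop_invalid("subject overlap < 3 across tables")
  align <- function(tb) tb[match(common, tb$subject_id), , drop = FALSE]
  clinical <- align(clinical); morph <- align(morph)
  confounds <- align(confounds); cognition <- align(cognition)
  parcel_cols <- setdiff(names(morph), "subject_id")
  missing_parcels <- setdiff(geometry$parcel_id, parcel_cols)
  extra_parcels <- setdiff(parcel_cols, geometry$parcel_id)
  if (length(missing_parcels) || length(extra_parcels)) {
    # region tables generated without geometry naming are accepted as-is if
    # counts match; otherwise the offenders are named
    if (length(parcel_cols) != nrow(geometry))
      stop_invalid("parcel mismatch; missing: %s; extra: %s",
                   paste(utils::head(missing_parcels, 5), collapse = ", "),
                   paste(utils::head(extra_parcels, 5), collapse = ", "))
  } else {
    morph <- morph[, c("subject_id", geometry$parcel_id)]
  }
  conn_f <- read_matrix_csv(file.path(input_dir, "connectome_functional.csv"))
  conn_s <- read_matrix_csv(file.path(input_dir, "connectome_structural.csv"))
  expr <- read_matrix_csv(file.path(input_dir, "expression.csv"))
  catalog <- rd("gene_catalog.csv")
  clin_mat <- clinical[, setdiff(names(clinical), "subject_id")]
  validation <- list(
    n_subjects = length(common),
    n_missing_clinical = colSums(is.na(clin_mat)),
    constant_columns = names(clin_mat)[vapply(clin_mat, function(x)
      stats::sd(x, na.rm = TRUE) == 0, logical(1))]
  )
  list(clinical = clinical, morph = morph, confounds = confounds,
       cognition = cognition,
       clinical_groups = stats::setNames(groups_df$group, groups_df$variable),
       geometry = geometry, connectome_functional = conn_f,
       connectome_structural = conn_s, expression = expr, catalog = catalog,
       validation = validation)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a loaded bundle: preprocessing
#' (group-restricted k-NN imputation, confound residualization, z-scoring),
#' PLS correlation with permutation/bootstrap/cross-validation inference,
#' batch mediation of cognition columns by the first latent variable's
#' scores, and contextualization of the first latent variable's bootstrap
#' ratio map (degree centrality, neighborhood abnormality, gradients,
#' gene-category enrichment) with spatially constrained nulls. Every stage
#' writes its outputs plus a provenance block; reruns with the same config
#' are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_inputs(config$input_dir)
  prov <- list(config = unclass(config), config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("brainpls")),
               n_subjects = inputs$validation$n_subjects)
  json_write(prov, file.path(out, "provenance.json"))

  run_stage <- function(name, body) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(body, error = function(e) {
      stop_invalid("stage '%s' failed: %s (partial outputs preserved in %s)",
                   name, conditionMessage(e), out)
    })
  }

  X <- Y <- NULL
  run_stage("preprocess", {
    clin <- impute_knn(inputs$clinical, inputs$clinical_groups, k = config$k_impute)
    Yr <- residualize_confounds(clin, inputs$confounds)
    Xr <- residualize_confounds(inputs$morph, inputs$confounds)
    Y <- zscore_columns(Yr)
    X <- zscore_columns(Xr)
    write_matrix_csv(`rownames<-`(X, inputs$morph$subject_id), file.path(out, "X_preprocessed.csv"))
    write_matrix_csv(`rownames<-`(Y, inputs$clinical$subject_id), file.path(out, "Y_preprocessed.csv"))
  })

  fit <- NULL
  run_stage("pls", {
    if (is.null(X)) stop("pls requires the preprocess stage")
    fit <- pls_fit(X, Y, n_perm = config$n_perm, n_boot = config$n_boot,
                    cv_folds = config$cv_folds,
                    seed = stage_seed(config$seed, "pls"))
    write_matrix_csv(fit$U, file.path(out, "U.csv"))
    write_matrix_csv(fit$V, file.path(out, "V.csv"))
    write_matrix_csv(fit$boot_ratio, file.path(out, "boot_ratio.csv"))
    sc <- cbind(imaging = fit$scores_imaging[, 1], clinical = fit$scores_clinical[, 1])
    rownames(sc) <- inputs$morph$subject_id
    write_matrix_csv(sc, file.path(out, "scores_lv1.csv"))
    json_write(list(delta = fit$delta,
                    explained_variance = fit$explained_variance,
                    perm_p = fit$perm_p, score_spearman = fit$score_spearman,
                    cv_mean_spearman = fit$cv$mean_spearman,
                    n_significant_regions_lv1 =
                      sum(abs(fit$boot_ratio[, 1]) > config$br_threshold),
                    n_perm = config$n_perm, n_boot = config$n_boot,
                    seed = stage_seed(config$seed, "pls")),
               file.path(out, "pls_summary.json"))
  })

  run_stage("mediation", {
    if (is.null(fit)) stop("mediation requires the pls stage")
    med <- mediate_batch(fit$scores_clinical[, 1], fit$scores_imaging[, 1],
                         inputs$cognition,
                         covariates = inputs$confounds[, c("age", "sex", "education")],
                         n_boot = config$n_boot,
                         seed = stage_seed(config$seed, "mediation"),
                         alpha = config$alpha)
    utils::write.csv(med, file.path(out, "mediation.csv"), row.names = FALSE)
  })

  run_stage("context", {
    if (is.null(fit)) stop("context requires the pls stage")
    br <- fit$boot_ratio[, 1]
    seed_c <- stage_seed(config$seed, "context")
    perms <- spin_permutation_indices(inputs$geometry, n = config$n_spin,
                                      seed = seed_c)
    rows <- list()
    for (mod in c("functional", "structural")) {
      conn <- inputs[[paste0("connectome_", mod)]]
      deg <- degree_centrality_rank(conn)
      nab <- neighborhood_abnormality(conn, br)
      r1 <- spatial_correlation(deg, br, nulls = "spin", n_null = config$n_spin,
                                geometry = inputs$geometry, seed = seed_c,
                                spin_perms = perms)
      r2 <- spatial_correlation(nab, br, nulls = c("spin", "rewire"),
                                n_null = config$n_spin,
                                geometry = inputs$geometry, connectome = conn,
                                base_map = br, seed = seed_c, spin_perms = perms)
      rows[[paste0(mod, "_degree")]] <- c(rsp = r1$rsp, p_spin = r1$p_spin, p_rewire = NA)
      rows[[paste0(mod, "_neighborhood")]] <- c(rsp = r2$rsp, p_spin = r2$p_spin,
                                                p_rewire = r2$p_rewire)
    }
    grads <- connectivity_gradients(inputs$connectome_functional, 2L)
    for (g in 1:2) {
      rg <- spatial_correlation(grads[, g], br, nulls = "spin",
                                n_null = config$n_spin,
                                geometry = inputs$geometry, seed = seed_c,
                                spin_perms = perms)
      rows[[paste0("functional_gradient_", g)]] <- c(rsp = rg$rsp,
                                                     p_spin = rg$p_spin,
                                                     p_rewire = NA)
    }
    net <- data.frame(comparison = names(rows), do.call(rbind, rows),
                      row.names = NULL, stringsAsFactors = FALSE)
    net$q_spin <- fdr_adjust(net$p_spin)
    utils::write.csv(net, file.path(out, "context_network.csv"), row.names = FALSE)
    gcea <- gcea_cell_types(br, inputs$expression, inputs$catalog,
                            n_surrogates = config$n_gcea,
                            seed = seed_c, geometry = inputs$geometry)
    utils::write.csv(gcea, file.path(out, "context_gcea.csv"), row.names = FALSE)
  })
  invisible(out)
}

#' Write a human-readable summary report
#'
#' Collates the stage outputs of [run_pipeline()] into one markdown
#' document: explained variance and permutation p per latent variable,
#' significant clinical loadings, bootstrap-ratio counts, the mediation
#' table, and the contextualization tables. Sections whose stage did not run
#' are marked "not run". Regeneration is byte-identical.
#'
#' @param results_dir a [run_pipeline()] output directory.
#' @return path to `report.md`, invisibly.
#' @export
write_report <- function(results_dir) {
  lines <- c("# Analysis report", "")
  pls_file <- file.path(results_dir, "pls_summary.json")
  if (file.exists(pls_file)) {
    s <- jsonlite::read_json(pls_file, simplifyVector = TRUE)
    lines <- c(lines, "## Latent variables", "")
    for (j in seq_along(s$explained_variance))
      lines <- c(lines, sprintf("- LV%d: explained variance %.2f%%, permutation p = %.4g",
                                j, 100 * s$explained_variance[j], s$perm_p[j]))
    lines <- c(lines, "",
               sprintf("Explained variance total: %.2f%%", 100 * sum(s$explained_variance)),
               sprintf("LV1 subject-score Spearman correlation: %.3f", s$score_spearman[1]),
               sprintf("LV1 mean out-of-sample score correlation (cross-validated): %.3f",
                       (s$cv_mean_spearman %||% NA_real_)[1]),
               sprintf("Regions with |bootstrap ratio| > threshold on LV1: %d",
                       s$n_significant_regions_lv1), "")
  } else lines <- c(lines, "## Latent variables", "", "not run", "")
  med_file <- file.path(results_dir, "mediation.csv")
  lines <- c(lines, "## Mediation", "")
  if (file.exists(med_file)) {
    med <- utils::read.csv(med_file, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(med)))
      lines <- c(lines, sprintf(
        "- %s: a=%.3f, b=%.3f, ab=%.3f [%.3f, %.3f], c'=%.3f, c=%.3f, q_ab=%.4g -> %s",
        med$test[i], med$a[i], med$b[i], med$ab[i], med$ci_ab_lower[i],
        med$ci_ab_upper[i], med$c_prime[i], med$c[i], med$q_ab[i], med$class[i]))
  } else lines <- c(lines, "not run")
  lines <- c(lines, "", "## Contextualization", "")
  net_file <- file.path(results_dir, "context_network.csv")
  if (file.exists(net_file)) {
    net <- utils::read.csv(net_file, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(net)))
      lines <- c(lines, sprintf("- %s: rsp=%.3f, p_spin=%.4g%s",
                                net$comparison[i], net$rsp[i], net$p_spin[i],
                                ifelse(is.na(net$p_rewire[i]), "",
                                       sprintf(", p_rewire=%.4g", net$p_rewire[i]))))
    gcea <- utils::read.csv(file.path(results_dir, "context_gcea.csv"),
                            stringsAsFactors = FALSE)
    lines <- c(lines, "", "### Gene-category enrichment", "")
    for (i in seq_len(nrow(gcea)))
      lines <- c(lines, sprintf("- %s (%d genes): Z(rsp)=%.3f, q=%.4g%s",
                                gcea$category[i], gcea$n_genes[i], gcea$z_rsp[i],
                                gcea$q[i], ifelse(gcea$q[i] < 0.05, " *", "")))
  } else lines <- c(lines, "not run")
  path <- file.path(results_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
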