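#' Group-restricted k-nearest-neighbour imputation
#'
#' Replaces each missing clinical value by the unweighted mean of the k
#' nearest subjects' observed values for that variable. Neighbour distances
#' are Euclidean over the z-scored variables of the *same* variable group
#' (e.g. a missing HDL is imputed from subjects close in the lipid block),
#' restricted to columns observed for both subjects. If a subject has no
#' observed variable in the group, distances fall back to all clinical
#' variables and a warning is issued. Ties are broken by subject order.
#'
#' @param data data.frame or matrix of clinical variables (may contain `NA`);
#'   a `subject_id` column, if present, is carried through untouched.
#' @param groups named character vector mapping variable name to group label;
#'   must cover every clinical column.
#' @param k number of neighbours (default 4).
#' @return object of the same shape with missing cells imputed.
#' @export
impute_knn <- function(data, groups, k = 4L) {
  id_col <- NULL
  df <- data
  if (is.data.frame(df) && "subject_id" %in% names(df)) {
    id_col <- df$subject_id
    df <- df[, setdiff(names(df), "subject_id"), drop = FALSE]
  }
  m <- as.matrix(df)
  if (!all(colnames(m) %in% names(groups)))
    stop_invalid("groups must label every clinical variable")
  if (!anyNA(m)) return(data)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  out <- m
  fell_back <- FALSE
  for (s in which(rowSums(is.na(m)) > 0)) {
    for (vj in which(is.na(m[s, ]))) {
      grp <- groups[[colnames(m)[vj]]]
      gcols <- which(colnames(m) %in% names(groups)[groups == grp])
      feat <- setdiff(gcols, vj)
      if (!length(feat) || all(is.na(m[s, feat]))) {
        feat <- setdiff(which(!is.na(m[s, ])), vj)
        fell_back <- TRUE
      }
      donors <- which(!is.na(m[, vj]) & seq_len(nrow(m)) != s)
      feat_s <- feat[!is.na(z[s, feat])]
      if (length(feat_s)) {
        zd <- z[donors, feat_s, drop = FALSE]
        sq <- sweep(zd, 2, z[s, feat_s], "-")^2
        # mean squared difference keeps partially observed donors comparable
        dd <- sqrt(rowMeans(sq, na.rm = TRUE))
        dd[rowSums(!is.na(sq)) == 0] <- Inf
      } else {
        dd <- rep(Inf, length(donors))
      }
      ord <- donors[order(dd, donors)]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[s, vj] <- mean(m[nn, vj])
    }
  }
  if (fell_back)
    warning("subject(s) with an entirely missing variable group; imputed from all clinical variables", call. = FALSE)
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  if (!is.null(id_col)) res <- cbind(subject_id = id_col, res)
  if (is.matrix(data)) res <- out
  res
}

#' Regress confounds out of every column
#'
#' Replaces each column by its OLS residuals against an intercept plus the
#' confound columns, so residuals are exactly orthogonal to each confound.
#'
#' @param data numeric matrix/data.frame (subjects x variables), complete.
#' @param confounds data.frame/matrix of confounds (complete); a
#'   `subject_id` column is dropped.
#' @return matrix of residuals with the input's dimnames.
#' @export
residualize_confounds <- function(data, confounds) {
  x <- as.matrix(drop_id(data))
  cf <- as.matrix(drop_id(confounds))
  if (anyNA(cf)) stop_invalid("confounds must be complete")
  if (nrow(x) <= ncol(cf) + 1)
    stop_invalid("need n_subjects > n_confounds + 1")
  design <- cbind(intercept = 1, cf)
  qr_ <- qr(design)
  if (qr_$rank < ncol(design)) {
    dropped <- utils::tail(colnames(design)[qr_$pivot], ncol(design) - qr_$rank)
    stop_invalid("confound matrix is rank deficient (collinear: %s)",
                 paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qr_, x)
  dimnames(res) <- dimnames(x)
  res
}

drop_id <- function(x) {
  if (is.data.frame(x) && "subject_id" %in% names(x))
    x <- x[, setdiff(names(x), "subject_id"), drop = FALSE]
  x
}

#' Z-score every column (sample SD, ddof = 1)
#'
#' @param data numeric matrix/data.frame; constant columns are an error.
#' @return matrix with column means 0 and sample SD 1.
#' @export
zscore_columns <- function(data) {
  m <- as.matrix(drop_id(data))
  sdv <- apply(m, 2, stats::sd)
  if (any(sdv == 0 | !is.finite(sdv))) {
    bad <- colnames(m)[sdv == 0 | !is.finite(sdv)]
    stop_invalid("constant or degenerate column(s): %s", paste(bad, collapse = ", "))
  }
  scale_cols(m)
}

#' Harmonize a score across cohorts
#'
#' Z-scores within each cohort, then z-scores the pooled result once more,
#' removing cohort-specific location and scale (e.g. different versions of
#' the same cognitive test).
#'
#' @param values numeric vector (may contain `NA`, which are preserved).
#' @param cohort cohort label per subject.
#' @return harmonized numeric vector.
#' @export
harmonize_across_cohorts <- function(values, cohort) {
  stopifnot(length(values) == length(cohort))
  out <- rep(NA_real_, length(values))
  for (g in unique(cohort)) {
    idx <- which(cohort == g & !is.na(values))
    if (length(idx) < 3)
      stop_invalid("cohort %s has fewer than 3 observed values", g)
    s <- stats::sd(values[idx])
    if (s == 0) stop_invalid("cohort %s has constant values", g)
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  obs <- !is.na(out)
  out[obs] <- (out[obs] - mean(out[obs])) / stats::sd(out[obs])
  out
}

#' Default metabolic-syndrome classification thresholds
#'
#' Conventional consensus-style cut-offs: sex-specific waist circumference,
#' triglycerides >= 150 mg/dL, HDL < 40 (men) / < 50 (women) mg/dL, blood
#' pressure >= 130/85 mmHg or antihypertensive treatment, fasting glucose
#' >= 100 mg/dL or antidiabetic treatment. All overridable.
#' @export
mets_thresholds <- function() {
  list(waist_male = 94, waist_female = 80,
       tg = 150, hdl_male = 40, hdl_female = 50,
       sbp = 130, dbp = 85, glucose = 100)
}

#' Binary metabolic-syndrome classification
#'
#' Positive iff the central-obesity criterion holds AND at least two of:
#' elevated triglycerides, low HDL (sex-specific), elevated blood pressure or
#' antihypertensive therapy, elevated glucose or antidiabetic therapy.
#'
#' @param table data.frame with columns `waist`, `tg`, `hdl`, `sbp`, `dbp`,
#'   `glucose`, `sex` (1 = male, 0 = female) and optional logical
#'   `bp_treatment`, `glucose_treatment`.
#' @param thresholds list of cut-offs, see [mets_thresholds()].
#' @return logical vector of labels.
#' @export
classify_mets <- function(table, thresholds = mets_thresholds()) {
  req <- c("waist", "tg", "hdl", "sbp", "dbp", "glucose", "sex")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop_invalid("missing required variable(s): %s", paste(miss, collapse = ", "))
  if (anyNA(table[req]))
    stop_invalid("required variables contain missing values; impute first")
  th <- thresholds
  male <- table$sex == 1
  obesity <- table$waist >= ifelse(male, th$waist_male, th$waist_female)
  high_tg <- table$tg >= th$tg
  low_hdl <- table$hdl < ifelse(male, th$hdl_male, th$hdl_female)
  bp_tx <- if ("bp_treatment" %in% names(table)) as.logical(table$bp_treatment) else FALSE
  glu_tx <- if ("glucose_treatment" %in% names(table)) as.logical(table$glucose_treatment) else FALSE
  high_bp <- table$sbp >= th$sbp | table$dbp >= th$dbp | bp_tx
  high_glu <- table$glucose >= th$glucose | glu_tx
  obesity & (high_tg + low_hdl + high_bp + high_glu) >= 2
}

#' Greedy 1:1 case-control matching on Mahalanobis distance
#'
#' Matches each case to its nearest unused control by Mahalanobis distance
#' over the supplied covariates, processing cases in a seeded random order
#' (without replacement). Returns the pairing and standardized mean
#' differences before/after matching as balance diagnostics.
#'
#' @param cases,pool character/integer subject identifiers (rows of
#'   `covariates`); `pool` must be at least as large as `cases`.
#' @param covariates data.frame of matching covariates indexed by
#'   `subject_id` column or rownames.
#' @param seed integer seed for the case processing order.
#' @return list with `pairs` (data.frame case, control, distance) and
#'   `balance` (data.frame covariate, smd_before, smd_after).
#' @export
match_cases_controls <- function(cases, pool, covariates, seed = 1L) {
  if (length(pool) < length(cases))
    stop_invalid("control pool (%d) smaller than case list (%d)",
                 length(pool), length(cases))
  ids <- if ("subject_id" %in% names(covariates)) covariates$subject_id else rownames(covariates)
  cv <- as.matrix(drop_id(covariates))
  rownames(cv) <- ids
  all_used <- cv[c(cases, pool), , drop = FALSE]
  S <- stats::cov(all_used)
  Sinv <- solve(S + diag(1e-10, ncol(S)))
  order_cases <- with_seed_(seed, sample(cases))
  avail <- pool
  pairs <- data.frame(case = character(0), control = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  for (cs in order_cases) {
    diffs <- sweep(cv[avail, , drop = FALSE], 2, cv[cs, ], "-")
    d2 <- rowSums((diffs %*% Sinv) * diffs)
    best <- which.min(d2)  # which.min takes the first index on ties
    pairs <- rbind(pairs, data.frame(case = cs, control = avail[best],
                                     distance = sqrt(d2[best]),
                                     stringsAsFactors = FALSE))
    avail <- avail[-best]
  }
  pairs <- pairs[match(cases, pairs$case), ]
  rownames(pairs) <- NULL
  smd <- function(ctrl_ids) {
    vapply(seq_len(ncol(cv)), function(j) {
      xc <- cv[cases, j]; xk <- cv[ctrl_ids, j]
      sp <- sqrt((stats::var(xc) + stats::var(xk)) / 2)
      if (sp == 0) 0 else (mean(xc) - mean(xk)) / sp
    }, numeric(1))
  }
  balance <- data.frame(covariate = colnames(cv),
                        smd_before = smd(pool),
                        smd_after = smd(pairs$control),
                        stringsAsFactors = FALSE)
  list(pairs = pairs, balance = balance)
}

#' Parcel-wise group-difference t-map with FDR correction
#'
#' Fits, per parcel, an OLS of the morphometric measure on an intercept, the
#' binary group label, and the confounds; returns the group-coefficient
#' t-statistic per parcel with Benjamini-Hochberg q-values.
#'
#' @param morph subjects x parcels matrix/data.frame.
#' @param labels binary group indicator per subject.
#' @param confounds confound data.frame (complete).
#' @return data.frame parcel, t, p, q.
#' @export
group_difference_map <- function(morph, labels, confounds) {
  x <- as.matrix(drop_id(morph))
  g <- as.numeric(labels)
  if (length(unique(g)) < 2) stop_invalid("both groups must be non-empty")
  cf <- as.matrix(drop_id(confounds))
  design <- cbind(intercept = 1, group = g, cf)
  qr_ <- qr(design)
  if (qr_$rank < ncol(design))
    warning("design matrix not full rank; proceeding with pivoted fit", call. = FALSE)
  coefs <- qr.coef(qr_, x)
  res <- qr.resid(qr_, x)
  df <- nrow(x) - qr_$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_))
  se_g <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- coefs["group", ] / se_g
  pval <- 2 * stats::pt(-abs(tval), df)
  data.frame(parcel = colnames(x) %||% seq_along(tval),
             t = unname(tval), p = unname(pval),
             q = stats::p.adjust(pval, method = "BH"),
             stringsAsFactors = FALSE)
}
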