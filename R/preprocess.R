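#' Average left/right hemisphere measures
#'
#' Regional tables exported per hemisphere carry paired columns `lh_<region>`
#' and `rh_<region>`; analysis uses their mean. Tables without any `lh_`/
#' `rh_` columns are assumed already averaged and returned unchanged.
#'
#' @param table data.frame with per-hemisphere columns and arbitrary
#'   metadata columns.
#' @return data.frame with one `<region>` column per pair, metadata columns
#'   untouched.
#' @export
average_hemispheres <- function(table) {
  nm <- names(table)
  lh <- nm[startsWith(nm, "lh_")]
  rh <- nm[startsWith(nm, "rh_")]
  if (!length(lh) && !length(rh)) return(table)
  reg_l <- substring(lh, 4L)
  reg_r <- substring(rh, 4L)
  unpaired <- c(setdiff(reg_l, reg_r), setdiff(reg_r, reg_l))
  if (length(unpaired)) {
    stop("unpaired region (one hemisphere missing): ",
         paste(unpaired, collapse = ", "))
  }
  out <- table[, setdiff(nm, c(lh, rh)), drop = FALSE]
  for (r in reg_l) out[[r]] <- (table[[paste0("lh_", r)]] +
                                  table[[paste0("rh_", r)]]) / 2
  out
}

# vectorized per-column OLS slope of each feature on a single regressor z
.ols_slopes <- function(xmat, z) {
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom <= 0) stop("zero variance in regressor")
  drop(crossprod(as.matrix(xmat), zc)) / denom
}

#' Fit head-size (eTIV) adjustment for volumetric features
#'
#' Per volumetric feature, the ordinary-least-squares slope on estimated
#' total intracranial volume is fitted over a designated reference set
#' (typically the amyloid-negative CN training subjects). Thickness features
#' are exempt: no slope is stored for them.
#'
#' @param table regional measure table (averaged hemispheres) with an `eTIV`
#'   column.
#' @param reference_ids subject ids the slopes are fitted on (>= 3).
#' @param volumes character vector of volumetric feature names.
#' @return list with `slopes` (named, volumes only), `ref_mean` (reference
#'   mean eTIV) and `reference_ids`.
#' @export
fit_etiv_adjustment <- function(table, reference_ids, volumes) {
  ref <- table[table$subject_id %in% reference_ids, , drop = FALSE]
  if (nrow(ref) < 3L) stop("need at least 3 reference subjects")
  if (stats::sd(ref$eTIV) == 0) stop("zero variance in eTIV among reference subjects")
  slopes <- .ols_slopes(ref[, volumes, drop = FALSE], ref$eTIV)
  names(slopes) <- volumes
  list(slopes = slopes, ref_mean = mean(ref$eTIV),
       reference_ids = ref$subject_id)
}

#' Apply a fitted eTIV adjustment
#'
#' `adjusted = raw - slope * (eTIV - ref_mean)` for each volumetric feature;
#' thickness features pass through unchanged. Applying frozen parameters is
#' pure: no refitting occurs.
#'
#' @param table regional measure table.
#' @param params result of [fit_etiv_adjustment()].
#' @return the table with adjusted volumetric columns.
#' @export
apply_etiv_adjustment <- function(table, params) {
  if (anyNA(table$eTIV)) stop("missing eTIV for some subjects")
  d <- table$eTIV - params$ref_mean
  for (v in names(params$slopes)) table[[v]] <- table[[v]] - params$slopes[[v]] * d
  table
}

#' Fit normative age detrending
#'
#' Per feature, an OLS slope on age is fitted within a cognitively normal
#' reference set, under the normative assumption that feature change in that
#' group reflects aging rather than disease. Runs after eTIV adjustment.
#'
#' @param table regional measure table (eTIV-adjusted).
#' @param reference_ids CN reference subject ids (>= 3, age variance > 0).
#' @param features feature names to detrend (all 51 by default usage).
#' @return list with `slopes` (named), `ref_mean` (reference mean age) and
#'   `reference_ids`.
#' @export
fit_age_detrend <- function(table, reference_ids, features) {
  ref <- table[table$subject_id %in% reference_ids, , drop = FALSE]
  if (nrow(ref) < 3L) stop("need at least 3 reference subjects")
  if (stats::sd(ref$age) == 0) stop("zero age variance in reference subjects")
  slopes <- .ols_slopes(ref[, features, drop = FALSE], ref$age)
  names(slopes) <- features
  list(slopes = slopes, ref_mean = mean(ref$age),
       reference_ids = ref$subject_id)
}

#' Apply fitted age detrending to any subjects
#'
#' Every subject, regardless of group, gets `feature - slope * (age -
#' ref_mean)`: disease-related deficits (age-independent) are preserved in
#' expectation.
#'
#' @param table regional measure table with an `age` column.
#' @param params result of [fit_age_detrend()].
#' @return the table with detrended feature columns.
#' @export
apply_age_detrend <- function(table, params) {
  d <- table$age - params$ref_mean
  for (f in names(params$slopes)) table[[f]] <- table[[f]] - params$slopes[[f]] * d
  table
}

#' Fit and apply unit-variance scaling / mean centering
#'
#' `fit_scaler()` learns per-feature means and SDs on the training table;
#' `apply_scaler()` centers and scales any table with the stored training
#' statistics, returning the numeric matrix fed to [opls()].
#'
#' @param table regional measure table.
#' @param features feature names.
#' @return `fit_scaler()`: list with `center`, `scale` (named vectors) and
#'   `features`; `apply_scaler()`: numeric matrix (subjects x features).
#' @export
fit_scaler <- function(table, features) {
  x <- as.matrix(table[, features, drop = FALSE])
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  if (any(sc == 0)) {
    stop("zero-SD feature(s): ", paste(features[sc == 0], collapse = ", "))
  }
  list(center = ctr, scale = sc, features = features)
}

#' @rdname fit_scaler
#' @param params result of `fit_scaler()`.
#' @export
apply_scaler <- function(table, params) {
  x <- as.matrix(table[, params$features, drop = FALSE])
  x <- sweep(x, 2, params$center, "-")
  x <- sweep(x, 2, params$scale, "/")
  rownames(x) <- table$subject_id
  x
}

#' Within-group PCA outlier screen
#'
#' Principal component analysis is run within each study group on the
#' feature panel (standardized by default) and subjects whose score on the
#' first or second component exceeds `threshold` standard deviations of that
#' component are flagged. The caller decides whether to remove them.
#'
#' @param table regional measure table with a `group` column.
#' @param features feature names.
#' @param n_components components screened (default 2).
#' @param threshold flag threshold in component SDs (default 4).
#' @param standardize use correlation-matrix PCA (default TRUE).
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   per-component scores `PC1..`, and logical `flagged`.
#' @export
pca_outlier_screen <- function(table, features, n_components = 2,
                               threshold = 4, standardize = TRUE) {
  out <- lapply(split(table, table$group), function(g) {
    if (nrow(g) < 3L) stop("each screened group needs >= 3 members")
    pc <- stats::prcomp(as.matrix(g[, features, drop = FALSE]),
                        center = TRUE, scale. = standardize)
    k <- min(n_components, ncol(pc$x))
    sco <- pc$x[, seq_len(k), drop = FALSE]
    sds <- apply(sco, 2, stats::sd)
    flagged <- rowSums(abs(sco) > threshold *
                         rep(sds, each = nrow(sco))) > 0
    data.frame(subject_id = g$subject_id, group = g$group,
               sco, flagged = flagged, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}

#' Age- and sex-match controls to a case group
#'
#' One-to-one matching without replacement: exact on sex, and within each
#' sex the assignment minimizing the total absolute age difference. Because
#' ages live on a line, the optimal assignment pairs age-sorted cases with
#' an age-sorted subset of the pool without crossings, which is found
#' exactly by dynamic programming; ties (equal ages) are broken
#' deterministically by ascending subject id.
#'
#' @param cn_pool data.frame of candidate controls (`subject_id`, `age`,
#'   `sex`).
#' @param cases data.frame of cases (`subject_id`, `age`, `sex`).
#' @return character vector of matched control subject ids, one per case,
#'   in the order of the age-sorted cases (within sex).
#' @export
match_controls <- function(cn_pool, cases) {
  for (s in unique(cases$sex)) {
    if (sum(cn_pool$sex == s) < sum(cases$sex == s)) {
      stop("insufficient controls of sex ", s)
    }
  }
  matched <- character(0)
  for (s in unique(cases$sex)) {
    ca <- cases[cases$sex == s, ]
    ca <- ca[order(ca$age, ca$subject_id), ]
    po <- cn_pool[cn_pool$sex == s, ]
    po <- po[order(po$age, po$subject_id), ]
    m <- nrow(ca)
    n <- nrow(po)
    # cost[i+1, j+1]: best total |age difference| matching the first i
    # cases to a subset of the first j controls
    cost <- matrix(Inf, m + 1, n + 1)
    cost[1, ] <- 0
    for (i in seq_len(m)) {
      for (j in i:n) {
        cost[i + 1, j + 1] <- min(cost[i + 1, j],
                                  cost[i, j] + abs(ca$age[i] - po$age[j]))
      }
    }
    pick <- integer(m)
    j <- n
    for (i in m:1) {
      while (j > i && cost[i + 1, j] <= cost[i, j] +
             abs(ca$age[i] - po$age[j]) + 1e-12) {
        j <- j - 1
      }
      pick[i] <- j
      j <- j - 1
    }
    matched <- c(matched, po$subject_id[pick])
  }
  matched
}
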