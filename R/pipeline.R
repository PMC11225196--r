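#' Assemble a pipeline run configuration
#'
#' @param cohort a [cohort_spec()] (the simulator settings) or `NULL` when
#'   `measures`/`subjects`/`followup` tables are supplied to
#'   [run_pipeline()] directly.
#' @param atlas a [region_atlas()].
#' @param flavors model flavors to build: `"dementia-based"`,
#'   `"aMCI-based"` or both.
#' @param n_ortho orthogonal OPLS components.
#' @param cv_k cross-validation folds.
#' @param prune_passes minimal-atrophy pruning passes.
#' @param bandwidth cutoff smoothing bandwidth (`NULL` = Silverman).
#' @param gds_threshold GDS score defining progression.
#' @param seed global seed; each stochastic stage derives its own seed from
#'   it deterministically (seed fan-out).
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(cohort = cohort_spec(), atlas = default_atlas(),
                       flavors = c("dementia-based", "aMCI-based"),
                       n_ortho = 1, cv_k = 10, prune_passes = 1,
                       bandwidth = NULL, gds_threshold = 3, seed = 1L,
                       out_dir = NULL) {
  flavors <- match.arg(flavors, several.ok = TRUE)
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(cohort = cohort, atlas = atlas, flavors = flavors,
                 n_ortho = n_ortho, cv_k = cv_k,
                 prune_passes = prune_passes, bandwidth = bandwidth,
                 gds_threshold = gds_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# deterministic per-stage seed fan-out from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, followup = 23L, model_dementia = 37L,
               model_amci = 41L, events = 53L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Validate a regional measure table against the expected schema
#'
#' Checks column presence, duplicate subject ids, missing feature values
#' and non-positive thickness/volume/eTIV entries. Violations are returned,
#' not thrown, so callers can decide whether to hard-fail.
#'
#' @param table a regional measure table (data.frame) or a path to a CSV
#'   file.
#' @param features expected feature columns.
#' @return data.frame of violations (`row`, `column`, `problem`); zero rows
#'   when the table is well formed.
#' @export
validate_tables <- function(table, features = atlas_regions(default_atlas())) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  v <- list()
  note <- function(row, column, problem) {
    v[[length(v) + 1]] <<- data.frame(row = row, column = column,
                                      problem = problem,
                                      stringsAsFactors = FALSE)
  }
  for (col in setdiff(c("subject_id", "age", "sex", "eTIV", features),
                      names(table))) {
    note(NA_integer_, col, "missing column")
  }
  if ("subject_id" %in% names(table)) {
    dup <- table$subject_id[duplicated(table$subject_id)]
    for (d in unique(dup)) note(NA_integer_, "subject_id",
                                paste("duplicated id:", d))
  }
  for (col in intersect(c("eTIV", features), names(table))) {
    x <- table[[col]]
    if (!is.numeric(x)) { note(NA_integer_, col, "non-numeric"); next }
    for (i in which(is.na(x))) note(i, col, "missing value")
    for (i in which(!is.na(x) & x <= 0)) note(i, col, "non-positive value")
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(0), column = character(0),
               problem = character(0), stringsAsFactors = FALSE)
}

#' Run the full severity-index workflow
#'
#' Simulates a cohort (or takes supplied tables), builds a severity model
#' per requested flavor, projects the SCD group, derives progression events
#' from follow-up, and evaluates each flavor against progression
#' (confusion metrics, ROC/AUC, Kaplan-Meier + log-rank, Cox models with
#' classification, amyloid status and sex as covariates), plus a paired
#' DeLong comparison when both flavors are built. Fully seeded; a run
#' manifest with per-stage subject counts is returned (and written to
#' `config$out_dir` when set).
#'
#' @param config a [run_config()].
#' @param measures,subjects,followup optional pre-generated tables
#'   (defaults: simulated from `config$cohort`).
#' @return An object of class `run_manifest`: list with `config`, `counts`,
#'   `models` (per flavor), `classifications`, `events`, `evaluation` (per
#'   flavor: `confusion`, `roc`, `km`, `logrank`, `cox`) and `comparison`
#'   (DeLong, or a notice when a single flavor was built).
#' @export
run_pipeline <- function(config, measures = NULL, subjects = NULL,
                         followup = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (is.null(measures)) {
    cohort <- generate_cohort(config$cohort, config$atlas,
                              seed = stage_seed(seed, "simulate"))
    measures <- cohort$measures
    subjects <- cohort$subjects
  }
  viol <- validate_tables(measures, atlas_regions(config$atlas))
  if (nrow(viol)) {
    stop("stage validate: ", nrow(viol), " schema violation(s); first: ",
         viol$problem[1], " [", viol$column[1], "]")
  }
  grp <- function(g) measures[measures$group == g, , drop = FALSE]
  cn <- grp("CN"); amci <- grp("aMCI"); dem <- grp("DEM"); scd <- grp("SCD")

  models <- list()
  classifications <- list()
  for (fl in config$flavors) {
    dis <- if (fl == "dementia-based") dem else amci
    st <- if (fl == "dementia-based") "model_dementia" else "model_amci"
    models[[fl]] <- tryCatch(
      severity_model(cn, dis, features = atlas_regions(config$atlas),
                     volumes = volume_regions(config$atlas), flavor = fl,
                     n_ortho = config$n_ortho, cv_k = config$cv_k,
                     prune_passes = config$prune_passes,
                     bandwidth = config$bandwidth,
                     seed = stage_seed(seed, st)),
      error = function(e) stop("stage build-model (", fl, "): ",
                               conditionMessage(e)))
    classifications[[fl]] <- predict(models[[fl]], scd)
  }

  if (is.null(followup)) {
    if (is.null(subjects)) stop("stage events: follow-up requires subjects")
    scd_subj <- subjects[subjects$group == "SCD", , drop = FALSE]
    followup <- generate_followup(scd_subj, config$cohort,
                                  seed = stage_seed(seed, "followup"))
  }
  events <- tryCatch(derive_events(followup, config$gds_threshold),
                     error = function(e) stop("stage events: ",
                                              conditionMessage(e)))
  events <- events[match(scd$subject_id, events$subject_id), ]
  if (anyNA(events$subject_id)) {
    stop("stage events: follow-up missing for some SCD subjects")
  }

  evaluation <- list()
  for (fl in names(models)) {
    cls <- classifications[[fl]]
    stopifnot(identical(cls$subject_id, events$subject_id))
    covars <- data.frame(
      disease_like = as.numeric(cls$label == "disease-like"),
      amyloid_positive = as.numeric(scd$amyloid_positive),
      sex_male = as.numeric(scd$sex == "M"))
    evaluation[[fl]] <- list(
      confusion = confusion_metrics(cls, events),
      roc = roc_curve(cls$severity, events$event),
      km = km_curve(events, cls$label),
      logrank = log_rank(events, cls$label),
      cox = cox_fit(events, covars))
  }

  comparison <- if (length(models) == 2) {
    delong_test(classifications[[1]]$severity,
                classifications[[2]]$severity, events$event)
  } else {
    "DeLong comparison skipped: a single flavor was built"
  }

  counts <- list(
    ingested = nrow(measures),
    matched = vapply(models, function(m) length(m$matched_cn_ids),
                     integer(1)),
    pruned = vapply(models, function(m) length(m$removed_ids), integer(1)),
    classified = vapply(classifications, nrow, integer(1)),
    evented = sum(events$event))
  manifest <- structure(list(config = config, counts = counts,
                             models = models,
                             classifications = classifications,
                             events = events, evaluation = evaluation,
                             comparison = comparison),
                        class = "run_manifest")
  if (!is.null(config$out_dir)) .write_manifest(manifest, config$out_dir)
  manifest
}

.write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(manifest$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  summ <- list(counts = manifest$counts)
  for (fl in names(manifest$evaluation)) {
    ev <- manifest$evaluation[[fl]]
    tag <- gsub("-based$", "", fl)
    utils::write.csv(manifest$classifications[[fl]],
                     file.path(dir, paste0("classification_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(ev$roc$curve,
                     file.path(dir, paste0("roc_", tag, ".csv")),
                     row.names = FALSE)
    write_severity_model(manifest$models[[fl]],
                         file.path(dir, paste0("model_", tag)))
    summ[[fl]] <- list(sensitivity = ev$confusion$sensitivity,
                       specificity = ev$confusion$specificity,
                       auc = ev$roc$auc, logrank_p = ev$logrank$p,
                       cox = ev$cox$table)
  }
  if (inherits(manifest$comparison, "delong_result")) {
    summ$delong <- unclass(manifest$comparison)
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Severity-index pipeline run (seed", x$config$seed, ")\n")
  cat("  subjects ingested:", x$counts$ingested,
      "| SCD progressors:", x$counts$evented, "\n")
  for (fl in names(x$evaluation)) {
    ev <- x$evaluation[[fl]]
    cat(sprintf("  %s: sens %.1f%% spec %.1f%% AUC %.3f (log-rank p = %.3g)\n",
                fl, 100 * ev$confusion$sensitivity,
                100 * ev$confusion$specificity, ev$roc$auc, ev$logrank$p))
  }
  if (inherits(x$comparison, "delong_result")) {
    cat(sprintf("  DeLong AUC comparison p = %.3g\n", x$comparison$p))
  } else cat(" ", x$comparison, "\n")
  invisible(x)
}
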