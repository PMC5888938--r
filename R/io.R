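# Table readers/writers and the pipeline configuration.

# Data dictionary: columns of the per-subject phenotype table. Types are
# checked loosely; unknown columns are preserved untouched.
COHORT_COLUMNS <- c("subject_id", "cohort", "group", "age", "gender",
                    "education", "site_id")

#' Read a per-subject phenotype table from TSV
#'
#' Checks the required data-dictionary columns, validates the MMSE bounds
#' and the consistency of amyloid status with the CSF A-beta 42/40 ratio
#' cutoff (< 0.1), and refuses tables mixing the two cohorts. Unknown
#' columns are preserved.
#'
#' @param path Path to a tab-separated phenotype table.
#' @param required Required column names (default the core dictionary).
#' @return Data frame, one row per subject.
#' @export
read_cohort_table <- function(path, required = COHORT_COLUMNS) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("phenotype table is missing required column(s): ",
         paste(miss, collapse = ", "))
  .assert_single_cohort(tab)
  # all-NA numeric dictionary columns (e.g. eyo in DELCODE) come back as
  # logical from read.delim; restore their numeric type
  num_cols <- c("eyo", "age", "education", "csf_tau", "csf_ptau181",
                "csf_abeta_ratio", "pib_suvr", "hippocampal_volume", "mmse",
                "lm_delayed", "adas_recall", "conn_lfc", "conn_rfc",
                "conn_occ", "conn_m1")
  for (col in intersect(num_cols, names(tab)))
    if (is.logical(tab[[col]])) tab[[col]] <- as.numeric(tab[[col]])
  if ("mmse" %in% names(tab)) {
    bad <- stats::na.omit(tab$mmse)
    if (any(bad < 0 | bad > 30)) stop("mmse values outside [0, 30]")
  }
  if (all(c("abeta_status", "csf_abeta_ratio") %in% names(tab))) {
    ok <- is.na(tab$csf_abeta_ratio) |
      (tab$abeta_status == "pos") == (tab$csf_abeta_ratio < 0.1)
    if (!all(ok))
      stop("abeta_status inconsistent with the 0.1 CSF ratio cutoff in row(s): ",
           paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  tab
}

#' Write a phenotype table as TSV (atomic)
#' @param table Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) .write_tsv_atomic(table, path)

#' Flatten model fits into a long results table
#'
#' @param fits List of [fit_reserve_interaction()] / [fit_education_model()]
#'   results.
#' @return Data frame with one row per fixed-effect term: cohort, stratum,
#'   outcome, severity, seed, term, beta, se, t, p, aic, delta_aic, r2, n.
#' @export
model_results_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "reserve_fit"))
    tt <- f$terms
    data.frame(cohort = f$cohort, stratum = f$stratum, outcome = f$outcome,
               severity = f$severity, seed = f$seed, term = rownames(tt),
               beta = tt$beta, se = tt$se, t = tt$t, p = tt$p,
               aic = f$aic,
               delta_aic = if (is.null(f$aic_comparison)) NA_real_
                           else f$aic_comparison$delta,
               r2 = f$r2, n = f$n, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write model results as TSV (atomic)
#' @param fits List of model fits (see [model_results_table()]) or an
#'   already-flattened data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(fits, path) {
  tab <- if (is.data.frame(fits)) fits else model_results_table(fits)
  .write_tsv_atomic(tab, path)
}

#' Write difference curves as TSV (atomic)
#' @param curves A `difference_curve` data frame or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (!is.data.frame(curves)) curves <- do.call(rbind, curves)
  .write_tsv_atomic(as.data.frame(curves), path)
}

#' Default pipeline configuration
#'
#' All analysis constants of the pipeline with their fixed defaults:
#' scrubbing at framewise displacement > 0.5 mm (1 volume back, 2 forward,
#' exclusion above 30% censored), 0.01-0.08 Hz band-pass, 8 mm smoothing,
#' grey-matter probability cutoff 0.3, the four 8 mm seed spheres,
#' Bonferroni-corrected primary alpha 0.0125, and the -20..+10 EYO plot
#' range.
#'
#' @return Named list of class `"pipeline_config"`.
#' @export
default_config <- function() {
  structure(list(
    cohort = "DIAN",
    table_path = NULL,
    images_dir = NULL,
    out_dir = "hubreserve-output",
    simulate = FALSE,
    fd_threshold = 0.5,
    fd_n_pre = 1,
    fd_n_post = 2,
    exclusion_fraction = 0.30,
    band = c(0.01, 0.08),
    fwhm = 8,
    gm_threshold = 0.3,
    seeds = c("LFC", "RFC", "OCC", "M1"),
    alpha_primary = 0.0125,
    alpha_nominal = 0.05,
    eyo_plot_range = c(-20, 10),
    rng_seed = 1
  ), class = "pipeline_config")
}

#' Read a pipeline configuration (YAML)
#'
#' Values in the file override [default_config()]; every override is
#' reported via `message()` so the log records all departures from the
#' fixed defaults.
#'
#' @param path Path to a YAML file (may set any `default_config()` key).
#' @return A `"pipeline_config"` list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (!identical(unname(cfg[[k]]), unname(user[[k]]))) {
      message("config override: ", k, " = ",
              paste(format(user[[k]]), collapse = ", "))
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}
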