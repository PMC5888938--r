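# Umbrella pipeline binding the stages: connectivity scoring, descriptive
# statistics, reserve moderation models, education models, scanner checks,
# and trajectory difference curves.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, for one cohort: (1) optional per-subject connectivity scoring
#' from NIfTI runs; (2) descriptive group comparisons; (3) the reserve
#' moderation models for every outcome x severity x seed x stratum
#' combination, Bonferroni-gated; (4) education models; (5) scanner-model
#' ANCOVA confound checks; (6) polynomial trajectory models and
#' standardized group difference curves for global cognition, including
#' high/low connectivity median-split curves. All outputs are written to
#' `config$out_dir` as TSV plus a JSON manifest recording the full
#' configuration (and its hash), so every threshold and seed used can be
#' reconstructed from the log.
#'
#' When `config$images_dir` is set it must contain, per subject,
#' `<subject_id>_bold.nii.gz` and `<subject_id>_motion.tsv`, plus shared
#' `gm_mask.nii.gz`, `wm_mask.nii.gz`, `csf_mask.nii.gz`; computed scores
#' replace the table's `conn_*` columns for those subjects.
#'
#' @param config A [default_config()] list (or [read_config()] result),
#'   with either `table_path` set or `simulate = TRUE`.
#' @param table Optional in-memory phenotype table (overrides `table_path`).
#' @return Invisibly, a report list: `table`, `descriptives`, `fits`,
#'   `models` (flattened, alpha-gated), `education`, `scanner`, `curves`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), table = NULL) {
  set.seed(config$rng_seed)
  cohort <- match.arg(config$cohort, c("DIAN", "DELCODE"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  tab <- .stage("load", {
    if (!is.null(table)) table
    else if (isTRUE(config$simulate))
      simulate_cohort(cohort, rng_seed = config$rng_seed)
    else if (!is.null(config$table_path)) read_cohort_table(config$table_path)
    else stop("config must provide table_path or simulate = TRUE")
  })
  .assert_single_cohort(tab, cohort)
  log("loaded %d subjects (%s)", nrow(tab), cohort)

  scores <- NULL
  if (!is.null(config$images_dir)) {
    scores <- .stage("connectivity", {
      .score_subjects(tab, config, log)
    })
    for (s in unique(scores$seed)) {
      col <- paste0("conn_", tolower(s))
      m <- scores[scores$seed == s, ]
      tab[[col]][match(m$subject_id, tab$subject_id)] <- m$score
    }
    write_scores(scores, file.path(config$out_dir, "scores.tsv"))
    log("connectivity scores written for %d subjects",
        length(unique(scores$subject_id)))
  }

  desc <- .stage("descriptives", {
    vars <- intersect(c("age", "education", "mmse", "lm_delayed", "csf_tau",
                        "csf_ptau181", "conn_lfc"), names(tab))
    num <- do.call(rbind, lapply(vars, function(v) {
      gc <- group_comparison(tab, v, "group")
      data.frame(variable = v, test = gc$test, statistic = gc$statistic,
                 p = gc$p, stringsAsFactors = FALSE)
    }))
    gcg <- group_comparison(tab, "gender", "group")
    rbind(num, data.frame(variable = "gender", test = gcg$test,
                          statistic = gcg$statistic, p = gcg$p))
  })

  strata <- if (cohort == "DIAN") c("MC", "NC") else c("Abeta+", "Abeta-")
  severities <- if (cohort == "DIAN") c("eyo", "csf_tau") else "csf_tau"
  outcomes <- c("mmse", "lm_delayed")
  if (cohort == "DELCODE" && any(is.finite(tab$adas_recall)))
    outcomes <- c(outcomes, "adas_recall")
  primary_severity <- if (cohort == "DIAN") "eyo" else "csf_tau"
  primary_stratum <- strata[1]

  fits <- .stage("reserve models", {
    out <- list()
    for (st in strata) for (sv in severities) for (oc in outcomes)
      for (sd in config$seeds) {
        key <- paste(oc, sv, sd, st, sep = ".")
        out[[key]] <- suppressWarnings(fit_reserve_interaction(
          tab, outcome = oc, severity = sv, connectivity_seed = sd,
          stratum = st, cohort = cohort))
      }
    out
  })
  log("%d reserve moderation models fitted", length(fits))

  models <- model_results_table(fits)
  inter <- models[grepl(" x conn_", models$term), ]
  inter$primary <- inter$seed == "LFC" &
    inter$severity == primary_severity &
    inter$stratum == primary_stratum &
    inter$outcome %in% c("mmse", "lm_delayed")
  inter <- apply_alpha_gate(inter, config$alpha_primary, config$alpha_nominal)

  edu <- .stage("education models", {
    lapply(stats::setNames(nm = strata), function(st)
      suppressWarnings(fit_education_model(tab, st, cohort)))
  })

  scanner <- .stage("scanner checks", {
    if (length(unique(tab$scanner_model)) >= 2L)
      lapply(stats::setNames(nm = paste0("conn_", tolower(config$seeds))),
             function(col) suppressWarnings(
               fit_group_ancova(tab, col, "scanner_model")))
    else list()
  })

  curves <- .stage("trajectories", {
    axis <- if (cohort == "DIAN") "eyo" else "csf_tau"
    g1 <- strata[1]; g2 <- strata[2]
    pooled_sd <- stats::sd(tab$mmse, na.rm = TRUE)
    f1 <- suppressWarnings(select_polynomial_model(
      tab, "mmse", axis, g1, cohort, with_connectivity_interaction = TRUE))
    f2 <- suppressWarnings(select_polynomial_model(tab, "mmse", axis, g2, cohort))
    out <- list(predict_difference_curve(f1, f2, pooled_sd))

    # high/low connectivity median-split curves for the affected stratum
    dat1 <- .subset_stratum(tab, g1, cohort)
    split <- median_split(dat1$conn_lfc)
    for (lv in c("high", "low")) {
      sub <- rbind(dat1[split == lv, ], .subset_stratum(tab, g2, cohort))
      fit_split <- tryCatch(
        suppressWarnings(select_polynomial_model(
          sub, "mmse", axis, g1, cohort, with_connectivity_interaction = TRUE)),
        error = function(e) {
          log("median-split stratum '%s' skipped: %s", lv, conditionMessage(e))
          NULL
        })
      if (!is.null(fit_split))
        out[[lv]] <- predict_difference_curve(fit_split, f2, pooled_sd,
                                              connectivity_stratum = lv)
    }
    out
  })
  log("%d difference curves computed", length(curves))

  .stage("write outputs", {
    write_models(models, file.path(config$out_dir, "models.tsv"))
    .write_tsv_atomic(inter, file.path(config$out_dir, "interactions.tsv"))
    .write_tsv_atomic(desc, file.path(config$out_dir, "descriptives.tsv"))
    write_curves(curves, file.path(config$out_dir, "curves.tsv"))
    cfg_file <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_file)
    manifest <- list(
      package = as.character(utils::packageVersion("hubreserve")),
      config = unclass(config),
      config_md5 = unname(tools::md5sum(cfg_file)),
      n_subjects = nrow(tab),
      outputs = c("models.tsv", "interactions.tsv", "descriptives.tsv",
                  "curves.tsv", if (!is.null(scores)) "scores.tsv"),
      log = log_lines)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(table = tab, descriptives = desc, fits = fits,
                 models = models, interactions = inter, education = edu,
                 scanner = scanner, curves = curves,
                 out_dir = config$out_dir))
}

# Score every subject with images present in config$images_dir.
.score_subjects <- function(tab, config, log) {
  dir <- config$images_dir
  gm <- read_nifti(file.path(dir, "gm_mask.nii.gz"))$data > 0.5
  wm <- read_nifti(file.path(dir, "wm_mask.nii.gz"))$data > 0.5
  csf <- read_nifti(file.path(dir, "csf_mask.nii.gz"))$data > 0.5
  out <- list()
  for (sid in tab$subject_id) {
    bold_path <- file.path(dir, paste0(sid, "_bold.nii.gz"))
    if (!file.exists(bold_path)) next
    res <- tryCatch({
      img <- read_nifti(bold_path)
      run <- bold_run(img$data, img$tr, img$affine, run_id = sid)
      motion <- read_motion(file.path(dir, paste0(sid, "_motion.tsv")))
      compute_global_connectivity(
        run, motion, gm, wm, csf, seeds = config$seeds, subject_id = sid,
        fwhm_mm = config$fwhm, band_hz = config$band,
        fd_threshold_mm = config$fd_threshold, n_pre = config$fd_n_pre,
        n_post = config$fd_n_post,
        exclusion_fraction = config$exclusion_fraction)
    }, error = function(e)
      stop("subject '", sid, "': ", conditionMessage(e), call. = FALSE))
    out[[sid]] <- res
  }
  if (!length(out)) stop("no subject images found in ", dir)
  do.call(rbind, out)
}
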