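# Reserve moderation models: disease severity x hub connectivity on
# cognition, fitted as linear mixed models (random intercept per site) on
# standardized variables, with AIC comparison of the full model against the
# reduced model without the interaction term.

# Shared fixed+random fitting engine. `df` must contain column `site_id`
# and the response column named in `response`. Fits by maximum likelihood
# (REML is invalid for AIC comparisons across fixed-effect structures).
# With a single site level the model falls back to a fixed-intercept lm
# with a warning. Aliased family-affiliation dummies are dropped with a
# warning; any other rank deficiency is an error naming the terms.
.fit_mixed <- function(df, response, fixed_terms) {
  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  fixed_formula <- stats::as.formula(paste(response, "~", fixed_rhs))

  mm <- stats::model.matrix(fixed_formula, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    from_family <- grepl("^family_id", aliased)
    if (all(from_family)) {
      warning("dropping aliased family affiliation level(s): ",
              paste(aliased, collapse = ", "))
    } else {
      stop("design is rank deficient; aliased term(s): ",
           paste(aliased, collapse = ", "))
    }
  }

  n_sites <- length(unique(df$site_id))
  if (n_sites >= 2L) {
    form <- stats::as.formula(paste(response, "~", fixed_rhs, "+ (1 | site_id)"))
    model <- suppressMessages(
      lme4::lmer(form, data = df, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))
    cf <- as.data.frame(summary(model)$coefficients)
    # ML residual variance ignores the fixed-effect count; rescale the SEs
    # by sqrt(n / (n - p)) (the REML-style finite-sample correction), which
    # matters when family-affiliation dummies make p large relative to n
    p_fix <- nrow(cf)
    corr <- sqrt(nrow(df) / max(nrow(df) - p_fix, 1L))
    cf[[2L]] <- cf[[2L]] * corr
    cf[[3L]] <- cf[[1L]] / cf[[2L]]
    fitted_vals <- stats::fitted(model)
    random_effect <- "site_id"
  } else {
    warning("only one site level; falling back to a fixed-intercept model")
    model <- stats::lm(fixed_formula, data = df)
    cf <- as.data.frame(summary(model)$coefficients[, 1:3, drop = FALSE])
    fitted_vals <- stats::fitted(model)
    random_effect <- "none"
  }
  names(cf) <- c("beta", "se", "t")
  n <- nrow(df)
  df_resid <- max(n - nrow(cf), 1L)
  cf$p <- 2 * stats::pt(-abs(cf$t), df = df_resid)
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  aic <- stats::AIC(model)
  # small-sample corrected AIC; essential when family-affiliation dummies
  # make the parameter count comparable to n
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  list(model = model, coefficients = cf, aic = aic, aicc = aicc, k = k,
       fitted = fitted_vals, n = n, df_resid = df_resid,
       random_effect = random_effect,
       r2 = stats::cor(fitted_vals, df[[response]])^2)
}

# Cohort-specific covariate columns for the moderation/education models;
# DIAN adjusts for gender + family affiliation (age is collinear with EYO
# and excluded), DELCODE for age + gender.
.covariate_terms <- function(cohort) {
  if (cohort == "DIAN") c("gender", "family_id") else c("z_age", "gender")
}

.prepare_model_frame <- function(dat, cohort, outcome, severity = NULL,
                                 conn_col = NULL) {
  need <- c(outcome, severity, conn_col, "gender", "site_id",
            if (cohort == "DIAN") "family_id" else "age")
  need <- unique(need[!is.na(need)])
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("table is missing column(s): ",
                         paste(miss, collapse = ", "))
  keep <- stats::complete.cases(dat[, need])
  dat <- droplevels(dat[keep, , drop = FALSE])
  df <- data.frame(z_outcome = .zscore(dat[[outcome]]),
                   gender = factor(dat$gender),
                   site_id = factor(dat$site_id))
  if (cohort == "DIAN") df$family_id <- factor(dat$family_id)
  else df$z_age <- .zscore(dat$age)
  if (!is.null(severity)) {
    df$z_severity <- if (severity == "eyo") .zscore(dat$eyo)
                     else as.numeric(log_z_transform(dat$csf_tau))
  }
  if (!is.null(conn_col))
    df$z_conn <- as.numeric(log_z_transform(dat[[conn_col]]))
  attr(df, "raw") <- dat
  df
}

#' Fit a severity x connectivity moderation (reserve) model
#'
#' Linear mixed model of a cognitive outcome on disease severity (EYO in
#' DIAN, CSF tau in DELCODE), global connectivity of a seed region, and
#' their interaction, with cohort-specific covariates (gender + family
#' affiliation in DIAN; age + gender in DELCODE) as fixed effects and study
#' site as a random intercept. All continuous variables are z-scored
#' (connectivity and CSF tau log-transformed first) so the reported betas
#' are standardized; the interaction column is the product of the z-scored
#' main effects and is not re-standardized. Fitted by maximum likelihood,
#' and compared by AIC against the reduced model without the interaction.
#'
#' A positive interaction beta means the (negative) severity slope on
#' cognition is attenuated at higher connectivity -- the reserve signature.
#'
#' @param table Cohort table (single cohort; mixing cohorts is an error).
#' @param outcome `"mmse"`, `"lm_delayed"`, or (DELCODE only)
#'   `"adas_recall"`.
#' @param severity `"eyo"` (DIAN) or `"csf_tau"`.
#' @param connectivity_seed `"LFC"`, `"RFC"`, `"OCC"`, or `"M1"`.
#' @param stratum `"MC"`/`"NC"` (DIAN) or `"Abeta+"`/`"Abeta-"` (DELCODE).
#' @param cohort `"DIAN"` or `"DELCODE"`.
#' @return An object of class `"reserve_fit"` with the standardized
#'   coefficient table (`terms`), `aic`, `r2`, `n`, and an
#'   `aic_comparison` list (`aic_full`, `aic_reduced`, `delta`,
#'   `full_preferred`).
#' @seealso [fit_education_model()], [fit_group_ancova()],
#'   [apply_alpha_gate()]
#' @export
fit_reserve_interaction <- function(table,
                                    outcome = c("mmse", "lm_delayed", "adas_recall"),
                                    severity = c("eyo", "csf_tau"),
                                    connectivity_seed = "LFC",
                                    stratum, cohort = c("DIAN", "DELCODE")) {
  cohort <- match.arg(cohort)
  outcome <- match.arg(outcome)
  severity <- match.arg(severity)
  .assert_single_cohort(table, cohort)
  if (outcome == "adas_recall" && cohort != "DELCODE")
    stop("adas_recall is only available in the DELCODE cohort")
  if (severity == "eyo" && cohort != "DIAN")
    stop("EYO is only defined for the DIAN cohort")
  conn_col <- .conn_column(connectivity_seed)

  dat <- .subset_stratum(table, stratum, cohort)
  df <- .prepare_model_frame(dat, cohort, outcome, severity, conn_col)
  if (nrow(df) < 20L)
    stop("stratum '", stratum, "' has only ", nrow(df),
         " complete rows; at least 20 are required")
  df$z_interaction <- df$z_severity * df$z_conn

  covs <- .covariate_terms(cohort)
  full <- .fit_mixed(df, "z_outcome",
                     c("z_severity", "z_conn", "z_interaction", covs))
  reduced <- .fit_mixed(df, "z_outcome", c("z_severity", "z_conn", covs))

  terms <- full$coefficients
  label <- c("(Intercept)" = "(Intercept)",
             z_severity = severity,
             z_conn = paste0("conn_", tolower(connectivity_seed)),
             z_interaction = paste0(severity, " x conn_",
                                    tolower(connectivity_seed)))
  rn <- rownames(terms)
  rownames(terms) <- ifelse(rn %in% names(label), label[rn], rn)

  structure(list(terms = terms, aic = full$aic, r2 = full$r2, n = full$n,
                 outcome = outcome, severity = severity,
                 seed = toupper(connectivity_seed), stratum = stratum,
                 cohort = cohort, random_effect = full$random_effect,
                 aic_comparison = list(aic_full = full$aic,
                                       aic_reduced = reduced$aic,
                                       delta = full$aic - reduced$aic,
                                       full_preferred = full$aic < reduced$aic),
                 interaction_term = paste0(severity, " x conn_",
                                           tolower(connectivity_seed)),
                 model = full$model, model_reduced = reduced$model),
            class = "reserve_fit")
}

#' @export
print.reserve_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Reserve moderation model (%s, stratum %s)\n", x$cohort, x$stratum))
  cat(sprintf("  outcome: %s ~ %s * conn_%s + covariates, site random intercept\n",
              x$outcome, x$severity, tolower(x$seed)))
  key <- x$terms[rownames(x$terms) != "(Intercept)" &
                   !grepl("^(gender|family_id|z_age)", rownames(x$terms)), ,
                 drop = FALSE]
  print(round(key, digits))
  cat(sprintf("  n = %d, overall R^2 = %.3f\n", x$n, x$r2))
  cat(sprintf("  AIC full %.1f vs reduced %.1f -> %s\n",
              x$aic_comparison$aic_full, x$aic_comparison$aic_reduced,
              if (x$aic_comparison$full_preferred)
                "interaction improves fit" else "interaction not supported"))
  invisible(x)
}

#' @export
summary.reserve_fit <- function(object, ...) {
  print(object)
  cat("\nAll fixed-effect terms:\n")
  print(round(object$terms, 4))
  invisible(object)
}

#' @export
coef.reserve_fit <- function(object, ...) {
  stats::setNames(object$terms$beta, rownames(object$terms))
}

#' Interaction p-value of a reserve fit
#'
#' @param fit A [fit_reserve_interaction()] result.
#' @return The two-sided p of the severity x connectivity term.
#' @export
interaction_p <- function(fit) {
  stopifnot(inherits(fit, "reserve_fit"))
  fit$terms[fit$interaction_term, "p"]
}

#' Education -> connectivity association
#'
#' Standardized effect of years of education on (log-z) global connectivity
#' of a seed, adjusted for gender and site (random intercept) plus EYO and
#' family affiliation in DIAN or age in DELCODE. Both the two-sided and the
#' one-sided p (for the directional hypothesis that education increases
#' connectivity) are reported.
#'
#' @inheritParams fit_reserve_interaction
#' @return An object of class `"reserve_fit"` (same structure, no AIC
#'   comparison) with extra element `p_one_sided`.
#' @export
fit_education_model <- function(table, stratum, cohort = c("DIAN", "DELCODE"),
                                connectivity_seed = "LFC") {
  cohort <- match.arg(cohort)
  .assert_single_cohort(table, cohort)
  conn_col <- .conn_column(connectivity_seed)
  dat <- .subset_stratum(table, stratum, cohort)
  if (!"education" %in% names(dat)) stop("table is missing column(s): education")
  keep <- stats::complete.cases(dat[, c("education", conn_col)])
  dat <- dat[keep, , drop = FALSE]
  df <- .prepare_model_frame(dat, cohort, outcome = conn_col,
                             severity = if (cohort == "DIAN") "eyo" else NULL)
  # outcome is the log-z connectivity, not a plain z-score
  df$z_outcome <- as.numeric(log_z_transform(attr(df, "raw")[[conn_col]]))
  df$z_education <- .zscore(attr(df, "raw")$education)
  if (nrow(df) < 20L) stop("stratum has only ", nrow(df), " complete rows")

  covs <- c("z_education",
            if (cohort == "DIAN") c("z_severity", .covariate_terms("DIAN"))
            else .covariate_terms("DELCODE"))
  fit <- .fit_mixed(df, "z_outcome", covs)
  terms <- fit$coefficients
  rownames(terms)[rownames(terms) == "z_education"] <- "education"
  rownames(terms)[rownames(terms) == "z_severity"] <- "eyo"
  tval <- terms["education", "t"]
  p_one <- stats::pt(tval, df = fit$df_resid, lower.tail = FALSE)

  structure(list(terms = terms, aic = fit$aic, r2 = fit$r2, n = fit$n,
                 outcome = paste0("conn_", tolower(connectivity_seed)),
                 severity = NA_character_, seed = toupper(connectivity_seed),
                 stratum = stratum, cohort = cohort,
                 random_effect = fit$random_effect,
                 aic_comparison = NULL, interaction_term = NA_character_,
                 p_one_sided = p_one, model = fit$model),
            class = "reserve_fit")
}

#' Group-difference / scanner ANCOVA on a connectivity score
#'
#' ANCOVA-style model of a (log-z transformed) connectivity score on a
#' grouping factor with continuous covariates z-scored, gender as a factor,
#' and site as a random intercept where more than one site is present. The
#' group effect is tested by a likelihood-ratio test of the full model
#' against the model without the grouping factor (both fitted by ML). Used
#' both for the carrier-vs-non-carrier comparison and for the
#' scanner-model confound check.
#'
#' @param table Cohort table (single cohort).
#' @param outcome Outcome column, e.g. `"conn_lfc"` (log-z applied when all
#'   values are positive, plain z-score otherwise).
#' @param grouping Grouping column, e.g. `"group"` or `"scanner_model"`.
#' @param covariates Covariate columns (default age, gender, education).
#' @return List of class `"ancova_fit"`: `p_group`, `chisq`, `df`, `n`,
#'   `aic`, group-term betas, and the underlying models.
#' @export
fit_group_ancova <- function(table, outcome, grouping,
                             covariates = c("age", "gender", "education")) {
  .assert_single_cohort(table)
  need <- c(outcome, grouping, covariates, "site_id")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table is missing column(s): ",
                         paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[, need]), need, drop = FALSE]
  g <- droplevels(factor(dat[[grouping]]))
  if (nlevels(g) < 2L) stop("grouping '", grouping, "' has fewer than 2 levels")

  y <- dat[[outcome]]
  df <- data.frame(z_outcome = if (all(y > 0)) as.numeric(log_z_transform(y))
                               else .zscore(y),
                   grp = g, site_id = factor(dat$site_id))
  cov_terms <- character(0)
  for (cv in covariates) {
    v <- dat[[cv]]
    if (is.numeric(v)) {
      nm <- paste0("z_", cv)
      df[[nm]] <- .zscore(v)
    } else {
      nm <- cv
      df[[nm]] <- droplevels(factor(v))
      if (nlevels(df[[nm]]) < 2L) next
    }
    cov_terms <- c(cov_terms, nm)
  }

  full <- .fit_mixed(df, "z_outcome", c("grp", cov_terms))
  reduced <- .fit_mixed(df, "z_outcome",
                        if (length(cov_terms)) cov_terms else "1")
  ll_full <- as.numeric(stats::logLik(full$model))
  ll_red <- as.numeric(stats::logLik(reduced$model))
  df_lrt <- nlevels(g) - 1L
  chisq <- max(0, 2 * (ll_full - ll_red))
  p <- stats::pchisq(chisq, df = df_lrt, lower.tail = FALSE)

  grp_terms <- full$coefficients[grepl("^grp", rownames(full$coefficients)), ,
                                 drop = FALSE]
  structure(list(p_group = p, chisq = chisq, df = df_lrt, n = full$n,
                 aic = full$aic, group_terms = grp_terms,
                 outcome = outcome, grouping = grouping,
                 random_effect = full$random_effect,
                 model = full$model, model_reduced = reduced$model),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ANCOVA of %s by %s (n = %d): LRT chisq(%d) = %.3f, p = %.4g\n",
              x$outcome, x$grouping, x$n, x$df, x$chisq, x$p_group))
  invisible(x)
}
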