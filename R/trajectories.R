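# Polynomial mixed-effects trajectory models over the disease-time axis
# (EYO in DIAN, log-z CSF tau in DELCODE), AIC-based order selection, and
# standardized between-group difference curves.

#' Fit a polynomial trajectory model with AIC order selection
#'
#' Fits nested polynomial mixed-effects models of order 1, 2 and 3 in the
#' (centred) disease-time axis by maximum likelihood, with cohort-specific
#' covariates (gender + family affiliation in DIAN; age + gender in
#' DELCODE) as fixed effects and site as a random intercept, and returns
#' the AIC-minimizing candidate. Lower-order axis terms are always kept
#' with higher orders. When `with_connectivity_interaction = TRUE` (used
#' for cognition outcomes) a first-order axis x connectivity term is added
#' to every candidate. The axis is centred before powering to reduce
#' collinearity; predictions are invariant to that reparameterization.
#'
#' @param table Cohort table (single cohort).
#' @param outcome Outcome column (modelled on its raw scale, e.g. `mmse`,
#'   `csf_tau`, `pib_suvr`, `hippocampal_volume`; positive right-skewed
#'   biomarkers may be log-z transformed upstream by the caller if wanted).
#' @param axis `"eyo"` (years) or `"csf_tau"` (log-z units).
#' @param stratum `"MC"`/`"NC"` (DIAN) or `"Abeta+"`/`"Abeta-"` (DELCODE).
#' @param cohort `"DIAN"` or `"DELCODE"`.
#' @param with_connectivity_interaction Add axis x connectivity (first
#'   order only) to every candidate.
#' @param connectivity_seed Seed whose (log-z) score enters the
#'   interaction.
#' @param orders Candidate polynomial orders (default `1:3`).
#' @param criterion `"aicc"` (default) or `"aic"`. The covariate set
#'   includes family-affiliation dummies whose count is comparable to the
#'   sample size; plain maximum-likelihood AIC then over-selects high
#'   orders badly (spurious curvature is picked for flat data more often
#'   than not), so the small-sample corrected AICc is the default. Plain
#'   AIC (penalty exactly 2 per added term) is available for designs
#'   without that saturation.
#' @return An object of class `"trajectory_fit"`: the chosen model,
#'   `chosen_order`, `aic_per_order`, and what [predict.trajectory_fit()]
#'   needs for population-level prediction.
#' @export
select_polynomial_model <- function(table, outcome, axis = c("eyo", "csf_tau"),
                                    stratum, cohort = c("DIAN", "DELCODE"),
                                    with_connectivity_interaction = FALSE,
                                    connectivity_seed = "LFC", orders = 1:3,
                                    criterion = c("aicc", "aic")) {
  cohort <- match.arg(cohort)
  axis <- match.arg(axis)
  criterion <- match.arg(criterion)
  .assert_single_cohort(table, cohort)
  if (axis == "eyo" && cohort != "DIAN")
    stop("EYO is only defined for the DIAN cohort")
  dat <- .subset_stratum(table, stratum, cohort)
  conn_col <- if (with_connectivity_interaction) .conn_column(connectivity_seed)
              else NULL

  need <- c(outcome, if (axis == "eyo") "eyo" else "csf_tau", conn_col,
            "gender", "site_id", if (cohort == "DIAN") "family_id" else "age")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("table is missing column(s): ",
                         paste(miss, collapse = ", "))
  dat <- droplevels(dat[stats::complete.cases(dat[, need]), , drop = FALSE])
  if (nrow(dat) < 30L)
    stop("stratum '", stratum, "' has only ", nrow(dat),
         " complete rows; at least 30 are required")

  ax_raw <- if (axis == "eyo") dat$eyo else as.numeric(log_z_transform(dat$csf_tau))
  center <- mean(ax_raw)
  # centre and scale before powering: keeps the cubic term numerically
  # tame; predictions are invariant to this reparameterization
  ax_scale <- stats::sd(ax_raw)
  if (!is.finite(ax_scale) || ax_scale == 0) stop("axis has zero variance")
  x <- (ax_raw - center) / ax_scale

  df <- data.frame(y = dat[[outcome]],
                   gender = factor(dat$gender),
                   site_id = factor(dat$site_id))
  if (cohort == "DIAN") df$family_id <- factor(dat$family_id)
  else df$z_age <- .zscore(dat$age)
  for (k in seq_len(max(orders))) df[[paste0("x", k)]] <- x^k
  if (!is.null(conn_col)) {
    df$z_conn <- as.numeric(log_z_transform(dat[[conn_col]]))
    df$x_conn <- df$x1 * df$z_conn
  }
  covs <- .covariate_terms(cohort)

  fits <- list()
  aics <- stats::setNames(rep(NA_real_, length(orders)), paste0("order", orders))
  crits <- aics
  for (k in orders) {
    terms_k <- c(paste0("x", seq_len(k)), covs,
                 if (!is.null(conn_col)) "x_conn")
    fit_k <- tryCatch(
      withCallingHandlers(
        .fit_mixed(df, "y", terms_k),
        warning = function(w) {
          if (grepl("family affiliation|one site", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) {
        warning("polynomial order ", k, " failed to fit (",
                conditionMessage(e), "); skipped")
        NULL
      })
    if (!is.null(fit_k)) {
      fits[[paste0("order", k)]] <- fit_k
      aics[paste0("order", k)] <- fit_k$aic
      crits[paste0("order", k)] <- if (criterion == "aicc") fit_k$aicc
                                   else fit_k$aic
    }
  }
  if (all(is.na(crits))) stop("no polynomial order could be fitted")
  chosen <- orders[which.min(crits)]
  best <- fits[[paste0("order", chosen)]]

  mm <- stats::model.matrix(
    stats::as.formula(paste("y ~", paste(c(paste0("x", seq_len(chosen)), covs,
                                           if (!is.null(conn_col)) "x_conn"),
                                         collapse = " + "))), df)
  structure(list(model = best$model, chosen_order = chosen,
                 aic_per_order = aics, criterion = criterion,
                 coefficients = best$coefficients,
                 outcome = outcome, axis = axis, stratum = stratum,
                 cohort = cohort, axis_center = center, axis_scale = ax_scale,
                 axis_values = ax_raw, n = best$n,
                 xbar = colMeans(mm),
                 with_connectivity_interaction = !is.null(conn_col),
                 random_effect = best$random_effect),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("Polynomial trajectory model: %s ~ poly(%s, %d) [%s, %s]\n",
              x$outcome, x$axis, x$chosen_order, x$cohort, x$stratum))
  cat("  AIC per order: ",
      paste(sprintf("%s=%.1f", names(x$aic_per_order), x$aic_per_order),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  n = %d, axis centred at %.2f\n", x$n, x$axis_center))
  invisible(x)
}

#' @export
coef.trajectory_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, rownames(object$coefficients))
}

#' Population-level trajectory prediction
#'
#' Predicts the outcome at given axis values with covariates held at their
#' pooled reference values: factor dummies at the sample proportions
#' (equivalent to averaging level-wise predictions), continuous covariates
#' at their means, random site effects at 0, and connectivity (when an
#' interaction is present) at its sample mean, i.e. z = 0.
#'
#' @param object A [select_polynomial_model()] fit.
#' @param axis_values Axis positions in the model's axis units (EYO years
#'   or log-z CSF-tau units).
#' @param ... Unused.
#' @return Numeric vector of predicted outcome values.
#' @export
predict.trajectory_fit <- function(object, axis_values, ...) {
  beta <- object$coefficients$beta
  names(beta) <- rownames(object$coefficients)
  xbar <- object$xbar[names(beta)]           # align to estimated terms
  xbar[is.na(xbar)] <- 0
  vapply(axis_values, function(v) {
    row <- xbar
    xc <- (v - object$axis_center) / object$axis_scale
    for (k in seq_len(object$chosen_order)) {
      nm <- paste0("x", k)
      if (nm %in% names(row)) row[nm] <- xc^k
    }
    if (object$with_connectivity_interaction && "x_conn" %in% names(row))
      row["x_conn"] <- 0                     # connectivity at its mean (z = 0)
    sum(row * beta)
  }, numeric(1))
}

#' Standardized between-group difference curve
#'
#' Evaluates two trajectory models (e.g. mutation carriers vs
#' non-carriers) on a common axis grid and returns their predicted
#' difference divided by the pooled-sample SD of the outcome. For the EYO
#' axis the grid is clipped to \[-20, +10\] years; for the CSF-tau axis the
#' default grid spans the central 95% of the observed (log-z) values.
#'
#' @param model_g1,model_g2 [select_polynomial_model()] fits sharing
#'   outcome and axis (group 1 minus group 2).
#' @param pooled_sd SD of the outcome in the pooled sample (> 0).
#' @param grid Axis grid; default `seq(-20, 10, by = step)` for EYO.
#' @param step Grid step (default 0.5 axis units).
#' @param connectivity_stratum Label (`"high"`, `"low"`, `"none"`) carried
#'   into the result for median-split stratified curves.
#' @return Data frame of class `"difference_curve"` with columns
#'   `axis_value`, `standardized_difference`, `stratum`, `outcome`.
#' @export
predict_difference_curve <- function(model_g1, model_g2, pooled_sd,
                                     grid = NULL, step = 0.5,
                                     connectivity_stratum = "none") {
  stopifnot(inherits(model_g1, "trajectory_fit"),
            inherits(model_g2, "trajectory_fit"))
  if (!identical(model_g1$outcome, model_g2$outcome))
    stop("the two models have different outcomes (",
         model_g1$outcome, " vs ", model_g2$outcome, ")")
  if (!identical(model_g1$axis, model_g2$axis))
    stop("the two models have different axes")
  if (!is.finite(pooled_sd) || pooled_sd <= 0) stop("pooled_sd must be > 0")

  if (is.null(grid)) {
    if (model_g1$axis == "eyo") {
      grid <- seq(-20, 10, by = step)
    } else {
      q <- stats::quantile(c(model_g1$axis_values, model_g2$axis_values),
                           c(0.025, 0.975))
      grid <- seq(q[1], q[2], by = step)
    }
  } else if (model_g1$axis == "eyo") {
    grid <- grid[grid >= -20 & grid <= 10]
  }

  diff <- (predict(model_g1, grid) - predict(model_g2, grid)) / pooled_sd
  if (any(!is.finite(diff))) stop("difference curve is not finite")
  structure(data.frame(axis_value = grid, standardized_difference = diff,
                       stratum = connectivity_stratum,
                       outcome = model_g1$outcome, stringsAsFactors = FALSE),
            class = c("difference_curve", "data.frame"))
}

#' @export
plot.difference_curve <- function(x, ...,
                                  xlab = "disease-time axis",
                                  ylab = "standardized group difference (SD units)") {
  plot(x$axis_value, x$standardized_difference, type = "l", lwd = 2,
       xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Median split into high/low groups
#'
#' Values strictly above the median are labelled `"high"`; values at or
#' below the median (including ties with the median) are labelled `"low"`.
#' Used only for stratified plotting and difference curves, never for
#' inference, which always uses the continuous measure.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Character vector of `"high"`/`"low"` labels.
#' @examples
#' median_split(c(1, 2, 2, 3))  # ties go low
#' @export
median_split <- function(values) {
  if (length(values) < 2L || length(unique(values)) < 2L)
    stop("median split needs at least 2 distinct values")
  ifelse(values > stats::median(values), "high", "low")
}
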