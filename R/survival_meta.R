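# Per-cohort dichotomized Cox proportional-hazards fits and their
# inverse-variance meta-analysis with heterogeneity-driven model selection.
#
# The Cox partial likelihood is maximized by survival::coxph (Newton
# iteration, Efron correction for tied event times); everything downstream
# of the per-cohort fits (Cochran's Q, DerSimonian-Laird tau^2, fixed vs
# random selection, combined effect) is implemented here.

#' Choose the survival endpoint for a cohort
#'
#' Relapse-free survival is the primary endpoint; when unavailable,
#' distant-metastasis-free survival is used, then disease-specific
#' survival.
#'
#' @param available nonempty character vector drawn from
#'   `c("RFS", "DMFS", "DSS")`.
#' @return the selected endpoint.
#' @export
select_endpoint <- function(available) {
  available <- unique(as.character(available))
  if (!length(available)) stop("no endpoint available")
  bad <- setdiff(available, VALID_ENDPOINTS)
  if (length(bad)) stop("unknown endpoint(s): ", paste(bad, collapse = ", "))
  for (e in VALID_ENDPOINTS) if (e %in% available) return(e)
}

#' Administratively censor follow-up at a horizon (5-year analysis)
#'
#' Patients with follow-up beyond the horizon are censored there
#' (`time = horizon`, `event = 0`). An event at exactly the horizon is
#' retained as an event, so each event is counted in exactly one of the
#' 5-year and late-relapse analyses.
#'
#' @param cohort a [cohort_survival()].
#' @param horizon months (default 60 = 5 years).
#' @return the truncated `cohort_survival`.
#' @export
truncate_5y <- function(cohort, horizon = 60) {
  stopifnot(inherits(cohort, "cohort_survival"), horizon > 0)
  late <- cohort$time_months > horizon
  cohort$event[late] <- 0L
  cohort$time_months[late] <- horizon
  cohort
}

#' Landmark a cohort at 5 years for late-relapse analysis
#'
#' Keeps only patients still event-free and in follow-up strictly beyond
#' the landmark (an event or censoring at exactly the landmark is
#' excluded), and shifts the time origin: `time' = time - landmark`.
#'
#' @param cohort a [cohort_survival()].
#' @param landmark months (default 60).
#' @return the landmarked `cohort_survival`.
#' @export
landmark_late <- function(cohort, landmark = 60) {
  stopifnot(inherits(cohort, "cohort_survival"), landmark > 0)
  keep <- cohort$time_months > landmark
  out <- cohort[keep, , drop = FALSE]
  out$time_months <- out$time_months - landmark
  if (nrow(out) < 2 || sum(out$event) == 0)
    stop("cohort '", cohort$cohort_id[1],
         "' non-analyzable after landmarking (", nrow(out),
         " patients, ", sum(out$event), " events)")
  class(out) <- c("cohort_survival", "data.frame")
  out
}

#' Cox proportional-hazards fit of a dichotomized signature score
#'
#' Fits `Surv(time, event) ~ label (+ adjustment)` by maximizing the Efron
#' tie-corrected partial likelihood (Newton iteration via
#' [survival::coxph()]). Returns the log hazard ratio of `high` vs `low`
#' with its standard error from the inverse observed information.
#'
#' @param cohort a [cohort_survival()].
#' @param labels factor/character of `"low"`/`"high"` aligned with the
#'   cohort rows, or a `score_table` with a `label` column (matched by
#'   `patient_id`/`sample_id`).
#' @param adjustment optional per-patient numeric covariate (e.g. the
#'   proliferation signature score), aligned like `labels`.
#' @return list of class `cox_fit`: `cohort_id`, `log_hr`, `se`, `hr`, `n`,
#'   `n_events`, `covariates`, `adj_coef` (NA if unadjusted).
#' @export
cox_binary <- function(cohort, labels, adjustment = NULL) {
  stopifnot(inherits(cohort, "cohort_survival"))
  if (inherits(labels, "score_table")) {
    if (is.null(labels$label)) stop("score table has no label column")
    m <- match(cohort$patient_id, labels$sample_id)
    if (anyNA(m)) stop("unlabeled patient(s): ",
                       paste(cohort$patient_id[is.na(m)], collapse = ", "))
    labels <- labels$label[m]
  }
  lab <- factor(as.character(labels), levels = c("low", "high"))
  if (anyNA(lab) || length(lab) != nrow(cohort))
    stop("labels must be low/high, one per patient")
  if (length(unique(lab)) < 2) stop("both label groups must be represented")
  if (sum(cohort$event) < 1) stop("cohort '", cohort$cohort_id[1],
                                  "': no events")
  df <- data.frame(time = cohort$time_months, event = cohort$event,
                   high = as.integer(lab == "high"))
  fml <- survival::Surv(time, event) ~ high
  covariates <- character(0)
  if (!is.null(adjustment)) {
    if (length(adjustment) != nrow(cohort) || any(!is.finite(adjustment)))
      stop("adjustment covariate must be finite, one per patient")
    df$adj <- as.numeric(adjustment)
    fml <- survival::Surv(time, event) ~ high + adj
    covariates <- "proliferation_score"
  }
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        stop("cohort '", cohort$cohort_id[1],
             "': Cox fit did not converge (monotone likelihood?): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients["high"])
  se <- sqrt(diag(fit$var))[match("high", names(fit$coefficients))]
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    stop("cohort '", cohort$cohort_id[1],
         "': Cox fit did not converge (monotone likelihood?)")
  structure(list(cohort_id = cohort$cohort_id[1],
                 log_hr = beta, se = unname(se), hr = exp(beta),
                 n = nrow(cohort), n_events = sum(cohort$event),
                 covariates = covariates,
                 adj_coef = if (is.null(adjustment)) NA_real_ else
                   unname(fit$coefficients["adj"])),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s: HR=%.3f (log %.3f +/- %.3f), n=%d, events=%d\n",
              x$cohort_id, x$hr, x$log_hr, x$se, x$n, x$n_events))
  invisible(x)
}

#' Inverse-variance meta-analysis with heterogeneity-based model selection
#'
#' Fixed-effect weights are `w_i = 1/se_i^2`; the fixed combined effect is
#' `sum(w_i theta_i) / sum(w_i)`. Between-cohort heterogeneity is tested
#' with Cochran's Q (`Q = sum w_i (theta_i - theta_F)^2`, chi-squared with
#' k-1 df). If the Q test is significant at `het_alpha`, the
#' DerSimonian-Laird random-effects model is used:
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, weights
#' `1/(se_i^2 + tau^2)`. Otherwise the fixed-effect model is kept and
#' `tau^2 = 0`. The combined standard error is `1/sqrt(sum weights)`; the
#' p-value and the 95% CI are Wald (normal z, 1.96).
#'
#' @param fits list of [cox_binary()] fits (at least 2).
#' @param het_alpha significance level of the heterogeneity test
#'   (default 0.05).
#' @return list of class `meta_result`: `fits`, `k`, `Q`, `q_pvalue`,
#'   `tau2`, `model` (`"fixed"`/`"random"`), `combined_log_hr`,
#'   `combined_se`, `combined_hr`, `ci95` (HR scale), `p`.
#' @export
meta_analyze <- function(fits, het_alpha = 0.05) {
  if (inherits(fits, "cox_fit")) fits <- list(fits)
  k <- length(fits)
  if (k < 2) stop("meta-analysis needs at least 2 cohort fits")
  theta <- vapply(fits, function(f) f$log_hr, 0)
  se <- vapply(fits, function(f) f$se, 0)
  if (any(!is.finite(se)) || any(se <= 0)) stop("all se must be positive")
  w <- 1 / se^2
  theta_f <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - theta_f)^2)
  q_pvalue <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  if (q_pvalue < het_alpha) {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (se^2 + tau2)
    combined <- sum(w_star * theta) / sum(w_star)
    combined_se <- 1 / sqrt(sum(w_star))
    model <- "random"
  } else {
    tau2 <- 0
    combined <- theta_f
    combined_se <- 1 / sqrt(sum(w))
    model <- "fixed"
  }
  z <- combined / combined_se
  structure(list(fits = fits, k = k, Q = Q, q_pvalue = q_pvalue,
                 tau2 = tau2, model = model,
                 combined_log_hr = combined, combined_se = combined_se,
                 combined_hr = exp(combined),
                 ci95 = exp(combined + c(-1, 1) * 1.96 * combined_se),
                 p = 2 * stats::pnorm(abs(z), lower.tail = FALSE)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %d cohorts, %s-effect model\n  combined HR = %.3f [%.3f, %.3f], p = %.3g\n  Q = %.2f (p = %.3g), tau^2 = %.4f\n",
    x$k, x$model, x$combined_hr, x$ci95[1], x$ci95[2], x$p,
    x$Q, x$q_pvalue, x$tau2))
  invisible(x)
}

#' Forest table of per-cohort fits with meta weights
#'
#' @param meta a `meta_result`.
#' @return data.frame: `cohort_id`, `n`, `n_events`, `hr`, `ci_lo`, `ci_hi`,
#'   `weight_pct` (weights of the selected model).
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  theta <- vapply(meta$fits, function(f) f$log_hr, 0)
  se <- vapply(meta$fits, function(f) f$se, 0)
  w <- 1 / (se^2 + meta$tau2)
  data.frame(cohort_id = vapply(meta$fits, function(f) f$cohort_id, ""),
             n = vapply(meta$fits, function(f) f$n, 0L),
             n_events = vapply(meta$fits, function(f) f$n_events, 0L),
             hr = exp(theta),
             ci_lo = exp(theta - 1.96 * se),
             ci_hi = exp(theta + 1.96 * se),
             weight_pct = 100 * w / sum(w),
             stringsAsFactors = FALSE)
}
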