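# End-to-end orchestration: simulate (or load) -> differential expression
# -> signature derivation -> cohort scoring -> dichotomized Cox survival ->
# meta-analysis -> report files. Every stage's output is persisted under
# the output directory; reruns with the same config and seed are
# bit-identical.

#' Assemble a pipeline configuration
#'
#' Exactly one input source is supported per input: simulation configs
#' (the default) or file paths. File-based mouse input expects per-model
#' expression/annotation files; file-based human input expects per-cohort
#' expression/annotation/clinical files.
#'
#' @param mouse a [mouse_sim_config()], or a list of two
#'   `list(expression=, annotations=)` file-path pairs.
#' @param human a [human_sim_config()], or a list of
#'   `list(expression=, annotations=, clinical=)` file-path triples.
#' @param fc_threshold,fdr_threshold derivation thresholds.
#' @param het_alpha heterogeneity test level.
#' @param horizon_months 5-year analysis horizon.
#' @param landmark_months landmark for late-relapse analysis.
#' @param late_relapse also run the landmarked late-relapse analysis?
#' @param proliferation_signature optional [gene_signature()]; when given,
#'   cohorts are additionally scored with it and the Cox fits adjust for
#'   that score as a covariate.
#' @param nu0,window regularized t-test settings.
#' @param seed master seed for the simulation stages.
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mouse = mouse_sim_config(),
                            human = human_sim_config(),
                            fc_threshold = 1.5, fdr_threshold = 0.1,
                            het_alpha = 0.05, horizon_months = 60,
                            landmark_months = 60, late_relapse = FALSE,
                            proliferation_signature = NULL,
                            nu0 = 10, window = 101L,
                            seed = 1L, out_dir = tempfile("dormsig_run_")) {
  if (fc_threshold <= 0 || fdr_threshold < 0 || het_alpha <= 0 ||
      horizon_months <= 0 || landmark_months <= 0)
    stop("thresholds must be positive")
  structure(list(mouse = mouse, human = human,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 het_alpha = het_alpha, horizon_months = horizon_months,
                 landmark_months = landmark_months,
                 late_relapse = isTRUE(late_relapse),
                 proliferation_signature = proliferation_signature,
                 nu0 = nu0, window = as.integer(window),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.load_mouse <- function(cfg) {
  if (inherits(cfg$mouse, "mouse_sim_config")) {
    sim_cfg <- cfg$mouse
    sim_cfg$seed <- cfg$seed
    generate_mouse_models(sim_cfg)
  } else {
    models <- lapply(cfg$mouse, function(m)
      read_expression(m$expression, m$annotations))
    list(models = models, truth = NULL)
  }
}

.load_human <- function(cfg, signature) {
  if (inherits(cfg$human, "human_sim_config")) {
    sim_cfg <- cfg$human
    sim_cfg$seed <- cfg$seed + 1L
    # simulated cohorts carry the signal of the signature just derived, so
    # the scoring/survival stages see the structure they assume
    generate_human_cohorts(sim_cfg, signature)
  } else {
    cohorts <- lapply(cfg$human, function(h)
      list(expression = read_expression(h$expression, h$annotations),
           survival = read_clinical(h$clinical)))
    list(cohorts = cohorts, truth = NULL)
  }
}

# score + dichotomize + endpoint-select + truncate/landmark + cox for one
# cohort; returns NULL (with logged reason) when the cohort is dropped
.cohort_fit <- function(cohort, signature, prolif_sig, horizon, landmark,
                        late, log) {
  cid <- cohort$survival$cohort_id[1]
  tryCatch({
    restricted <- harmonize(list(cohort$expression), signature)[[1]]
    sc <- dichotomize_by_median(
      score_samples(cohort$expression, restricted$signature))
    surv <- cohort$survival
    surv$endpoint <- select_endpoint(surv$endpoint)
    surv2 <- if (late) landmark_late(surv, landmark) else
      truncate_5y(surv, horizon)
    labs <- sc$label[match(surv2$patient_id, sc$sample_id)]
    adj <- NULL
    if (!is.null(prolif_sig)) {
      psc <- score_samples(cohort$expression, prolif_sig)
      adj <- psc$score[match(surv2$patient_id, psc$sample_id)]
    }
    fit <- cox_binary(surv2, labs, adjustment = adj)
    fit$coverage <- restricted$coverage
    fit$scores <- sc
    fit
  }, error = function(e) {
    log(sprintf("cohort %s dropped (%s analysis): %s", cid,
                if (late) "late" else "5y", conditionMessage(e)))
    NULL
  })
}

#' Run the full dormancy-signature pipeline
#'
#' Stages: load/simulate mouse models; run the four RL-vs-comparator
#' regularized t-tests; derive the concordant signature; load/simulate
#' patient cohorts; harmonize, score and median-dichotomize each cohort;
#' select endpoints, truncate at the 5-year horizon (and optionally
#' landmark for late relapse); fit per-cohort Cox models (cohorts that
#' fail are dropped with a logged reason); meta-analyze. All stage outputs
#' are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`: `signature`, `de_tables`, `scores`,
#'   `meta_5y`, `forest_5y`, `meta_late`/`forest_late` (if requested),
#'   `dropped`, `log`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  log(sprintf("seed=%d fc>%g fdr<%g het_alpha=%g horizon=%g landmark=%g",
              config$seed, config$fc_threshold, config$fdr_threshold,
              config$het_alpha, config$horizon_months,
              config$landmark_months))

  mouse <- .load_mouse(config)
  cmp <- mouse_comparisons(mouse$models, window = config$window,
                           nu0 = config$nu0)
  for (nm in names(cmp))
    write_de_result(cmp[[nm]], file.path(config$out_dir,
                                         paste0("de_", nm, ".tsv")))
  signature <- derive_dormancy_signature(cmp, config$fc_threshold,
                                         config$fdr_threshold)
  if (nrow(signature) == 0)
    stop("no genes passed the derivation thresholds; aborting before scoring")
  write_signature_gmt(signature, file.path(config$out_dir, "signature.gmt"))
  log(sprintf("derived signature: %d genes (%d up, %d down in RL)",
              nrow(signature), sum(signature$weight > 0),
              sum(signature$weight < 0)))

  human <- .load_human(config, signature)
  fits_5y <- list(); fits_late <- list(); all_scores <- list()
  dropped <- character(0)
  for (cohort in human$cohorts) {
    f <- .cohort_fit(cohort, signature, config$proliferation_signature,
                     config$horizon_months, config$landmark_months,
                     late = FALSE, log = log)
    if (is.null(f)) {
      dropped <- c(dropped, cohort$survival$cohort_id[1])
    } else {
      all_scores[[length(all_scores) + 1L]] <- f$scores
      f$scores <- NULL
      fits_5y[[length(fits_5y) + 1L]] <- f
    }
    if (config$late_relapse) {
      fl <- .cohort_fit(cohort, signature, config$proliferation_signature,
                        config$horizon_months, config$landmark_months,
                        late = TRUE, log = log)
      if (!is.null(fl)) {
        fl$scores <- NULL
        fits_late[[length(fits_late) + 1L]] <- fl
      }
    }
  }
  scores <- do.call(rbind, all_scores)
  if (!is.null(scores)) {
    class(scores) <- c("score_table", "data.frame")
    write_scores(scores, file.path(config$out_dir, "scores.tsv"))
  }

  meta_5y <- meta_analyze(fits_5y, config$het_alpha)
  forest_5y <- forest_table(meta_5y)
  utils::write.table(forest_5y, file.path(config$out_dir, "forest_5y.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta_json <- function(m) list(k = m$k, Q = m$Q, q_pvalue = m$q_pvalue,
                                tau2 = m$tau2, model = m$model,
                                hr = m$combined_hr, ci_lo = m$ci95[1],
                                ci_hi = m$ci95[2], p = m$p)
  payload <- list(seed = config$seed,
                  thresholds = list(fc = config$fc_threshold,
                                    fdr = config$fdr_threshold,
                                    het_alpha = config$het_alpha,
                                    horizon_months = config$horizon_months,
                                    landmark_months = config$landmark_months),
                  n_signature_genes = nrow(signature),
                  dropped_cohorts = as.list(dropped),
                  meta_5y = meta_json(meta_5y))
  report <- list(signature = signature, de_tables = cmp, scores = scores,
                 meta_5y = meta_5y, forest_5y = forest_5y,
                 dropped = dropped, config = config, truth = human$truth)
  if (config$late_relapse) {
    if (length(fits_late) >= 2) {
      meta_late <- meta_analyze(fits_late, config$het_alpha)
      report$meta_late <- meta_late
      report$forest_late <- forest_table(meta_late)
      utils::write.table(report$forest_late,
                         file.path(config$out_dir, "forest_late.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      payload$meta_late <- meta_json(meta_late)
    } else {
      log("late-relapse meta-analysis skipped: fewer than 2 analyzable cohorts")
    }
  }
  jsonlite::write_json(payload, file.path(config$out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  report$log <- log_lines
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> signature of %d genes; %d cohorts analyzed",
              nrow(x$signature), x$meta_5y$k),
      if (length(x$dropped)) sprintf(" (%d dropped)", length(x$dropped))
      else "", "\n", sep = "")
  print(x$meta_5y)
  invisible(x)
}
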