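# Synthetic data with the statistical structure the analysis assumes:
# two-model mouse residual-lesion expression with planted concordant
# dormancy genes, multi-cohort patient expression + proportional-hazards
# survival coupled to the signature score, and single-hit Poisson
# limiting-dilution outcomes.
#
# All generators are deterministic given their config seed; per-cohort
# sub-seeds are derived from the master seed so cohorts have independent
# noise streams.

.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% (.Machine$integer.max - 1))
}

#' Configuration for the two-model mouse expression simulation
#'
#' Defaults describe the stated world of the derivation experiments: 2000
#' genes, 4 replicates per group, 60 planted concordant dormancy genes at
#' log2 effect 1.2 (comfortably above the 1.5-fold threshold), residual
#' log2 noise sd 0.5, plus model-specific and discordant distractor genes
#' that must NOT be recovered.
#'
#' @param n_genes total genes simulated.
#' @param n_per_group replicates per {PT, RL, RT} group per model.
#' @param n_planted concordant dormancy genes (shifted in RL, same sign in
#'   both models).
#' @param planted_lfc log2 shift of planted genes in RL vs both PT and RT;
#'   sign randomized per gene, shared across models.
#' @param n_model_specific distractors DE in only one model (split between
#'   the two models).
#' @param n_discordant distractors DE with opposite signs in the two
#'   models.
#' @param noise_sd residual log2 sd (> 0).
#' @param seed integer seed.
#' @return list of class `mouse_sim_config`.
#' @export
mouse_sim_config <- function(n_genes = 2000L, n_per_group = 4L,
                             n_planted = 60L, planted_lfc = 1.2,
                             n_model_specific = 100L, n_discordant = 40L,
                             noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group),
              n_planted = as.integer(n_planted),
              planted_lfc = as.numeric(planted_lfc),
              n_model_specific = as.integer(n_model_specific),
              n_discordant = as.integer(n_discordant),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_per_group < 1) stop("sizes must be positive")
  if (cfg$n_planted + cfg$n_model_specific + cfg$n_discordant > cfg$n_genes)
    stop("infeasible gene budget: planted + distractors exceed n_genes")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  structure(cfg, class = "mouse_sim_config")
}

#' Simulate the two-model mouse residual-lesion expression experiment
#'
#' Each model yields PT/RL/RT groups with `n_per_group` samples. Baseline
#' gene means are drawn once (log2 N(7, 1.5)) and shared across groups and
#' models; planted genes are shifted by `+/- planted_lfc` in RL only, with
#' the same sign in both models; model-specific distractors are shifted in
#' the RL of one model only (half in each); discordant distractors are
#' shifted with opposite signs in the two models; Gaussian noise with sd
#' `noise_sd` is added everywhere.
#'
#' @param config a [mouse_sim_config()].
#' @return list with `models` (named list of two [expr_matrix()]) and
#'   `truth` (list: `planted_genes` data.frame of gene_id/direction,
#'   `model_specific_genes`, `discordant_genes`).
#' @export
generate_mouse_models <- function(config) {
  stopifnot(inherits(config, "mouse_sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; np <- config$n_per_group
  gene_ids <- sprintf("g%05d", seq_len(ng))
  baseline <- stats::rnorm(ng, mean = 7, sd = 1.5)

  idx_planted <- seq_len(config$n_planted)
  idx_ms <- seq_len(config$n_model_specific) + config$n_planted
  idx_disc <- seq_len(config$n_discordant) + config$n_planted +
    config$n_model_specific
  dir_planted <- sample(c(-1, 1), config$n_planted, replace = TRUE)
  dir_ms <- sample(c(-1, 1), config$n_model_specific, replace = TRUE)
  ms_model <- rep_len(1:2, config$n_model_specific)
  dir_disc <- sample(c(-1, 1), config$n_discordant, replace = TRUE)

  groups <- c("PT", "RL", "RT")
  model_names <- c("her2", "wnt1")
  models <- lapply(1:2, function(m) {
    shift <- numeric(ng)
    shift[idx_planted] <- dir_planted * config$planted_lfc
    sel <- ms_model == m
    shift[idx_ms[sel]] <- dir_ms[sel] * config$planted_lfc
    dsign <- if (m == 1) dir_disc else -dir_disc
    shift[idx_disc] <- dsign * config$planted_lfc
    sample_ids <- as.vector(outer(groups, seq_len(np),
                                  function(g, r) sprintf("%s_%s_r%d",
                                                         model_names[m], g, r)))
    grp <- rep(groups, times = np)
    mu <- matrix(baseline, ng, length(sample_ids))
    mu[, grp == "RL"] <- mu[, grp == "RL"] + shift
    vals <- mu + matrix(stats::rnorm(ng * length(sample_ids),
                                     sd = config$noise_sd),
                        ng, length(sample_ids))
    dimnames(vals) <- list(gene_ids, sample_ids)
    expr_matrix(vals, data.frame(sample_id = sample_ids,
                                 model_id = model_names[m], group = grp,
                                 stringsAsFactors = FALSE))
  })
  names(models) <- model_names
  list(models = models,
       truth = list(
         planted_genes = data.frame(gene_id = gene_ids[idx_planted],
                                    direction = dir_planted,
                                    stringsAsFactors = FALSE),
         model_specific_genes = gene_ids[idx_ms],
         discordant_genes = gene_ids[idx_disc]))
}

#' Run the four derivation comparisons on simulated (or real) mouse models
#'
#' Convenience wrapper producing the [comparison_set()] of RL-vs-PT and
#' RL-vs-RT tests for two models.
#'
#' @param models named list of two [expr_matrix()] with PT/RL/RT groups.
#' @param ... passed to [regularized_ttest()] (`window`, `nu0`).
#' @return a [comparison_set()].
#' @export
mouse_comparisons <- function(models, ...) {
  stopifnot(length(models) == 2L)
  one <- function(m, comparator) {
    ann <- m$annotations
    regularized_ttest(m, ann$sample_id[ann$group == "RL"],
                      ann$sample_id[ann$group == comparator], ...)
  }
  comparison_set(one(models[[1]], "PT"), one(models[[1]], "RT"),
                 one(models[[2]], "PT"), one(models[[2]], "RT"))
}

#' Configuration for the multi-cohort patient simulation
#'
#' Defaults describe the stated world of the survival meta-analysis: 17
#' cohorts of 260 patients (~4400 total), signature-gene expression coupled
#' to a latent dormancy activity with unit coupling, a planted hazard ratio
#' of 0.49 for score-high vs score-low, an exponential baseline hazard of
#' 0.01 events/month (~45% 5-year event probability in the low group),
#' light random censoring (0.003/month) and administrative censoring at 120
#' months.
#'
#' @param n_cohorts number of patient cohorts.
#' @param n_patients patients per cohort.
#' @param coupling beta, expression shift of each signature gene per unit
#'   latent activity, in the gene's weight direction.
#' @param true_hr planted hazard ratio (> 0) of high vs low score group.
#' @param baseline_rate exponential event hazard (per month) in the low
#'   group.
#' @param censor_rate exponential censoring hazard per month (0 disables).
#' @param horizon_months administrative censoring horizon (Inf disables).
#' @param n_extra_genes unrelated noise genes added to each cohort matrix.
#' @param seed integer seed.
#' @return list of class `human_sim_config`.
#' @export
human_sim_config <- function(n_cohorts = 17L, n_patients = 260L,
                             coupling = 1, true_hr = 0.49,
                             baseline_rate = 0.01, censor_rate = 0.003,
                             horizon_months = 120, n_extra_genes = 40L,
                             seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_patients = as.integer(n_patients),
              coupling = as.numeric(coupling),
              true_hr = as.numeric(true_hr),
              baseline_rate = as.numeric(baseline_rate),
              censor_rate = as.numeric(censor_rate),
              horizon_months = as.numeric(horizon_months),
              n_extra_genes = as.integer(n_extra_genes),
              seed = as.integer(seed))
  if (cfg$n_cohorts < 1 || cfg$n_patients < 2) stop("sizes must be positive")
  if (!is.finite(cfg$true_hr) || cfg$true_hr <= 0) stop("true_hr must be > 0")
  if (cfg$baseline_rate < 0 || cfg$censor_rate < 0) stop("rates must be >= 0")
  structure(cfg, class = "human_sim_config")
}

#' Simulate patient cohorts with survival coupled to a signature score
#'
#' Per patient, a latent dormancy activity `a ~ N(0, 1)` drives signature
#' genes: `expression = baseline + weight * coupling * a + N(0, 1)` noise;
#' extra genes are pure noise. The weighted z-score of the generated
#' expression is computed (exactly as [score_samples()] does) and the
#' cohort is split at its realized median (ties to low); the event hazard
#' is `baseline_rate * true_hr^[high]`, so `true_hr` is the literal
#' estimand of the dichotomized Cox model downstream. Event times are
#' exponential; censoring is independent exponential plus administrative
#' censoring at `horizon_months`. Cohort endpoints cycle through
#' RFS/RFS/RFS/DMFS/DSS.
#'
#' @param config a [human_sim_config()].
#' @param signature a [gene_signature()] giving the coupled genes; default
#'   is a generic 30-gene direction signature.
#' @return list with `cohorts` (list of lists: `expression`, `survival`)
#'   and `truth` (list: `signature`, `true_hr`, `labels` per cohort).
#' @export
generate_human_cohorts <- function(config, signature = NULL) {
  stopifnot(inherits(config, "human_sim_config"))
  if (is.null(signature))
    signature <- gene_signature(sprintf("SG%03d", 1:30),
                                rep(c(1, -1), 15), name = "planted")
  stopifnot(inherits(signature, "gene_signature"))
  endpoints <- rep_len(c("RFS", "RFS", "RFS", "DMFS", "DSS"),
                       config$n_cohorts)
  truth_labels <- vector("list", config$n_cohorts)
  cohorts <- lapply(seq_len(config$n_cohorts), function(i) {
    set.seed(.sub_seed(config$seed, i))
    cid <- sprintf("cohort%02d", i)
    npt <- config$n_patients
    pid <- sprintf("%s_p%04d", cid, seq_len(npt))
    a <- stats::rnorm(npt)
    nsig <- nrow(signature)
    base_sig <- stats::rnorm(nsig, 7, 1.5)
    sigvals <- base_sig +
      outer(signature$weight * config$coupling, a) +
      matrix(stats::rnorm(nsig * npt), nsig, npt)
    extra <- matrix(stats::rnorm(config$n_extra_genes * npt, 7, 1.5),
                    config$n_extra_genes, npt)
    vals <- rbind(sigvals, extra)
    dimnames(vals) <- list(c(signature$gene_id,
                             sprintf("NOISE%03d_%02d",
                                     seq_len(config$n_extra_genes), i)),
                           pid)
    em <- expr_matrix(vals, data.frame(sample_id = pid, cohort_id = cid,
                                       stringsAsFactors = FALSE))
    sc <- dichotomize_by_median(score_samples(em, signature))
    high <- sc$label[match(pid, sc$sample_id)] == "high"
    rate <- config$baseline_rate * ifelse(high, config$true_hr, 1)
    t_event <- if (config$baseline_rate > 0) stats::rexp(npt, rate) else
      rep(Inf, npt)
    t_cens <- if (config$censor_rate > 0)
      stats::rexp(npt, config$censor_rate) else rep(Inf, npt)
    t_obs <- pmin(t_event, t_cens, config$horizon_months)
    event <- as.integer(t_event <= t_cens & t_event <= config$horizon_months)
    truth_labels[[i]] <<- ifelse(high, "high", "low")
    list(expression = em,
         survival = cohort_survival(pid, t_obs, event,
                                    endpoint = endpoints[i],
                                    cohort_id = cid))
  })
  names(cohorts) <- sprintf("cohort%02d", seq_len(config$n_cohorts))
  names(truth_labels) <- names(cohorts)
  list(cohorts = cohorts,
       truth = list(signature = signature, true_hr = config$true_hr,
                    labels = truth_labels))
}

#' Simulate a limiting-dilution assay from a true TIC frequency
#'
#' Takes at dose `d` are `Binomial(n_per_dose, 1 - exp(-f d))`.
#'
#' @param true_frequency f in (0, 1].
#' @param doses positive cell doses.
#' @param n_per_dose injections per dose.
#' @param seed integer seed.
#' @param group_label label for the generated assay.
#' @return an [ld_assay()].
#' @export
generate_ld_assay <- function(true_frequency, doses = c(100, 300, 1000, 3000),
                              n_per_dose = 6L, seed = 1L,
                              group_label = "sim") {
  if (!is.finite(true_frequency) || true_frequency <= 0 || true_frequency > 1)
    stop("true_frequency must lie in (0, 1]")
  if (any(doses <= 0)) stop("doses must be positive")
  set.seed(as.integer(seed))
  p_take <- -expm1(-true_frequency * doses)
  takes <- stats::rbinom(length(doses), n_per_dose, p_take)
  ld_assay(doses, rep(n_per_dose, length(doses)), takes, group_label)
}
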