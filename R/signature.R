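# Derivation of the cross-model concordant dormancy signature and signed
# z-score scoring of samples/patients.

#' Bundle the four differential-expression comparisons used for derivation
#'
#' The dormancy signature is defined from four comparisons, all oriented
#' "residual lesion minus comparator": RL vs PT and RL vs RT in each of two
#' mouse models (e.g. HER2/neu and Wnt1). Gene universes may differ between
#' tables; derivation uses their intersection.
#'
#' @param m1_rl_pt,m1_rl_rt,m2_rl_pt,m2_rl_rt `de_result` tables.
#' @return list of class `comparison_set`.
#' @export
comparison_set <- function(m1_rl_pt, m1_rl_rt, m2_rl_pt, m2_rl_rt) {
  cmp <- list(m1_rl_pt = m1_rl_pt, m1_rl_rt = m1_rl_rt,
              m2_rl_pt = m2_rl_pt, m2_rl_rt = m2_rl_rt)
  for (nm in names(cmp))
    if (!inherits(cmp[[nm]], "de_result"))
      stop(nm, " is not a de_result")
  structure(cmp, class = "comparison_set")
}

#' Derive the dormancy gene signature from the four-way comparison set
#'
#' A gene enters the signature iff, in all four comparisons, it passes
#' `|fold-change| > fc_threshold` on the anti-logged scale (i.e.
#' `|log2fc| > log2(fc_threshold)`), `q < fdr_threshold`, and the sign of
#' its `log2fc` is identical across all four comparisons (concordant in
#' both models and against both comparator states). The gene's weight is
#' that common sign: +1 = up in residual lesions.
#'
#' @param comparisons a [comparison_set()].
#' @param fc_threshold fold-change threshold on the linear scale
#'   (default 1.5, strict inequality).
#' @param fdr_threshold FDR threshold (default 0.1, strict inequality).
#' @return a [gene_signature()] with weights in `{-1, +1}`. May have zero
#'   genes if nothing passes.
#' @export
derive_dormancy_signature <- function(comparisons, fc_threshold = 1.5,
                                      fdr_threshold = 0.1) {
  stopifnot(inherits(comparisons, "comparison_set"))
  if (fc_threshold <= 0 || fdr_threshold <= 0) stop("thresholds must be > 0")
  genes <- Reduce(intersect, lapply(comparisons, function(d) d$gene_id))
  if (!length(genes)) stop("empty intersection of gene universes")
  lfc_thr <- log2(fc_threshold)
  lfc <- sapply(comparisons, function(d) d$log2fc[match(genes, d$gene_id)])
  qv <- sapply(comparisons, function(d) d$q[match(genes, d$gene_id)])
  pass_fc <- rowSums(abs(lfc) > lfc_thr) == 4L
  pass_q <- rowSums(qv < fdr_threshold) == 4L
  sgn <- sign(lfc)
  concordant <- (rowSums(sgn == 1) == 4L) | (rowSums(sgn == -1) == 4L)
  keep <- pass_fc & pass_q & concordant
  if (!any(keep)) {
    out <- data.frame(gene_id = character(0), weight = numeric(0))
    attr(out, "name") <- "dormancy"
    attr(out, "provenance") <- "derived: empty (no genes passed)"
    class(out) <- c("gene_signature", "data.frame")
    return(out)
  }
  gene_signature(genes[keep], sgn[keep, 1],
                 name = "dormancy",
                 provenance = sprintf(
                   "derived: |FC|>%g, FDR<%g, concordant in 4/4 comparisons",
                   fc_threshold, fdr_threshold))
}

#' Score samples with a signed gene signature (weighted z-score average)
#'
#' Within each cohort independently, every measured signature gene is
#' standardized across that cohort's samples (subtract mean, divide by sd;
#' zero-sd genes are dropped with a warning). The per-sample score is the
#' weighted average of those z-scores,
#' `score_j = sum_g w_g * z_gj / sum_g |w_g|`,
#' with the denominator taken over the genes actually retained in that
#' cohort, so score magnitudes stay comparable across cohorts with
#' different platform coverage. Works for direction-only signatures
#' (weights +/-1), log-fold-change-weighted signatures (proliferation),
#' and pathway-activity gene lists alike.
#'
#' @param matrix an [expr_matrix()]. Samples with no `cohort_id` annotation
#'   are pooled into a single implicit cohort.
#' @param signature a [gene_signature()]; at least one gene must be
#'   measured.
#' @return data.frame of class `score_table`: `sample_id`, `cohort_id`,
#'   `score`, `n_genes_used`.
#' @export
score_samples <- function(matrix, signature) {
  stopifnot(inherits(matrix, "expr_matrix"),
            inherits(signature, "gene_signature"))
  if (ncol(matrix$values) < 2) stop("need at least 2 samples to z-score")
  present <- signature$gene_id %in% rownames(matrix$values)
  if (!any(present)) stop("no signature gene measured in the matrix")
  sig <- signature[present, , drop = FALSE]
  coh <- matrix$annotations$cohort_id
  coh[is.na(coh)] <- "(all)"
  out <- lapply(unique(coh), function(cid) {
    idx <- which(coh == cid)
    if (length(idx) < 2)
      stop("cohort '", cid, "' has fewer than 2 samples; cannot z-score")
    sub <- matrix$values[sig$gene_id, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    keep <- sdv > 0
    if (!any(keep))
      stop("cohort '", cid, "': all signature genes have zero variance")
    if (!all(keep))
      warning("cohort '", cid, "': dropping ", sum(!keep),
              " zero-variance signature gene(s)")
    z <- (sub[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    w <- sig$weight[keep]
    data.frame(sample_id = colnames(sub),
               cohort_id = cid,
               score = as.numeric(crossprod(w, z)) / sum(abs(w)),
               n_genes_used = sum(keep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Dichotomize signature scores at each cohort's median
#'
#' Patients with score strictly above their cohort's median are labeled
#' `high`; scores equal to the median go to `low` (deterministic tie rule).
#' Labels are computed per cohort over all scored patients, before any
#' survival truncation or landmarking.
#'
#' @param scores a `score_table` from [score_samples()].
#' @return the score table with an added factor column `label`
#'   (levels `low`, `high`).
#' @export
dichotomize_by_median <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  lab <- rep(NA_character_, nrow(scores))
  for (cid in unique(scores$cohort_id)) {
    idx <- which(scores$cohort_id == cid)
    if (length(idx) < 2) stop("cohort '", cid, "' has fewer than 2 patients")
    s <- scores$score[idx]
    if (max(s) == min(s))
      stop("cohort '", cid, "': all scores identical, degenerate split")
    lab[idx] <- ifelse(s > stats::median(s), "high", "low")
  }
  scores$label <- factor(lab, levels = c("low", "high"))
  scores
}

#' Write a score table (with labels if present) to a tab-delimited file
#' @param x a `score_table`.
#' @param path output file.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "score_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
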