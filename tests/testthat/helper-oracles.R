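# Independent oracles used across the suite. Each is deliberately written
# from the textbook definition, not by calling the package's own code path.

# ordinary pooled-variance two-sample t (oracle for regularized_ttest at
# nu0 = 0), via stats::t.test
oracle_pooled_t <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

# brute-force BH step-up: q_i = smallest alpha at which the step-up
# procedure rejects hypothesis i, scanning the finite set of candidate
# levels where the rejection set can change
oracle_bh <- function(p) {
  g <- length(p)
  ord <- order(p)
  ps <- p[ord]
  cand <- sort(unique(pmin(1, ps * g / seq_len(g))))
  rejected_at <- function(alpha) {
    # tiny nudge guards against float round-trip in alpha = p*g/j
    ok <- which(ps <= alpha * seq_len(g) / g + 1e-12)
    if (!length(ok)) integer(0) else seq_len(max(ok))
  }
  q_sorted <- rep(NA_real_, g)
  for (alpha in cand) {
    rej <- rejected_at(alpha)
    newly <- setdiff(rej, which(!is.na(q_sorted)))
    q_sorted[newly] <- alpha
  }
  q_sorted[is.na(q_sorted)] <- 1
  q <- numeric(g)
  q[ord] <- q_sorted
  q
}

# Efron-corrected Cox partial log-likelihood for a single binary/numeric
# covariate, written from the formula
oracle_efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  risk <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(risk[D])
    sumR <- sum(risk[R])
    ll <- ll + sum(eta[D]) -
      sum(vapply(seq_len(d) - 1L,
                 function(l) log(sumR - (l / d) * sumD), 0))
  }
  ll
}

# two-stage grid-search maximizer of a 1-D function (coarse then fine)
oracle_grid_max <- function(f, lo, hi, coarse = 1e-3, fine = 1e-7) {
  g1 <- seq(lo, hi, by = coarse)
  v1 <- vapply(g1, f, 0)
  b1 <- g1[which.max(v1)]
  g2 <- seq(b1 - 2 * coarse, b1 + 2 * coarse, by = fine)
  g2[which.max(vapply(g2, f, 0))]
}

# single-hit Poisson log-likelihood, written from the model definition
oracle_ld_loglik <- function(f, dose, n, r) {
  p <- 1 - exp(-f * dose)
  sum(r * log(p) + (n - r) * log(1 - p))
}

# exact hypergeometric upper tail P(X >= k) by choose() enumeration
oracle_hyper_upper <- function(k, N, K, n) {
  kk <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= k])
}

# fabricate a de_result table with given log2fc and q (other columns
# filled consistently) for signature-derivation tests
make_de <- function(gene_id, log2fc, q, p = q / 2) {
  out <- data.frame(gene_id = gene_id, mean_A = log2fc, mean_B = 0,
                    log2fc = log2fc, t_reg = sign(log2fc) * 5,
                    p = p, q = q, pooled_sd = 1, background_sd = 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

# small deterministic expression matrix builder
make_expr <- function(vals, genes = NULL, samples = NULL, cohort_id = NA,
                      group = NA, model_id = NA) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(vals)))
  dimnames(vals) <- list(genes, samples)
  ann <- data.frame(sample_id = samples, model_id = model_id,
                    group = group, cohort_id = cohort_id,
                    stringsAsFactors = FALSE)
  if (all(is.na(ann$group)) && all(is.na(ann$cohort_id)))
    ann$cohort_id <- "c1"
  expr_matrix(vals, ann)
}
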