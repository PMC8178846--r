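# Two-group differential expression with a Bayesian-regularized
# (Cyber-T style) t-statistic and Benjamini-Hochberg FDR control.
#
# The regularization shrinks each gene's pooled variance toward a local
# background variance estimated from genes of similar overall expression,
# on the premise that genes expressed at similar levels have similar
# measurement variance. With nu0 = 0 the statistic reduces exactly to the
# ordinary pooled-variance Student t.

#' Regularized two-group t-test over all genes of an expression matrix
#'
#' For each gene, the pooled sample variance `s2` across both groups
#' (`df_raw = n_A + n_B - 2`) is combined with a background variance
#' `sigma0^2` -- the mean pooled variance over the `window` genes whose
#' overall mean expression rank is nearest the gene's (window centered on
#' the gene's rank, truncated at the extremes of the ranking). The
#' posterior variance is
#' `v = (nu0 * sigma0^2 + (n - 2) * s2) / (nu0 + n - 2)`
#' and the statistic
#' `t_reg = (mean_A - mean_B) / sqrt(v * (1/n_A + 1/n_B))`
#' is referred to a Student t distribution with `nu0 + n - 2` degrees of
#' freedom (two-sided). `log2fc` is `mean_A - mean_B`, with A the
#' residual-lesion-style group by convention.
#'
#' @param matrix an [expr_matrix()].
#' @param group_a,group_b character vectors of sample ids; each group needs
#'   at least 2 samples.
#' @param window odd positive integer, size of the background window
#'   (default 101, clipped to the number of genes).
#' @param nu0 nonnegative prior degrees of freedom (default 10); `nu0 = 0`
#'   gives the ordinary pooled t-test.
#' @return data.frame of class `de_result` with per-gene columns `gene_id`,
#'   `mean_A`, `mean_B`, `log2fc`, `t_reg`, `p`, `q`, `pooled_sd`,
#'   `background_sd`.
#' @export
regularized_ttest <- function(matrix, group_a, group_b,
                              window = 101L, nu0 = 10) {
  stopifnot(inherits(matrix, "expr_matrix"))
  vals <- matrix$values
  miss <- setdiff(c(group_a, group_b), colnames(vals))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 samples")
  if (nu0 < 0) stop("nu0 must be nonnegative")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  window <- min(window, nrow(vals))

  a <- vals[, group_a, drop = FALSE]
  b <- vals[, group_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  df_raw <- n_a + n_b - 2L
  s2 <- (ss_a + ss_b) / df_raw

  # background variance: running mean of s2 over the window of genes
  # nearest in overall mean expression (both groups jointly)
  overall <- rowMeans(vals[, c(group_a, group_b), drop = FALSE])
  ord <- order(overall)
  s2_ord <- s2[ord]
  g <- length(s2_ord)
  half <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(g) - half, 1L)
  hi <- pmin(seq_len(g) + half, g)
  cs <- c(0, cumsum(s2_ord))
  bg_ord <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  sigma0_2 <- numeric(g)
  sigma0_2[ord] <- bg_ord

  if (nu0 == 0 && all(s2 == 0))
    stop("zero variance everywhere with nu0 = 0 (first gene: '",
         rownames(vals)[1], "')")
  v <- (nu0 * sigma0_2 + df_raw * s2) / (nu0 + df_raw)
  diff <- mean_a - mean_b
  # an all-constant gene with no shift is a clean null (t = 0); a shift
  # with literally zero posterior variance is unresolvable
  if (any(v == 0 & diff != 0))
    stop("degenerate zero variance with nonzero shift for gene '",
         rownames(vals)[which(v == 0 & diff != 0)[1]], "'")
  t_reg <- ifelse(diff == 0, 0, diff / sqrt(v * (1 / n_a + 1 / n_b)))
  df_post <- nu0 + df_raw
  p <- 2 * stats::pt(abs(t_reg), df = df_post, lower.tail = FALSE)

  out <- data.frame(gene_id = rownames(vals),
                    mean_A = mean_a, mean_B = mean_b,
                    log2fc = mean_a - mean_b,
                    t_reg = t_reg, p = p, q = bh_fdr(p),
                    pooled_sd = sqrt(s2), background_sd = sqrt(sigma0_2),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  attr(out, "nu0") <- nu0
  attr(out, "window") <- window
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * G / j` over the ascending order of the G
#' p-values; tied p-values share the q of their common rank position; the
#' result is returned in the input order and capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values aligned with the input.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  g <- length(p)
  if (g == 0L) return(numeric(0))
  ord <- order(p)
  q_ord <- pmin(1, rev(cummin(rev(p[ord] * g / seq_len(g)))))
  q <- numeric(g)
  q[ord] <- q_ord
  # ties share the q of their shared rank position (the most favorable,
  # i.e. largest, rank of the tie block -- already what cummin delivers,
  # but enforce exact equality within ties)
  q <- stats::ave(q, p, FUN = min)
  q
}

#' Write a DE table to a tab-delimited file
#' @param x a `de_result`.
#' @param path output file.
#' @export
write_de_result <- function(x, path) {
  stopifnot(inherits(x, "de_result"))
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}
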