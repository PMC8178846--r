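# Tumor-initiating cell frequency from limiting-dilution assays under the
# single-hit Poisson model: P(tumor | dose d) = 1 - exp(-f * d).
#
# The log-likelihood over dose rows (r_d takes of n_d injections) is
#   l(f) = sum_d [ r_d * log(1 - exp(-f d)) - (n_d - r_d) * f * d ],
# unimodal in log f. The MLE is found by 1-D golden-section/parabolic
# optimization on log f and the 95% CI by profile likelihood (drop of
# qchisq(0.95, 1)/2 = 1.9207).

.LD_LOGF_MIN <- log(1e-12)

#' Construct a limiting-dilution assay table
#'
#' Rows sharing a dose are aggregated by summing counts (the likelihood
#' only depends on the per-dose totals), so doses end up distinct.
#'
#' @param dose positive integer cell doses.
#' @param n_injected number of injections per dose.
#' @param n_tumors number of tumor takes per dose, `0 <= n_tumors <=
#'   n_injected`.
#' @param group_label label for the cell population assayed.
#' @return data.frame of class `ld_assay`, one row per distinct dose,
#'   sorted by dose.
#' @export
ld_assay <- function(dose, n_injected, n_tumors, group_label = "group") {
  dose <- as.numeric(dose); n_injected <- as.integer(n_injected)
  n_tumors <- as.integer(n_tumors)
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(n_injected < 1)) stop("n_injected must be >= 1")
  if (any(n_tumors < 0) || any(n_tumors > n_injected))
    stop("need 0 <= n_tumors <= n_injected")
  agg <- rowsum(cbind(n_injected, n_tumors), group = dose)
  dose_u <- as.numeric(rownames(agg))
  ord <- order(dose_u)
  out <- data.frame(group_label = as.character(group_label),
                    dose = dose_u[ord],
                    n_injected = as.integer(agg[ord, 1]),
                    n_tumors = as.integer(agg[ord, 2]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ld_assay", "data.frame")
  out
}

#' Read limiting-dilution assays from a tab-delimited file
#'
#' Columns: `group`, `dose`, `n_injected`, `n_tumors`; one [ld_assay()] is
#' returned per distinct group.
#'
#' @param path input file.
#' @return named list of `ld_assay` objects.
#' @export
read_ld_assays <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("group", "dose", "n_injected", "n_tumors")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("assay table lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$group), function(d)
    ld_assay(d$dose, d$n_injected, d$n_tumors, d$group[1]))
  out
}

# single-hit Poisson log-likelihood at log-frequency lf; dose rows
# (d, n, r). Uses -expm1 for accuracy at tiny f*d.
.ld_loglik <- function(lf, d, n, r) {
  fd <- exp(lf) * d
  p_term <- ifelse(r > 0, r * log(-expm1(-fd)), 0)
  sum(p_term - (n - r) * fd)
}

#' Fit tumor-initiating cell frequency by maximum likelihood
#'
#' Requires an informative assay: at least one take and at least one
#' negative injection overall. All-negative assays leave the frequency
#' unidentifiable from below and all-positive assays from above; both are
#' errors directing the user to report a bound instead.
#'
#' @param assay an [ld_assay()].
#' @return list of class `ld_fit`: `frequency` (the MLE f), `one_in`
#'   (rounded 1/f), `ci95` on f (profile likelihood), `loglik`, `n_doses`,
#'   `group_label`.
#' @export
fit_frequency <- function(assay) {
  stopifnot(inherits(assay, "ld_assay"))
  d <- assay$dose; n <- assay$n_injected; r <- assay$n_tumors
  if (sum(r) == 0)
    stop("all-negative assay: frequency not identifiable; report upper bound")
  if (sum(r) == sum(n))
    stop("all-positive assay: frequency not identifiable; report lower bound")
  opt <- stats::optimize(.ld_loglik, c(.LD_LOGF_MIN, 0), d = d, n = n, r = r,
                         maximum = TRUE, tol = 1e-12)
  lf_hat <- opt$maximum
  ll_max <- opt$objective
  drop <- stats::qchisq(0.95, 1) / 2
  g <- function(lf) .ld_loglik(lf, d, n, r) - (ll_max - drop)
  lo <- if (g(.LD_LOGF_MIN) < 0)
    stats::uniroot(g, c(.LD_LOGF_MIN, lf_hat), tol = 1e-10)$root
  else .LD_LOGF_MIN
  hi <- if (g(0) < 0)
    stats::uniroot(g, c(lf_hat, 0), tol = 1e-10)$root
  else 0
  f <- exp(lf_hat)
  structure(list(frequency = f, one_in = round(1 / f),
                 ci95 = exp(c(lo, hi)), loglik = ll_max,
                 n_doses = length(d), group_label = assay$group_label[1]),
            class = "ld_fit")
}

#' @export
print.ld_fit <- function(x, ...) {
  cat(sprintf(
    "<ld_fit> %s: f = %.4g (1 in %d), 95%% CI [%.4g, %.4g], %d dose(s)\n",
    x$group_label, x$frequency, x$one_in, x$ci95[1], x$ci95[2], x$n_doses))
  invisible(x)
}

#' Compare TIC frequencies of two assays by likelihood-ratio test
#'
#' Tests H0: shared frequency against separate frequencies by comparing the
#' pooled-data fit with the two individual fits;
#' `LRT = 2 (l_a + l_b - l_shared)` referred to chi-squared with 1 df.
#'
#' @param a,b fittable [ld_assay()] objects.
#' @return list: `ratio` (`f_a / f_b`), `lrt_stat`, `lrt_p`, `fit_a`,
#'   `fit_b`.
#' @export
compare_frequencies <- function(a, b) {
  fit_a <- fit_frequency(a)
  fit_b <- fit_frequency(b)
  pooled <- rbind(as.data.frame(a), as.data.frame(b))
  # shared fit ignores the distinct-dose rule: evaluate the likelihood on
  # the concatenated rows directly
  opt <- stats::optimize(.ld_loglik, c(.LD_LOGF_MIN, 0), d = pooled$dose,
                         n = pooled$n_injected, r = pooled$n_tumors,
                         maximum = TRUE, tol = 1e-12)
  lrt <- max(0, 2 * (fit_a$loglik + fit_b$loglik - opt$objective))
  list(ratio = fit_a$frequency / fit_b$frequency,
       lrt_stat = lrt,
       lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       fit_a = fit_a, fit_b = fit_b)
}
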