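# Over-representation of a published gene set among differentially
# expressed genes, by one-sided hypergeometric overlap test.

#' Hypergeometric over-representation test
#'
#' With universe size `N`, reference-set size `K` (after intersecting the
#' reference set with the universe), DE-set size `n`, and overlap `k`, the
#' upper-tail p-value is `P(X >= k)` for `X ~ Hypergeom(N, K, n)`. The DE
#' genes must be a subset of the universe.
#'
#' @param de_genes character vector of differentially expressed genes.
#' @param reference_set character vector, the published gene set.
#' @param universe character vector of all genes measured in the
#'   comparison.
#' @param direction optional label (`"up"`/`"down"`) recording which DE
#'   direction was tested; informational only.
#' @return list of class `enrichment_result`: `N`, `K`, `n`, `k`, `p`,
#'   `direction`, `overlap_genes`.
#' @export
overlap_test <- function(de_genes, reference_set, universe,
                         direction = NA_character_) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  de_genes <- unique(as.character(de_genes))
  out_of_univ <- setdiff(de_genes, universe)
  if (length(out_of_univ))
    stop("DE genes outside the universe: ",
         paste(utils::head(out_of_univ, 5), collapse = ", "))
  ref <- intersect(unique(as.character(reference_set)), universe)
  N <- length(universe); K <- length(ref); n <- length(de_genes)
  overlap <- intersect(de_genes, ref)
  k <- length(overlap)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p = p,
                 direction = direction, overlap_genes = overlap),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> overlap %d of %d DE genes with set of %d (universe %d): p = %.3g%s\n",
    x$k, x$n, x$K, x$N, x$p,
    if (is.na(x$direction)) "" else paste0(" [", x$direction, " in RL]")))
  invisible(x)
}
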