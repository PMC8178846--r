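# Shared domain containers and plain-text readers/writers.
#
# All expression values are assumed to be on the log2 scale and fully
# observed; missing or non-finite entries are rejected at load time.

VALID_GROUPS <- c("PT", "RL", "RT", "RS")
VALID_ENDPOINTS <- c("RFS", "DMFS", "DSS")

#' Construct an expression matrix with per-sample annotations
#'
#' The central expression container: a numeric genes x samples matrix on the
#' log2 scale plus a per-sample annotation table. Annotations carry the
#' mouse-model identity (`model_id`), the cell-state group (`PT` primary
#' tumor, `RL` residual lesion, `RT` recurrent tumor, `RS` recurrent stroma),
#' and/or a patient-cohort identifier (`cohort_id`).
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param annotations data.frame with column `sample_id` and any of
#'   `model_id`, `group`, `cohort_id`. Every column of `values` must have a
#'   matching row; extra annotation rows are an error.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `annotations` (annotations reordered to match the columns).
#' @export
expr_matrix <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("expression values must be finite; missing entries are not allowed")
  if (!is.data.frame(annotations) || is.null(annotations$sample_id))
    stop("`annotations` must be a data.frame with a sample_id column")
  for (col in c("model_id", "group", "cohort_id"))
    if (is.null(annotations[[col]])) annotations[[col]] <- NA_character_
  orphans_m <- setdiff(colnames(values), annotations$sample_id)
  if (length(orphans_m))
    stop("samples without annotation: ", paste(orphans_m, collapse = ", "))
  orphans_a <- setdiff(annotations$sample_id, colnames(values))
  if (length(orphans_a))
    stop("annotation rows without matching sample: ",
         paste(orphans_a, collapse = ", "))
  bad_grp <- annotations$group[!is.na(annotations$group) &
                                 !annotations$group %in% VALID_GROUPS]
  if (length(bad_grp))
    stop("invalid group label(s): ", paste(unique(bad_grp), collapse = ", "))
  no_anno <- is.na(annotations$group) & is.na(annotations$cohort_id)
  if (any(no_anno))
    stop("samples carry neither a group nor a cohort annotation: ",
         paste(annotations$sample_id[no_anno], collapse = ", "))
  annotations <- annotations[match(colnames(values), annotations$sample_id),
                             c("sample_id", "model_id", "group", "cohort_id"),
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(values = values, annotations = annotations),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  grp <- table(x$annotations$group, useNA = "no")
  if (length(grp))
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = " "), "\n")
  coh <- unique(stats::na.omit(x$annotations$cohort_id))
  if (length(coh)) cat("  cohorts:", length(coh), "\n")
  invisible(x)
}

#' Read a tab-delimited expression matrix plus sample annotations
#'
#' The matrix file has a header row of sample ids and gene ids in the first
#' column. Duplicate gene ids are collapsed by averaging their rows on the
#' log2 scale (with a warning); non-numeric cells are an error naming the
#' offending gene and sample. The annotation file is tab-delimited with a
#' header and must contain `sample_id`; samples lacking an annotation row
#' are rejected.
#'
#' @param path expression matrix file.
#' @param annotation_path sample annotation file.
#' @return [expr_matrix()]
#' @export
read_expression <- function(path, annotation_path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2) stop("expression file needs gene id column plus samples")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' for gene '%s', sample '%s'",
                   col[bad[1]], gene_ids[bad[1]], sample_ids[j]))
    vals[, j] <- num
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warning("collapsing ", length(dups),
            " duplicated gene id(s) by mean: ",
            paste(utils::head(dups, 5), collapse = ", "),
            if (length(dups) > 5) ", ..." else "")
    vals <- rowsum(vals, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    rownames(vals) <- unique(gene_ids)
  } else {
    rownames(vals) <- gene_ids
  }
  anno <- utils::read.delim(annotation_path, header = TRUE,
                            colClasses = "character", check.names = FALSE)
  if (is.null(anno$sample_id)) stop("annotation file lacks sample_id column")
  anno[anno == ""] <- NA
  expr_matrix(vals, anno)
}

#' Write an expression matrix and its annotations to tab-delimited files
#'
#' Inverse of [read_expression()]; round-trips are lossless up to numeric
#' printing precision (15 significant digits are written).
#'
#' @param x an `expr_matrix`.
#' @param path,annotation_path output files.
#' @export
write_expression <- function(x, path, annotation_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values),
                   format(x$values, digits = 15, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(x)
}

#' Construct a per-cohort clinical survival table
#'
#' @param patient_id unique patient identifiers.
#' @param time_months nonnegative follow-up times in months.
#' @param event 0/1 event indicator (1 = relapse/death observed).
#' @param endpoint endpoint type, one of `RFS`, `DMFS`, `DSS`; a cohort has
#'   exactly one endpoint.
#' @param cohort_id cohort identifier (scalar or per-patient, must be
#'   constant).
#' @return data.frame of class `cohort_survival`.
#' @export
cohort_survival <- function(patient_id, time_months, event,
                            endpoint = "RFS", cohort_id = "cohort1") {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicate patient ids")
  time_months <- as.numeric(time_months)
  if (any(!is.finite(time_months)) || any(time_months < 0))
    stop("time_months must be finite and >= 0")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  endpoint <- unique(as.character(endpoint))
  if (length(endpoint) != 1L || !endpoint %in% VALID_ENDPOINTS)
    stop("a cohort has one endpoint, one of ",
         paste(VALID_ENDPOINTS, collapse = "/"))
  cohort_id <- unique(as.character(cohort_id))
  if (length(cohort_id) != 1L) stop("cohort_id must be a single value")
  out <- data.frame(patient_id = patient_id, time_months = time_months,
                    event = event, endpoint = endpoint,
                    cohort_id = cohort_id, stringsAsFactors = FALSE)
  class(out) <- c("cohort_survival", "data.frame")
  out
}

#' Read a tab-delimited clinical table
#'
#' Expected columns: `patient_id`, `time_months`, `event`, `endpoint`, and
#' optionally `cohort_id` (defaulting to the file's basename).
#'
#' @param path clinical table file.
#' @return [cohort_survival()]
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event", "endpoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "))
  cid <- if (!is.null(df$cohort_id)) df$cohort_id else
    sub("\\.[^.]*$", "", basename(path))
  cohort_survival(df$patient_id, df$time_months, df$event, df$endpoint, cid)
}

#' Write a clinical table
#' @param x a `cohort_survival`.
#' @param path output file.
#' @export
write_clinical <- function(x, path) {
  stopifnot(inherits(x, "cohort_survival"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Construct a signed gene signature
#'
#' A signature is a list of (gene, weight) pairs. Direction-only signatures
#' (the dormancy signature) use weights +1/-1; weighted signatures (the
#' proliferation signature) use real nonzero weights such as log
#' fold-changes.
#'
#' @param gene_id unique gene identifiers.
#' @param weight nonzero real weights, recycled if scalar.
#' @param name signature name.
#' @param provenance free-text provenance string.
#' @return data.frame of class `gene_signature` with attributes `name` and
#'   `provenance`.
#' @export
gene_signature <- function(gene_id, weight = 1, name = "signature",
                           provenance = "") {
  gene_id <- as.character(gene_id)
  if (length(gene_id) == 0L) stop("signature has no genes")
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in signature")
  weight <- rep_len(as.numeric(weight), length(gene_id))
  if (any(!is.finite(weight)) || any(weight == 0))
    stop("weights must be finite and nonzero")
  out <- data.frame(gene_id = gene_id, weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- as.character(name)
  attr(out, "provenance") <- as.character(provenance)
  class(out) <- c("gene_signature", "data.frame")
  out
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s': %d genes (%d up, %d down)\n",
              attr(x, "name"), nrow(x), sum(x$weight > 0),
              sum(x$weight < 0)))
  invisible(x)
}

#' Read signed gene signatures from a GMT file
#'
#' GMT dialect: one signature per line, tab-separated fields
#' `name  description  GENE1  GENE2:w2 ...`. A bare token gets weight +1; a
#' `GENE:w` token is split on its last colon, and `w` must parse as a
#' nonzero real. Lines with no gene tokens are an error.
#'
#' @param path GMT file.
#' @return named list of [gene_signature()] objects.
#' @export
read_signature_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d ('%s'): no genes", i, f[1]))
    toks <- f[-(1:2)]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) stop(sprintf("GMT line %d ('%s'): no genes", i, f[1]))
    has_w <- grepl(":", toks, fixed = TRUE)
    gene <- ifelse(has_w, sub(":[^:]*$", "", toks), toks)
    wtok <- ifelse(has_w, sub("^.*:", "", toks), "1")
    w <- suppressWarnings(as.numeric(wtok))
    if (any(is.na(w)))
      stop(sprintf("GMT line %d: non-numeric weight in token '%s'",
                   i, toks[which(is.na(w))[1]]))
    gene_signature(gene, w, name = f[1], provenance = f[2])
  })
  names(sigs) <- vapply(sigs, attr, "", "name")
  sigs
}

#' Write gene signatures to a GMT file
#'
#' Weights of exactly +1 are written as bare gene tokens; any other weight
#' is written as `GENE:w`. Round-trip through [read_signature_gmt()]
#' preserves entries and order.
#'
#' @param sigs a `gene_signature` or list of them.
#' @param path output file.
#' @export
write_signature_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s) {
    toks <- ifelse(s$weight == 1, s$gene_id,
                   paste0(s$gene_id, ":",
                          format(s$weight, digits = 15, trim = TRUE)))
    paste(c(attr(s, "name"), attr(s, "provenance"), toks), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sigs)
}

#' Restrict a signature to the genes measured in each cohort
#'
#' Different microarray platforms measure different gene universes; before
#' scoring, the signature is intersected with each cohort's measured genes,
#' preserving weights, and the coverage fraction is reported. A cohort
#' measuring none of the signature genes is an error.
#'
#' @param cohorts list of `expr_matrix` (one per cohort).
#' @param signature a `gene_signature`.
#' @return named list per cohort with elements `signature` (restricted) and
#'   `coverage` (fraction of signature genes measured).
#' @export
harmonize <- function(cohorts, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  if (inherits(cohorts, "expr_matrix")) cohorts <- list(cohorts)
  nm <- names(cohorts)
  if (is.null(nm)) nm <- paste0("cohort", seq_along(cohorts))
  out <- lapply(seq_along(cohorts), function(i) {
    keep <- signature$gene_id %in% rownames(cohorts[[i]]$values)
    if (!any(keep))
      stop("cohort '", nm[i], "' measures no signature gene")
    restricted <- gene_signature(signature$gene_id[keep],
                                 signature$weight[keep],
                                 name = attr(signature, "name"),
                                 provenance = attr(signature, "provenance"))
    list(signature = restricted, coverage = mean(keep))
  })
  names(out) <- nm
  out
}
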