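#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2-scale intensities
#' with genes as rows (unique rownames) and samples as columns (unique
#' colnames). Values are assumed already normalized and log2-transformed;
#' the only numeric check performed here is finiteness.
#'
#' @param x numeric matrix, genes x samples.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicated gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicated sample IDs: ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample IDs, a first column named `gene_id`
#' holding gene identifiers, and a numeric body of log2-scale intensities.
#' Row and column order are preserved.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, genes x samples, validated by
#'   [validate_expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("expression TSV needs a gene_id column plus samples")
  gene_ids <- tab[[1L]]
  body <- tab[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(gene_ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   body[[j]][bad[1L]], gene_ids[bad[1L]], colnames(body)[j]))
    vals[, j] <- v
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' @param x numeric matrix, genes x samples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  tab <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sex_tokens <- c("male", "female")
genotype_tokens <- c("control_het", "germ_ablated", "smad4_ko", "dko", "other")

#' Validate a sample design table
#'
#' A design is a data.frame with one row per sample and columns
#' `sample_id`, `sex` (male/female), `genotype` (control_het, germ_ablated,
#' smad4_ko, dko, other), `stage` (free label, e.g. "E13.5"), and
#' `replicate` (positive integer). When `expr` is given, every sample
#' column of the matrix must have exactly one design row.
#'
#' @param design data.frame as above.
#' @param expr optional companion expression matrix to pair against.
#' @return `design`, invisibly.
#' @export
validate_design <- function(design, expr = NULL) {
  need <- c("sample_id", "sex", "genotype", "stage", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design")
  bad_sex <- setdiff(unique(design$sex), sex_tokens)
  if (length(bad_sex))
    stop("unknown sex token(s) ", paste(bad_sex, collapse = ", "),
         "; allowed: ", paste(sex_tokens, collapse = ", "))
  bad_gt <- setdiff(unique(design$genotype), genotype_tokens)
  if (length(bad_gt))
    stop("unknown genotype token(s) ", paste(bad_gt, collapse = ", "),
         "; allowed: ", paste(genotype_tokens, collapse = ", "))
  rep_num <- suppressWarnings(as.numeric(design$replicate))
  if (any(is.na(rep_num)) || any(rep_num < 1) || any(rep_num != round(rep_num)))
    stop("replicate must be a positive integer")
  if (!is.null(expr)) {
    unmatched <- setdiff(colnames(expr), design$sample_id)
    if (length(unmatched))
      stop("samples in matrix missing from design: ",
           paste(unmatched, collapse = ", "))
  }
  invisible(design)
}

#' Read a sample design table from TSV
#'
#' @param path TSV with columns sample_id, sex, genotype, stage, replicate.
#' @return validated data.frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  design <- utils::read.delim(path, check.names = FALSE,
                              colClasses = "character")
  validate_design(design)
  design$replicate <- as.integer(design$replicate)
  design
}

#' Write a sample design table to TSV
#'
#' @param design validated design data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Sample IDs belonging to one (sex, genotype) group, in matrix column order.
design_samples <- function(design, group, expr = NULL) {
  stopifnot(length(group) == 2L)
  ids <- design$sample_id[design$sex == group[[1L]] &
                          design$genotype == group[[2L]]]
  if (!is.null(expr)) ids <- intersect(colnames(expr), ids)
  ids
}

group_label <- function(group) paste(group[[1L]], group[[2L]], sep = ".")
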