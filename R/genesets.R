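gene_classes <- c("male_germ", "female_germ", "male_soma", "female_soma",
                  "unclassified")

#' Construct a gene-set table
#'
#' A gene-set table is a partition of the gene universe into the four
#' compartment-specific classes (male_germ, female_germ, male_soma,
#' female_soma) plus unclassified, with a free-text provenance note per
#' gene recording which contrasts assigned it.
#'
#' @param gene_id character vector of unique gene IDs.
#' @param class character vector, one of the five class tokens per gene.
#' @param provenance optional character vector of same length.
#' @return data.frame of class `gene_set_table`.
#' @export
gene_set_table <- function(gene_id, class, provenance = NA_character_) {
  if (anyDuplicated(gene_id)) stop("duplicated gene_id in gene-set table")
  bad <- setdiff(unique(class), gene_classes)
  if (length(bad))
    stop("unknown class token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(gene_classes, collapse = ", "))
  out <- data.frame(gene_id = as.character(gene_id),
                    class = as.character(class),
                    provenance = provenance,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_set_table", "data.frame")
  out
}

#' Genes belonging to one class of a gene-set table
#'
#' @param sets a `gene_set_table`.
#' @param cls one of the five class tokens, or a vector of them.
#' @return character vector of gene IDs.
#' @export
gene_set <- function(sets, cls) {
  bad <- setdiff(cls, gene_classes)
  if (length(bad)) stop("unknown class token(s): ", paste(bad, collapse = ", "))
  sets$gene_id[sets$class %in% cls]
}

#' Class counts of a gene-set table
#'
#' @param sets a `gene_set_table`.
#' @return named integer vector over the five classes.
#' @export
gene_set_counts <- function(sets) {
  vapply(gene_classes, function(k) sum(sets$class == k), integer(1L))
}

#' @export
print.gene_set_table <- function(x, ...) {
  cat("gene_set_table:", nrow(x), "genes\n")
  print(gene_set_counts(x))
  invisible(x)
}

#' Write gene sets as a long-format TSV
#'
#' Two columns, gene_id and class; one row per gene (the partition view).
#'
#' @param sets a `gene_set_table`.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  utils::write.table(sets[, c("gene_id", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from the long-format TSV
#'
#' @param path TSV with columns gene_id, class.
#' @return a `gene_set_table`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, colClasses = "character")
  gene_set_table(tab$gene_id, tab$class)
}

#' Write the four specific classes in GMT format
#'
#' One line per class: set name, a description, then the tab-separated
#' member gene IDs. Unclassified genes are not emitted.
#'
#' @param sets a `gene_set_table`.
#' @param path output path.
#' @param description one-line description reused for every set.
#' @export
write_gmt <- function(sets, path, description = "compartment-specific genes") {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in setdiff(gene_classes, "unclassified")) {
    members <- gene_set(sets, k)
    writeLines(paste(c(k, description, members), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GMT file into a named list of gene-ID vectors
#'
#' @param path GMT file (set name, description, members per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  out
}
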