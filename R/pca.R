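#' Subset-restricted principal component analysis
#'
#' PCA of the samples over a chosen gene subset. Genes are mean-centered
#' across samples (no variance scaling by default) and components come
#' from the singular value decomposition of the centered sample x gene
#' matrix. Per-gene factor loadings are reported as the Pearson
#' correlation between the gene's values across samples and the component
#' scores — bounded in [-1, 1], unlike raw rotation entries — with 0 for
#' zero-variance genes. PC1's sign is oriented so that the mean PC1 score
#' of the `orient_ref` group is positive, making the axis direction
#' reproducible.
#'
#' @param expr log2 expression matrix.
#' @param design companion design data.frame.
#' @param gene_subset character vector of genes to restrict to.
#' @param orient_ref `c(sex, genotype)` group whose mean PC1 score is made
#'   positive; must be present among the used samples.
#' @param groups optional list of `c(sex, genotype)` pairs restricting
#'   which samples enter the PCA (default: all matrix columns).
#' @param scale_genes logical; also scale genes to unit variance
#'   (default FALSE, centering only).
#' @return a `subset_pca` list: `scores` (samples x components),
#'   `loadings` (genes x components, correlation scale), `percent_var`,
#'   `sdev`, `samples`, `orient_ref`.
#' @export
run_subset_pca <- function(expr, design, gene_subset, orient_ref,
                           groups = NULL, scale_genes = FALSE) {
  validate_expression_matrix(expr)
  validate_design(design, expr)
  if (!length(gene_subset)) stop("gene_subset must be non-empty")
  absent <- setdiff(gene_subset, rownames(expr))
  if (length(absent))
    stop("subset gene(s) absent from matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  samples <- colnames(expr)
  if (!is.null(groups)) {
    samples <- unlist(lapply(groups, design_samples, design = design,
                             expr = expr))
    samples <- intersect(colnames(expr), samples)
  }
  if (length(samples) < 3L) stop("PCA needs at least 3 samples")
  x <- t(expr[gene_subset, samples, drop = FALSE])  # samples x genes
  gene_var <- apply(x, 2L, stats::var)
  if (all(gene_var == 0))
    stop("all genes in the subset have zero variance across samples")
  if (scale_genes && any(gene_var == 0))
    stop("cannot unit-scale zero-variance genes")
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_genes)
  k <- min(length(samples) - 1L, length(gene_subset))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  lambda <- pc$sdev[seq_len(k)] ^ 2
  percent_var <- 100 * lambda / sum(lambda)

  ref_samples <- intersect(samples, design_samples(design, orient_ref))
  if (!length(ref_samples))
    stop("orientation group ", group_label(orient_ref),
         " has no samples in the PCA")
  flip <- mean(scores[ref_samples, 1L]) < 0

  loadings <- suppressWarnings(stats::cor(x, scores))
  loadings[gene_var == 0, ] <- 0
  if (flip) {
    scores[, 1L] <- -scores[, 1L]
    loadings[, 1L] <- -loadings[, 1L]
  }
  structure(list(scores = scores, loadings = loadings,
                 percent_var = percent_var, sdev = sqrt(lambda),
                 samples = samples, orient_ref = group_label(orient_ref)),
            class = "subset_pca")
}

#' @export
print.subset_pca <- function(x, ...) {
  cat("subset PCA:", nrow(x$loadings), "genes,", nrow(x$scores),
      "samples\n")
  pv <- x$percent_var[seq_len(min(3L, length(x$percent_var)))]
  cat("percent variance:", paste(sprintf("PC%d %.1f%%", seq_along(pv), pv),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Mean PC1 score of a design group
#'
#' @param pca a `subset_pca`.
#' @param design the design used to build it.
#' @param group `c(sex, genotype)`.
#' @return mean PC1 score over the group's samples in the PCA.
#' @export
pc1_group_mean <- function(pca, design, group) {
  ids <- intersect(pca$samples, design_samples(design, group))
  if (!length(ids)) stop("group ", group_label(group), " not in the PCA")
  mean(pca$scores[ids, 1L])
}

#' Germ-vs-soma contribution test on PC1 loadings
#'
#' Compares the absolute PC1 factor loadings of the pooled germ-specific
#' genes (male_germ + female_germ) against the pooled somatic-specific
#' genes (male_soma + female_soma) with a two-sided Wilcoxon rank-sum
#' test. A group whose genes track PC1 tightly has |loadings| near 1; a
#' small p-value means the two compartments contribute unequally to the
#' axis.
#'
#' @param pca a `subset_pca` whose gene universe contains both groups.
#' @param gene_sets a [gene_set_table()].
#' @return a `contribution_test` list: medians of |PC1 loading| per group,
#'   rank-sum statistic, two-sided p-value, group sizes.
#' @export
contribution_test <- function(pca, gene_sets) {
  stopifnot(inherits(pca, "subset_pca"))
  universe <- rownames(pca$loadings)
  germ <- intersect(universe, gene_set(gene_sets,
                                       c("male_germ", "female_germ")))
  soma <- intersect(universe, gene_set(gene_sets,
                                       c("male_soma", "female_soma")))
  if (length(germ) < 2L || length(soma) < 2L)
    stop("both germ and soma groups need at least 2 genes in the PCA")
  g <- abs(pca$loadings[germ, 1L])
  s <- abs(pca$loadings[soma, 1L])
  wt <- suppressWarnings(stats::wilcox.test(g, s, alternative = "two.sided"))
  structure(list(median_abs_germ = stats::median(g),
                 median_abs_soma = stats::median(s),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n_germ = length(germ), n_soma = length(soma)),
            class = "contribution_test")
}

#' @export
print.contribution_test <- function(x, ...) {
  cat(sprintf(paste0("germ |PC1 loading| median %.3f (n=%d) vs ",
                     "soma %.3f (n=%d)\n"),
              x$median_abs_germ, x$n_germ, x$median_abs_soma, x$n_soma))
  cat(sprintf("rank-sum W = %.1f, two-sided p = %.3g\n",
              x$statistic, x$p_value))
  invisible(x)
}
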