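# Shared fixtures built in code.

# Small simulator config: full condition panel, modest gene counts.
tiny_config <- function(...) {
  args <- list(n_male_germ = 20L, n_female_germ = 18L, n_male_soma = 25L,
               n_female_soma = 22L, n_background = 60L, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Deterministic toy matrix: two groups of two replicates, no spread.
# Log2 group means per gene are given explicitly.
toy_matrix <- function(means_a, means_b, genes = NULL) {
  n <- length(means_a)
  stopifnot(length(means_b) == n)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(n))
  m <- cbind(a1 = means_a, a2 = means_a, b1 = means_b, b2 = means_b)
  rownames(m) <- genes
  m
}

toy_design <- function(group_a = c("male", "control_het"),
                       group_b = c("female", "control_het")) {
  data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    sex = c(group_a[1], group_a[1], group_b[1], group_b[1]),
    genotype = c(group_a[2], group_a[2], group_b[2], group_b[2]),
    stage = "E13.5",
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
}

# A fold_change object assembled directly (for shift/quadrant tests).
make_fc <- function(lfc, genes = names(lfc)) {
  structure(stats::setNames(as.numeric(lfc), genes),
            group_a = "x.a", group_b = "x.b",
            class = c("fold_change", "numeric"))
}

# A minimal subset_pca carrying given PC1 loadings (for contribution tests).
make_pca_loadings <- function(loadings) {
  structure(list(scores = NULL,
                 loadings = matrix(loadings, ncol = 1L,
                                   dimnames = list(names(loadings), "PC1")),
                 percent_var = 100, sdev = 1, samples = character(),
                 orient_ref = "male.control_het"),
            class = "subset_pca")
}
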