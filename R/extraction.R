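#' Extraction configuration
#'
#' Parameters of the double fold-change gene-set extraction rule.
#'
#' @param fold_threshold linear-scale ratio a gene must reach to count as
#'   specific (default 1.5); must exceed 1.
#' @param inclusive logical; whether the comparison is `>=` (default) or
#'   strictly `>`.
#' @param germ_rule "matching" (default) evaluates the germ-presence
#'   contrast only in the gene's specific sex; "both" requires it in both
#'   sexes (intersection of the testis and ovary het-vs-ablated lists).
#' @return a validated `extraction_config` list.
#' @export
extraction_config <- function(fold_threshold = 1.5, inclusive = TRUE,
                              germ_rule = c("matching", "both")) {
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  cfg <- list(fold_threshold = fold_threshold,
              inclusive = isTRUE(inclusive),
              germ_rule = match.arg(germ_rule))
  class(cfg) <- "extraction_config"
  cfg
}

# Threshold comparison on the log2 scale. The 1e-12 guard keeps a gene
# sitting exactly on the cut from flipping sides through representation
# error of log2(); it is far below any biologically meaningful margin.
clears_cut <- function(lfc, cut, inclusive) {
  if (inclusive) lfc >= cut - 1e-12 else lfc > cut + 1e-12
}

# Gene IDs whose lfc clears +log2(fold_threshold).
passes_up <- function(lfc, cfg) {
  names(lfc)[clears_cut(lfc, log2(cfg$fold_threshold), cfg$inclusive)]
}

#' Sex-specific gene sets from the control contrast
#'
#' Genes at least `fold_threshold`-fold higher in control testes than in
#' control ovaries (linear-scale group means) are male-specific; the
#' reciprocal contrast gives female-specific genes. The two sets are
#' disjoint by construction (the threshold exceeds 1).
#'
#' @param expr log2 expression matrix.
#' @param design companion design; must contain `control_het` samples of
#'   both sexes.
#' @param cfg an [extraction_config()].
#' @return list with character vectors `male_specific`, `female_specific`.
#' @export
derive_sex_specific <- function(expr, design, cfg = extraction_config()) {
  stopifnot(inherits(cfg, "extraction_config"))
  for (grp in list(c("male", "control_het"), c("female", "control_het")))
    if (!length(design_samples(design, grp, expr)))
      stop("design lacks samples for group ", group_label(grp))
  fc <- log2_fold_change(expr, design,
                         c("male", "control_het"), c("female", "control_het"))
  list(male_specific = passes_up(fc, cfg),
       female_specific = passes_up(-fc, cfg))
}

#' Germ-cell-specific gene sets via the ablation contrast
#'
#' Intersects the sex-specific sets with genes at least
#' `fold_threshold`-fold higher in normal (het) gonads than in
#' germ-cell-ablated gonads — expression lost when germ cells are absent
#' is attributed to the germ compartment. By default the ablation
#' contrast is evaluated in the gene's own sex only (a male-specific gene
#' is near-absent in ovaries, so the ovary contrast is uninformative);
#' `germ_rule = "both"` additionally requires the other sex's contrast.
#'
#' @param expr log2 expression matrix.
#' @param design companion design; must contain `germ_ablated` samples of
#'   both sexes.
#' @param sex_sets output of [derive_sex_specific()].
#' @param cfg an [extraction_config()].
#' @return list with character vectors `male_germ`, `female_germ`.
#' @export
derive_germ_specific <- function(expr, design, sex_sets,
                                 cfg = extraction_config()) {
  stopifnot(inherits(cfg, "extraction_config"))
  for (grp in list(c("male", "germ_ablated"), c("female", "germ_ablated")))
    if (!length(design_samples(design, grp, expr)))
      stop("design lacks samples for group ", group_label(grp))
  germ_m <- passes_up(log2_fold_change(expr, design,
                                       c("male", "control_het"),
                                       c("male", "germ_ablated")), cfg)
  germ_f <- passes_up(log2_fold_change(expr, design,
                                       c("female", "control_het"),
                                       c("female", "germ_ablated")), cfg)
  if (cfg$germ_rule == "both") {
    both <- intersect(germ_m, germ_f)
    germ_m <- both
    germ_f <- both
  }
  list(male_germ = intersect(sex_sets$male_specific, germ_m),
       female_germ = intersect(sex_sets$female_specific, germ_f))
}

#' Partition genes into compartment-specific classes
#'
#' Somatic-specific genes are the sex-specific genes that are not
#' germ-cell-specific; everything else is unclassified. The output is a
#' partition of the matrix's gene universe.
#'
#' @param gene_ids full gene universe (matrix rownames).
#' @param sex_sets output of [derive_sex_specific()].
#' @param germ_sets output of [derive_germ_specific()].
#' @return a [gene_set_table()].
#' @export
partition_compartment_sets <- function(gene_ids, sex_sets, germ_sets) {
  if (length(setdiff(germ_sets$male_germ, sex_sets$male_specific)) ||
      length(setdiff(germ_sets$female_germ, sex_sets$female_specific)))
    stop("internal inconsistency: germ set not a subset of its sex set")
  stray <- setdiff(c(sex_sets$male_specific, sex_sets$female_specific),
                   gene_ids)
  if (length(stray))
    stop("sex-specific genes absent from the gene universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  cls <- rep("unclassified", length(gene_ids))
  names(cls) <- gene_ids
  cls[sex_sets$male_specific] <- "male_soma"
  cls[sex_sets$female_specific] <- "female_soma"
  cls[germ_sets$male_germ] <- "male_germ"
  cls[germ_sets$female_germ] <- "female_germ"
  prov <- ifelse(cls == "unclassified", "no contrast passed",
                 "sex contrast + ablation contrast")
  gene_set_table(gene_ids, unname(cls), prov)
}

#' Full gene-set extraction
#'
#' Runs [derive_sex_specific()], [derive_germ_specific()] and
#' [partition_compartment_sets()] in sequence.
#'
#' @inheritParams derive_sex_specific
#' @return a [gene_set_table()] over all genes of `expr`.
#' @examples
#' sim <- simulate_gonad_expression(sim_config(noise_sd = 0, seed = 7))
#' sets <- derive_gene_sets(sim$expr, sim$design)
#' gene_set_counts(sets)
#' @export
derive_gene_sets <- function(expr, design, cfg = extraction_config()) {
  sex_sets <- derive_sex_specific(expr, design, cfg)
  germ_sets <- derive_germ_specific(expr, design, sex_sets, cfg)
  partition_compartment_sets(rownames(expr), sex_sets, germ_sets)
}

#' Recovery metrics of an extracted partition against planted truth
#'
#' Sensitivity is the fraction of planted specific genes (the four
#' compartment classes) assigned their planted class; precision is the
#' fraction of genes assigned to any specific class whose assignment
#' matches the planted class.
#'
#' @param sets extracted [gene_set_table()].
#' @param truth simulation `truth` (see [simulate_gonad_expression()]).
#' @return named list: sensitivity, precision, n_planted, n_called.
#' @export
recovery_metrics <- function(sets, truth) {
  planted <- truth_gene_sets(truth)
  m <- merge(planted, sets, by = "gene_id", suffixes = c("_true", "_call"))
  spec <- setdiff(gene_classes, "unclassified")
  is_planted <- m$class_true %in% spec
  is_called <- m$class_call %in% spec
  hit <- m$class_true == m$class_call
  list(sensitivity = sum(is_planted & hit) / sum(is_planted),
       precision = sum(is_called & hit) / sum(is_called),
       n_planted = sum(is_planted), n_called = sum(is_called))
}
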