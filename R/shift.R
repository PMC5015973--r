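#' Quadrant classification of genes by two fold-change axes
#'
#' Labels every gene by where its two log2 fold changes fall relative to
#' the cut lines at +/- log2(fold_threshold): `up` / `down` / `neutral`
#' on each axis. On the scatter this pipeline targets, the y-axis is the
#' control testis-vs-ovary change (sex specificity) and the x-axis the
#' mutant-vs-control-ovary change (shift in the mutant).
#'
#' @param fc_x,fc_y `fold_change` vectors over the same gene universe.
#' @param cfg an [extraction_config()] supplying the threshold.
#' @return data.frame with columns gene_id, x, y (each up/down/neutral)
#'   and quadrant (e.g. "y_up.x_up").
#' @export
quadrant_classify <- function(fc_x, fc_y, cfg = extraction_config()) {
  stopifnot(inherits(cfg, "extraction_config"))
  if (!setequal(names(fc_x), names(fc_y)))
    stop("fc_x and fc_y must share the same gene universe")
  fc_y <- fc_y[names(fc_x)]
  cut <- log2(cfg$fold_threshold)
  axis_class <- function(v) {
    ifelse(clears_cut(v, cut, cfg$inclusive), "up",
           ifelse(clears_cut(-v, cut, cfg$inclusive), "down", "neutral"))
  }
  x <- axis_class(as.numeric(fc_x))
  y <- axis_class(as.numeric(fc_y))
  data.frame(gene_id = names(fc_x), x = x, y = y,
             quadrant = paste0("y_", y, ".x_", x),
             stringsAsFactors = FALSE)
}

#' Sex-shift fractions of compartment-specific germ genes
#'
#' Counts how many male-germ genes are at least `fold_threshold`-fold up,
#' and how many female-germ genes at least `fold_threshold`-fold down, in
#' a mutant-vs-control fold-change vector, and reports the fractions as
#' percentages (1 decimal).
#'
#' @param gene_sets a [gene_set_table()] sharing `fc_x`'s gene universe.
#' @param fc_x mutant-vs-control `fold_change` vector.
#' @param cfg an [extraction_config()].
#' @return a `shift_summary` list: n_male_total, n_male_up, pct_male_up,
#'   n_female_total, n_female_down, pct_female_down, fold_threshold.
#' @export
shift_fractions <- function(gene_sets, fc_x, cfg = extraction_config()) {
  stopifnot(inherits(cfg, "extraction_config"))
  missing_genes <- setdiff(gene_sets$gene_id, names(fc_x))
  if (length(missing_genes))
    stop("gene-set genes absent from fold-change vector: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  male <- gene_set(gene_sets, "male_germ")
  female <- gene_set(gene_sets, "female_germ")
  if (!length(male) || !length(female))
    stop("male_germ and female_germ sets must be non-empty")
  cut <- log2(cfg$fold_threshold)
  up <- clears_cut(fc_x[male], cut, cfg$inclusive)
  down <- clears_cut(-fc_x[female], cut, cfg$inclusive)
  out <- list(n_male_total = length(male), n_male_up = sum(up),
              pct_male_up = proportion_percent(sum(up), length(male), 1),
              n_female_total = length(female), n_female_down = sum(down),
              pct_female_down = proportion_percent(sum(down),
                                                   length(female), 1),
              fold_threshold = cfg$fold_threshold)
  class(out) <- "shift_summary"
  out
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("male-germ genes up   in mutant: %d/%d (%.1f%%)\n",
              x$n_male_up, x$n_male_total, x$pct_male_up))
  cat(sprintf("female-germ genes down in mutant: %d/%d (%.1f%%)\n",
              x$n_female_down, x$n_female_total, x$pct_female_down))
  cat(sprintf("fold threshold: %.2f\n", x$fold_threshold))
  invisible(x)
}
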