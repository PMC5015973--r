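#' Log2 fold change between two sample groups
#'
#' Fold change is the ratio of linear-scale group means: each log2
#' intensity is unlogged (2^x), averaged over the group's replicates, and
#' the log2 ratio of the two group means is returned. This matches the
#' "fold change in expression level" reading of a ratio of intensities,
#' not a difference of mean log values.
#'
#' @param expr numeric matrix, genes x samples, log2 scale.
#' @param design companion design data.frame (see [validate_design()]).
#' @param group_a,group_b length-2 character vectors `c(sex, genotype)`;
#'   the result is the change of A over B.
#' @return a `fold_change` object: a named numeric vector of per-gene log2
#'   fold changes, with attributes `group_a` and `group_b`.
#' @examples
#' cfg <- sim_config(n_male_germ = 5, n_female_germ = 5, n_male_soma = 5,
#'                   n_female_soma = 5, n_background = 10, noise_sd = 0)
#' sim <- simulate_gonad_expression(cfg)
#' fc <- log2_fold_change(sim$expr, sim$design,
#'                        c("male", "control_het"), c("female", "control_het"))
#' head(fc)
#' @export
log2_fold_change <- function(expr, design, group_a, group_b) {
  validate_expression_matrix(expr)
  validate_design(design, expr)
  sa <- design_samples(design, group_a, expr)
  sb <- design_samples(design, group_b, expr)
  if (!length(sa)) stop("empty group: ", group_label(group_a))
  if (!length(sb)) stop("empty group: ", group_label(group_b))
  if (length(intersect(sa, sb)))
    stop("groups overlap: ", paste(intersect(sa, sb), collapse = ", "))
  lfc <- log2(rowMeans(2 ^ expr[, sa, drop = FALSE])) -
         log2(rowMeans(2 ^ expr[, sb, drop = FALSE]))
  structure(lfc,
            group_a = group_label(group_a),
            group_b = group_label(group_b),
            class = c("fold_change", "numeric"))
}

#' Report a count as a percentage
#'
#' The count-to-percent convention used throughout the results tables:
#' 100 * count / total, rounded half-away-from-zero to `decimals` places
#' (so 43/104 prints as 41.3, 20/104 as 19.2).
#'
#' @param count non-negative integer, at most `total`.
#' @param total positive integer.
#' @param decimals non-negative integer number of decimal places (default 1).
#' @return the rounded percentage as a plain number.
#' @examples
#' proportion_percent(20, 104)       # 19.2
#' proportion_percent(302, 431, 0)   # 70
#' @export
proportion_percent <- function(count, total, decimals = 1) {
  if (length(count) != 1L || length(total) != 1L || length(decimals) != 1L)
    stop("count, total and decimals must be scalars")
  if (is.na(count) || is.na(total) || count != round(count) ||
      total != round(total))
    stop("count and total must be integers")
  if (total <= 0) stop("total must be positive")
  if (count < 0 || count > total)
    stop("count must lie in [0, total]")
  if (decimals < 0 || decimals != round(decimals))
    stop("decimals must be a non-negative integer")
  round_half_away(100 * count / total, decimals)
}

# Half-away-from-zero rounding (base round() is half-to-even). The 1e-9
# guard absorbs binary representation error in 100*count/total without
# moving any genuinely sub-half value across the boundary.
round_half_away <- function(x, digits) {
  p <- 10 ^ digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
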