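#' Simulator configuration
#'
#' Parameters of the two-compartment gonad expression simulator. Defaults
#' mirror the study conditions the pipeline targets: gene-set sizes of
#' 386/360 germ-specific and 680/636 soma-specific genes per sex, three
#' replicates per condition, a conditional-KO recombination efficiency of
#' 0.80, and double-knockout penetrances of 0.521 (male-germ genes
#' activated) and 0.711 (female-germ genes silenced).
#'
#' @param n_male_germ,n_female_germ,n_male_soma,n_female_soma,n_background
#'   planted gene counts per class.
#' @param spec_fold linear-scale elevation of a specific gene in its home
#'   (sex, compartment) over everywhere else; must exceed 1.
#' @param baseline_log2 background mean log2 intensity.
#' @param noise_sd replicate-level additive log2 noise s.d. (multiplicative
#'   on intensities).
#' @param germ_fraction fraction of tissue signal contributed by the germ
#'   compartment in germ-containing gonads.
#' @param germ_fraction_jitter s.d. of per-sample Gaussian jitter on
#'   `germ_fraction` (clamped to [0, 1]); 0 disables it.
#' @param ko_efficiency fraction of germ cells recombined in conditional-KO
#'   conditions (Cre mosaicism).
#' @param p_up_male fraction of male-germ genes that activate in DKO germ
#'   cells.
#' @param p_down_female fraction of female-germ genes that deactivate in
#'   DKO germ cells.
#' @param n_reps replicates per condition.
#' @param conditions list of `c(sex, genotype)` pairs to emit.
#' @param seed RNG seed making the simulation reproducible.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_male_germ = 386L, n_female_germ = 360L,
                       n_male_soma = 680L, n_female_soma = 636L,
                       n_background = 2000L,
                       spec_fold = 4.0, baseline_log2 = 8.0,
                       noise_sd = 0.25,
                       germ_fraction = 0.3, germ_fraction_jitter = 0,
                       ko_efficiency = 0.80,
                       p_up_male = 0.521, p_down_female = 0.711,
                       n_reps = 3L,
                       conditions = default_conditions(),
                       seed = 1L) {
  cfg <- list(n_male_germ = as.integer(n_male_germ),
              n_female_germ = as.integer(n_female_germ),
              n_male_soma = as.integer(n_male_soma),
              n_female_soma = as.integer(n_female_soma),
              n_background = as.integer(n_background),
              spec_fold = spec_fold, baseline_log2 = baseline_log2,
              noise_sd = noise_sd,
              germ_fraction = germ_fraction,
              germ_fraction_jitter = germ_fraction_jitter,
              ko_efficiency = ko_efficiency,
              p_up_male = p_up_male, p_down_female = p_down_female,
              n_reps = as.integer(n_reps),
              conditions = conditions, seed = as.integer(seed))
  counts <- unlist(cfg[1:5])
  if (any(counts < 0)) stop("gene counts must be non-negative")
  fr <- c(cfg$germ_fraction, cfg$ko_efficiency, cfg$p_up_male,
          cfg$p_down_female)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$spec_fold <= 1) stop("spec_fold must exceed 1")
  if (cfg$noise_sd < 0 || cfg$germ_fraction_jitter < 0)
    stop("noise parameters must be non-negative")
  if (cfg$n_reps < 1L) stop("n_reps must be at least 1")
  if (!length(cfg$conditions)) stop("conditions list must be non-empty")
  for (cond in cfg$conditions) {
    if (length(cond) != 2L || !(cond[[1L]] %in% sex_tokens) ||
        !(cond[[2L]] %in% genotype_tokens))
      stop("each condition must be c(sex, genotype) with known tokens")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default simulated conditions
#'
#' Control testes and ovaries, germ-cell-ablated testes and ovaries (the
#' subtraction controls for gene-set extraction), conditional single-KO
#' ovaries, and double-KO ovaries.
#'
#' @return list of `c(sex, genotype)` pairs.
#' @export
default_conditions <- function() {
  list(c("male", "control_het"), c("female", "control_het"),
       c("male", "germ_ablated"), c("female", "germ_ablated"),
       c("female", "smad4_ko"), c("female", "dko"))
}

#' Default simulator configuration
#'
#' @return the `sim_config` with all defaults.
#' @export
default_config <- function() sim_config()

# Stage labels: extraction-era conditions are E13.5, mutant-era ovaries
# E14.5 (the mutant timepoint developmentally matched to E13.5 controls).
condition_stage <- function(genotype) {
  if (genotype %in% c("smad4_ko", "dko")) "E14.5" else "E13.5"
}

#' Simulate two-compartment gonad expression
#'
#' Each gonad sample is a linear-scale mixture of a germ-cell and a
#' somatic-cell expression profile,
#' `log2(f_germ * G + (1 - f_germ) * S) + eps`, with
#' `eps ~ N(0, noise_sd^2)` per gene and replicate. A
#' (sex, compartment)-specific gene sits at `baseline * spec_fold` in its
#' home compartment-and-sex and at `baseline` elsewhere; background genes
#' sit at baseline everywhere. Condition semantics:
#'
#' * `control_het`: normal mixture for the sample's sex.
#' * `germ_ablated`: germ fraction forced to 0 (somatic profile only).
#' * `smad4_ko` ovary: the recombined germ fraction (weight
#'   `ko_efficiency`) silences female-germ genes without activating
#'   male-germ genes; the rest keeps the female germ profile.
#' * `dko` ovary: the recombined fraction expresses the male-germ profile
#'   for the male-germ genes flagged active (`p_up_male`) and silences the
#'   female-germ genes flagged inactive (`p_down_female`); the
#'   unrecombined fraction keeps the female germ profile.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (log2 matrix, genes x samples), `design`
#'   (sample design data.frame) and `truth` (planted class and DKO
#'   activation flags per gene, plus the per-sample mixing weights used).
#' @export
simulate_gonad_expression <- function(config = default_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- with(config, n_male_germ + n_female_germ + n_male_soma +
                    n_female_soma + n_background)
  if (n_total < 2L) stop("simulator needs at least 2 genes in total")

  classes <- rep(c("male_germ", "female_germ", "male_soma", "female_soma",
                   "background"),
                 times = c(config$n_male_germ, config$n_female_germ,
                           config$n_male_soma, config$n_female_soma,
                           config$n_background))
  gene_ids <- sprintf("%s_%04d", c(male_germ = "MG", female_germ = "FG",
                                   male_soma = "MS", female_soma = "FS",
                                   background = "BG")[classes],
                      stats::ave(seq_along(classes), classes, FUN = seq_along))

  base <- 2 ^ config$baseline_log2
  fold <- config$spec_fold
  level <- function(active) base * ifelse(active, fold, 1)

  germ_profile <- function(sex)
    level(classes == if (sex == "male") "male_germ" else "female_germ")
  soma_profile <- function(sex)
    level(classes == if (sex == "male") "male_soma" else "female_soma")

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  # Planted DKO germ-cell state: exactly round(p * n) genes flip.
  up_idx <- sample(which(classes == "male_germ"),
                   round(config$p_up_male * config$n_male_germ))
  down_idx <- sample(which(classes == "female_germ"),
                     round(config$p_down_female * config$n_female_germ))
  dko_active <- rep(NA, n_total)
  dko_active[classes == "male_germ"] <- FALSE
  dko_active[up_idx] <- TRUE
  dko_silenced <- rep(NA, n_total)
  dko_silenced[classes == "female_germ"] <- FALSE
  dko_silenced[down_idx] <- TRUE

  e <- config$ko_efficiency
  germ_for <- function(genotype, sex) {
    g_wt <- germ_profile(sex)
    switch(genotype,
      control_het = g_wt,
      germ_ablated = g_wt,  # unused: f_germ forced to 0
      smad4_ko = {
        g_rec <- g_wt
        g_rec[classes == "female_germ"] <- base
        e * g_rec + (1 - e) * g_wt
      },
      dko = {
        g_rec <- rep(base, n_total)
        g_rec[which(dko_active)] <- base * fold
        g_rec[classes == "female_germ" & !dko_silenced] <- base * fold
        e * g_rec + (1 - e) * g_wt
      },
      stop("unsupported genotype in simulator: ", genotype))
  }

  n_cond <- length(config$conditions)
  n_samples <- n_cond * config$n_reps
  expr <- matrix(NA_real_, n_total, n_samples)
  design <- vector("list", n_samples)
  weights <- vector("list", n_samples)
  j <- 0L
  for (cond in config$conditions) {
    sex <- cond[[1L]]; genotype <- cond[[2L]]
    f0 <- if (genotype == "germ_ablated") 0 else config$germ_fraction
    if (f0 == 0 && genotype != "germ_ablated")
      message("note: germ_fraction = 0 for germ-containing genotype ",
              genotype, "; germ signal absent")
    g <- germ_for(genotype, sex)
    s <- soma_profile(sex)
    for (r in seq_len(config$n_reps)) {
      j <- j + 1L
      f <- f0
      if (config$germ_fraction_jitter > 0 && genotype != "germ_ablated")
        f <- min(1, max(0, f0 + stats::rnorm(1L, 0,
                                             config$germ_fraction_jitter)))
      expr[, j] <- log2(f * g + (1 - f) * s) +
        stats::rnorm(n_total, 0, config$noise_sd)
      id <- sprintf("%s_%s_r%d", sex, genotype, r)
      design[[j]] <- data.frame(sample_id = id, sex = sex,
                                genotype = genotype,
                                stage = condition_stage(genotype),
                                replicate = r, stringsAsFactors = FALSE)
      weights[[j]] <- data.frame(sample_id = id, germ_fraction = f,
                                 ko_efficiency =
                                   if (genotype %in% c("smad4_ko", "dko"))
                                     e else NA_real_,
                                 stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, design)
  dimnames(expr) <- list(gene_ids, design$sample_id)
  validate_expression_matrix(expr)
  validate_design(design, expr)

  truth <- list(
    genes = data.frame(gene_id = gene_ids, class = classes,
                       dko_active = dko_active, dko_silenced = dko_silenced,
                       stringsAsFactors = FALSE),
    mixing = do.call(rbind, weights),
    config = config)
  class(truth) <- "sim_truth"
  list(expr = expr, design = design, truth = truth)
}

#' Planted gene-set table from a simulation truth
#'
#' Recasts the simulator's planted classes as a [gene_set_table()]
#' (background becomes unclassified), for recovery comparisons.
#'
#' @param truth the `truth` element of [simulate_gonad_expression()].
#' @return a `gene_set_table`.
#' @export
truth_gene_sets <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  cls <- truth$genes$class
  cls[cls == "background"] <- "unclassified"
  gene_set_table(truth$genes$gene_id, cls, provenance = "planted")
}
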