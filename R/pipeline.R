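#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate (or load) -> gene-set extraction -> shift
#' quantification -> subset PCA -> contribution tests, and assembles a
#' machine-readable report. All randomness derives from the single
#' top-level `seed`, so rerunning the same config reproduces the report
#' exactly.
#'
#' The config (YAML file or equivalent list) holds:
#' \describe{
#'   \item{seed}{integer; drives the simulator.}
#'   \item{simulate}{[sim_config()] fields, to simulate the input; or}
#'   \item{input}{`matrix:` and `design:` TSV paths, to load it.}
#'   \item{extraction}{[extraction_config()] fields.}
#'   \item{shift}{`mutant:` and `reference:` `[sex, genotype]` pairs
#'     (default dko ovary vs control ovary).}
#'   \item{pca}{`orient_ref:` pair (default male control) and
#'     `scale_genes:` flag.}
#'   \item{outdir}{optional directory for TSV/GMT/JSON outputs.}
#' }
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return the report, invisibly: gene-set class counts, shift summary,
#'   per-subset PCA percent variance, contribution results for the
#'   control and mutant comparisons, and (when simulated) recovery
#'   metrics against the planted truth.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)

  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL
  dat <- stage("input", function() {
    if (!is.null(config$input)) {
      m_path <- config$input$matrix
      d_path <- config$input$design
      if (is.null(m_path) || !file.exists(m_path))
        stop("missing matrix file: ", m_path %||% "<unset>")
      if (is.null(d_path) || !file.exists(d_path))
        stop("missing design file: ", d_path %||% "<unset>")
      list(expr = read_expression_matrix(m_path),
           design = read_design(d_path), truth = NULL)
    } else {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- seed
      if (!is.null(sim_args$conditions))
        sim_args$conditions <- lapply(sim_args$conditions, unlist)
      simulate_gonad_expression(do.call(sim_config, sim_args))
    }
  })
  expr <- dat$expr; design <- dat$design; truth <- dat$truth
  validate_design(design, expr)

  ecfg <- stage("extraction_config", function()
    do.call(extraction_config, config$extraction %||% list()))

  sets <- stage("extract", function() derive_gene_sets(expr, design, ecfg))
  counts <- gene_set_counts(sets)
  message("gene-set class counts: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))

  mutant <- unlist(config$shift$mutant %||% c("female", "dko"))
  reference <- unlist(config$shift$reference %||% c("female", "control_het"))
  shift <- stage("shift", function() {
    fc <- log2_fold_change(expr, design, mutant, reference)
    shift_fractions(sets, fc, ecfg)
  })

  orient_ref <- unlist(config$pca$orient_ref %||% c("male", "control_het"))
  scale_genes <- isTRUE(config$pca$scale_genes)
  germ_genes <- gene_set(sets, c("male_germ", "female_germ"))
  soma_genes <- gene_set(sets, c("male_soma", "female_soma"))
  panel <- analysis_panel(design)

  pca_res <- stage("pca", function() {
    subsets <- list(all = rownames(expr), germ = germ_genes,
                    soma = soma_genes)
    lapply(subsets, function(gs) {
      if (length(gs) < 2L) return(NULL)
      run_subset_pca(expr, design, gs, orient_ref, groups = panel,
                     scale_genes = scale_genes)
    })
  })

  contrib <- stage("contribution", function() {
    specific <- c(germ_genes, soma_genes)
    if (length(germ_genes) < 2L || length(soma_genes) < 2L)
      return(list(control = NULL, mutant = NULL))
    ctrl_pca <- run_subset_pca(expr, design, specific, orient_ref,
                               groups = list(c("male", "control_het"),
                                             c("female", "control_het")),
                               scale_genes = scale_genes)
    mut_pca <- run_subset_pca(expr, design, specific, mutant,
                              groups = list(mutant, reference),
                              scale_genes = scale_genes)
    list(control = contribution_test(ctrl_pca, sets),
         mutant = contribution_test(mut_pca, sets))
  })

  recovery <- if (!is.null(truth))
    stage("recovery", function() recovery_metrics(sets, truth))

  report <- list(
    seed = seed,
    gene_set_counts = as.list(counts),
    shift = unclass(shift),
    pca_percent_var = lapply(pca_res, function(p)
      if (is.null(p)) NULL else p$percent_var),
    contribution = lapply(contrib, function(ct)
      if (is.null(ct)) NULL else unclass(ct)),
    recovery = recovery)

  if (!is.null(config$outdir)) {
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(truth)) {
      write_expression_matrix(expr, file.path(outdir, "matrix.tsv"))
      write_design(design, file.path(outdir, "design.tsv"))
      utils::write.table(truth$genes, file.path(outdir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_gene_sets(sets, file.path(outdir, "gene_sets.tsv"))
    write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    yaml::write_yaml(config, file.path(outdir, "config_resolved.yaml"))
  }
  invisible(report)
}

# Samples entering the headline PCA panel: everything except the
# germ-ablated subtraction controls, which belong to extraction only.
analysis_panel <- function(design) {
  keep <- unique(design[design$genotype != "germ_ablated",
                        c("sex", "genotype")])
  lapply(seq_len(nrow(keep)), function(i)
    c(keep$sex[i], keep$genotype[i]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
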