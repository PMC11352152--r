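# One-call orchestration of the full analysis: (simulate or load) ->
# probe collapse -> size factors -> NB Wald differential expression ->
# mutual-information screen -> seed intersection -> regularized-Laplacian
# diffusion -> percentile candidates -> hypergeometric enrichment ->
# panel evaluation, with TSV artifacts and a provenance record.

default_config <- function() {
  list(
    paths = NULL,
    simulate = NULL,
    diffexp = list(alpha = 0.05, min_abs_lfc = 1.5,
                   dispersion_mode = "gene"),
    mi = list(method = "equal_width", bins = NULL,
              select = "max_ties", k = NULL),
    diffusion = list(alpha = 1, percentile = 99, exclude_seeds = TRUE),
    enrichment = list(min_size = 10, max_size = 500, alpha = 0.01),
    rng_seed = 1L
  )
}

default_simulate_block <- function() {
  list(n_genes = 2000, n_high = 12, n_low = 3, de_fraction = 0.05,
       lfc_location = 2.5, dispersion = 0.1, depth_range = c(0.5, 2),
       n_separators = 7, network_nodes = 500, network_model = "barabasi_albert",
       n_sets = 50, set_size_range = c(10, 40), n_enriched = 3)
}

merge_block <- function(defaults, user, block, errs) {
  if (is.null(user)) return(list(value = defaults, errs = errs))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0(block, ": unknown key(s) ",
                           paste(unknown, collapse = ", ")))
  for (nm in intersect(names(user), names(defaults)))
    defaults[[nm]] <- user[[nm]]
  list(value = defaults, errs = errs)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (DE: adjusted p < 0.05, |log2 FC| > 1.5; MI: equal-width
#' bins, max-tie selection; diffusion: alpha 1, 99th percentile, seeds
#' excluded; enrichment: sizes 10-500, p < 0.01), rejects unknown keys and
#' aggregates every domain violation into a single error.
#'
#' @param cfg named list (possibly nested) or a YAML file path; must carry
#'   either `paths` (counts, sample_sheet, edges, gmt) or a `simulate`
#'   block.
#' @return normalized configuration list.
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg) && length(cfg) == 1L)
    cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  errs <- character()
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown, collapse = ", ")))
  for (block in c("diffexp", "mi", "diffusion", "enrichment")) {
    res <- merge_block(def[[block]], cfg[[block]], block, errs)
    def[[block]] <- res$value; errs <- res$errs
  }
  if (!is.null(cfg$rng_seed)) def$rng_seed <- as.integer(cfg$rng_seed)
  if (!is.null(cfg$simulate)) {
    res <- merge_block(default_simulate_block(), cfg$simulate, "simulate", errs)
    def$simulate <- res$value; errs <- res$errs
  }
  if (!is.null(cfg$paths)) {
    need <- c("counts", "sample_sheet", "edges", "gmt")
    res <- merge_block(stats::setNames(as.list(rep(NA_character_, 4L)), need),
                       cfg$paths, "paths", errs)
    def$paths <- res$value; errs <- res$errs
    if (anyNA(unlist(def$paths)))
      errs <- c(errs, "paths block must name counts, sample_sheet, edges, gmt")
  }
  if (is.null(def$paths) && is.null(def$simulate))
    errs <- c(errs, "config needs either a paths block or a simulate block")
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(def$diffexp$alpha > 0 && def$diffexp$alpha < 1,
      "diffexp.alpha must lie in (0, 1)")
  chk(def$diffexp$min_abs_lfc >= 0, "diffexp.min_abs_lfc must be >= 0")
  chk(def$diffexp$dispersion_mode %in% c("gene", "trend"),
      "diffexp.dispersion_mode must be gene or trend")
  chk(def$mi$method %in% c("equal_width", "equal_frequency", "distinct"),
      "mi.method must be equal_width, equal_frequency or distinct")
  chk(def$mi$select %in% c("max_ties", "top_k"),
      "mi.select must be max_ties or top_k")
  if (identical(def$mi$select, "top_k"))
    chk(!is.null(def$mi$k) && def$mi$k >= 1, "mi.k must be >= 1 for top_k")
  chk(def$diffusion$alpha >= 0, "diffusion.alpha must be >= 0")
  chk(def$diffusion$percentile > 0 && def$diffusion$percentile < 100,
      "diffusion.percentile must lie in (0, 100)")
  chk(def$enrichment$min_size <= def$enrichment$max_size,
      "enrichment.min_size must be <= enrichment.max_size")
  chk(def$enrichment$min_size >= 1, "enrichment.min_size must be >= 1")
  chk(def$enrichment$alpha > 0 && def$enrichment$alpha < 1,
      "enrichment.alpha must lie in (0, 1)")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  def
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes every stage in order and writes the artifacts to `out_dir`:
#' gene-level counts, size factors, the differential-expression table, the
#' MI score table, the seed list, the diffusion score table, the candidate
#' list, the enrichment table, the panel-evaluation report, and a
#' provenance JSON (config, package version, seed, config digest). The same
#' configuration and seed give byte-identical tables.
#'
#' @param cfg configuration list or YAML path, see [validate_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with every intermediate result (`counts`,
#'   `samples`, `network`, `pathways`, `truth` if simulated, `size_factors`,
#'   `norm`, `de_table`, `degs`, `mi_table`, `mi_genes`, `seeds`,
#'   `diffusion`, `candidates`, `enrichment`, `evaluation`, `artifacts`).
#' @export
run_pipeline <- function(cfg = list(simulate = list()), out_dir = tempfile("budnet_run_")) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sb <- cfg$simulate
    sim <- stage("simulate", simulate_counts(
      n_genes = sb$n_genes, n_high = sb$n_high, n_low = sb$n_low,
      de_fraction = sb$de_fraction, lfc_location = sb$lfc_location,
      dispersion = sb$dispersion, depth_range = sb$depth_range,
      n_separators = sb$n_separators, rng_seed = cfg$rng_seed))
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    node_names <- stage("simulate", withr::with_seed(cfg$rng_seed + 1L, {
      pool <- setdiff(counts$gene_symbols, truth$seed_genes)
      c(truth$seed_genes,
        sample(pool, sb$network_nodes - length(truth$seed_genes)))
    }))
    network <- stage("simulate", simulate_network(
      sb$network_nodes, model = sb$network_model,
      rng_seed = cfg$rng_seed + 2L, node_names = node_names))
    pathways <- stage("simulate", simulate_pathways(
      network, truth$seed_genes, n_sets = sb$n_sets,
      size_range = sb$set_size_range, n_enriched = sb$n_enriched,
      rng_seed = cfg$rng_seed + 3L))
    truth$enriched_sets <- attr(pathways, "enriched_sets")
  } else {
    counts <- stage("read_counts", read_counts(cfg$paths$counts,
      level = if (is.null(cfg$paths$level)) "gene" else cfg$paths$level))
    samples <- stage("read_sample_sheet", read_sample_sheet(cfg$paths$sample_sheet))
    network <- stage("read_string_edges", read_string_edges(cfg$paths$edges))
    pathways <- stage("read_gmt", read_gmt(cfg$paths$gmt))
  }
  if (counts$level == "probe")
    counts <- stage("collapse_probes", collapse_probes(counts))
  lab <- samples[!is.na(samples$class_label), , drop = FALSE]
  sub <- stage("diffexp", {
    if (!nrow(lab) || length(unique(lab$class_label)) < 2L)
      stop("no class-labeled samples in both classes")
    bud_counts(counts$counts[, lab$sample_id, drop = FALSE], level = "gene")
  })
  sf <- stage("size_factors", size_factors(sub))
  norm <- stage("normalize", normalize_counts(sub, sf))
  de_table <- stage("diffexp", run_diffexp(sub, samples,
    dispersion_mode = cfg$diffexp$dispersion_mode))
  degs <- filter_degs(de_table, alpha = cfg$diffexp$alpha,
                      min_abs_lfc = cfg$diffexp$min_abs_lfc)
  mi_tab <- stage("mi_select", mi_table(norm, samples,
    method = cfg$mi$method, n_bins = cfg$mi$bins))
  mi_genes <- stage("mi_select", select_top_mi(mi_tab, mode = cfg$mi$select,
                                               k = cfg$mi$k))
  seeds <- stage("diffusion", build_seed_set(degs, mi_genes, network))
  diff_res <- stage("diffusion", diffuse(network, seeds,
    alpha = cfg$diffusion$alpha))
  candidates <- stage("diffusion", percentile_cutoff(diff_res,
    percentile = cfg$diffusion$percentile,
    exclude_seeds = cfg$diffusion$exclude_seeds))
  enr <- stage("enrichment", enrich(
    union(candidates, seeds$matched), pathways, universe = network$nodes,
    min_size = cfg$enrichment$min_size, max_size = cfg$enrichment$max_size,
    alpha = cfg$enrichment$alpha))
  eval_res <- stage("evaluation", evaluate_panel(norm, samples, seeds$genes))
  art <- file.path(out_dir, c(
    counts = "gene_counts.tsv", sf = "size_factors.tsv",
    de = "de_table.tsv", mi = "mi_table.tsv", seeds = "seed_list.tsv",
    diffusion = "diffusion_table.tsv", candidates = "candidate_list.tsv",
    enrichment = "enrichment_table.tsv", evaluation = "evaluation.tsv",
    provenance = "provenance.json"))
  names(art) <- c("counts", "sf", "de", "mi", "seeds", "diffusion",
                  "candidates", "enrichment", "evaluation", "provenance")
  write_table(data.frame(gene = rownames(counts$counts), counts$counts,
                         check.names = FALSE), art[["counts"]])
  write_table(data.frame(sample_id = names(sf), size_factor = sf),
              art[["sf"]])
  write_table(de_table, art[["de"]])
  write_table(mi_tab, art[["mi"]])
  write_table(data.frame(gene = seeds$genes,
                         in_network = seeds$genes %in% seeds$matched),
              art[["seeds"]])
  write_table(diff_res, art[["diffusion"]])
  write_table(data.frame(node = candidates), art[["candidates"]])
  write_table(enr, art[["enrichment"]])
  write_table(data.frame(
    metric = c("separation_score", "pc1_var", "pc2_var",
               "n_seeds", "n_degs", "n_mi_genes", "n_candidates"),
    value = c(as.numeric(eval_res$separation_score),
              eval_res$pca$var_explained, length(seeds$genes),
              length(degs), length(mi_genes), length(candidates))),
    art[["evaluation"]])
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  digest <- unname(tools::md5sum(tmp)); unlink(tmp)
  jsonlite::write_json(list(
    package = "budnet",
    version = as.character(utils::packageVersion("budnet")),
    rng_seed = cfg$rng_seed, config_digest = digest,
    config = cfg), art[["provenance"]], auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(list(config = cfg, counts = counts, samples = samples,
                 network = network, pathways = pathways, truth = truth,
                 size_factors = sf, norm = norm, de_table = de_table,
                 degs = degs, mi_table = mi_tab, mi_genes = mi_genes,
                 seeds = seeds, diffusion = diff_res,
                 candidates = candidates, enrichment = enr,
                 evaluation = eval_res, artifacts = art))
}
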