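# End-to-end orchestration: DEG calling -> list fusion -> enrichment of
# the three lists -> comparison table / pathway overlap -> optional
# network landscape, driven by a single validated config.  All stage
# outputs are plain TSV/JSON; identical config + inputs give a
# byte-identical report (no timestamps are recorded).

.default_config <- function() {
  list(
    mode = "synthetic",
    synthetic = list(seed = 1L, n_genes = 12000L, n_pathways = 150L,
                     n_planted = 10L, disjointness = 1,
                     effect_log2 = 2, noise_sd = 0.5, replicates = 4L,
                     sensitivity = 0.5, genome_fpr = 0.03,
                     low_fraction = 0.1),
    inputs = list(matrix = NULL, hits = NULL, gmt = NULL, namespace = "syn"),
    deg = list(p = 0.05, fold = 2, pseudo = 0.1, floor = 2,
               timepoints = c(8, 24, 72)),
    fusion = list(direction = "up"),
    enrichment = list(p = 0.05, fdr = 0.10, blocklist = character()),
    landscape = list(enabled = FALSE, network = NULL, min_confidence = 0.4,
                     timepoint = 8, resolution = 64L, bandwidth = 0.05,
                     edge_mode = "nodes_only", seed = 1L),
    out_dir = NULL
  )
}

# shallow-merge user config over defaults (one level of nesting)
.merge_config <- function(user) {
  cfg <- .default_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

#' Read a pipeline run configuration from a JSON file
#'
#' CLI flags override config values; the effective config is echoed into
#' the output directory for auditability.
#'
#' @param path JSON file; any subset of the default fields may be given.
#' @return a validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(.merge_config(user))
}

#' Validate a pipeline run configuration
#'
#' @param config config list (missing fields filled with defaults).
#' @return the completed config, or an error naming the offending field.
#' @export
validate_run_config <- function(config) {
  cfg <- .merge_config(config)
  if (!cfg$mode %in% c("synthetic", "files"))
    stop("config mode must be 'synthetic' or 'files'", call. = FALSE)
  for (fld in c("p", "fdr"))
    if (cfg$enrichment[[fld]] <= 0 || cfg$enrichment[[fld]] > 1)
      stop("enrichment ", fld, " must lie in (0, 1]", call. = FALSE)
  if (cfg$deg$p <= 0 || cfg$deg$p > 1)
    stop("deg p must lie in (0, 1]", call. = FALSE)
  if (cfg$deg$fold < 1) stop("deg fold must be >= 1", call. = FALSE)
  if (!cfg$fusion$direction %in% c("up", "down", "any"))
    stop("fusion direction must be up, down or any", call. = FALSE)
  if (cfg$mode == "files") {
    for (fld in c("matrix", "hits", "gmt")) {
      p <- cfg$inputs[[fld]]
      if (is.null(p)) stop("config inputs$", fld, " is required in files mode",
                           call. = FALSE)
      if (!file.exists(p)) stop("config inputs$", fld, ": no such file: ", p,
                                call. = FALSE)
    }
  }
  if (isTRUE(cfg$landscape$enabled) && cfg$mode == "files" &&
      (is.null(cfg$landscape$network) || !file.exists(cfg$landscape$network)))
    stop("config landscape$network: file required when landscape is enabled",
         call. = FALSE)
  cfg
}

#' Run the full fusion pathway-enrichment pipeline
#'
#' Stages: (synthetic generation or file loading) -> low-expression
#' filter -> DEG calling -> fusion of the chosen-direction DEG list with
#' the RNAi hit list -> enrichment of the microarray, RNAi and fused
#' lists against the same collection and universe -> term filtering ->
#' comparison table and pathway/gene overlap statistics -> optional
#' expression landscape.  The universe is the post-filter detected gene
#' set.
#'
#' @param config a config list (see [read_run_config()]); missing fields
#'   take defaults.
#' @param out_dir output directory (overrides `config$out_dir`); created
#'   if needed.  `NULL` skips writing files.
#' @return the run report (list), invisibly written as
#'   `report.json` plus per-stage TSVs when `out_dir` is set.
#' @export
run_fusion_pea <- function(config = list(), out_dir = NULL) {
  cfg <- validate_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  truth <- NULL
  if (cfg$mode == "synthetic") {
    sc <- cfg$synthetic
    collection <- make_universe(n_genes = sc$n_genes,
                                n_pathways = sc$n_pathways,
                                seed = sc$seed)
    planted <- names(collection$terms)[seq_len(sc$n_planted)]
    study <- simulate_study(collection, planted,
                            disjointness = sc$disjointness,
                            effect_log2 = sc$effect_log2,
                            noise_sd = sc$noise_sd,
                            replicates = sc$replicates,
                            timepoints = cfg$deg$timepoints,
                            low_fraction = sc$low_fraction,
                            sensitivity = sc$sensitivity,
                            genome_fpr = sc$genome_fpr, seed = sc$seed)
    mat <- study$matrix; hits <- study$hits; truth <- study$truth
  } else {
    ns <- cfg$inputs$namespace
    mat <- read_expression_table(cfg$inputs$matrix, namespace = ns)
    hits <- read_gene_list(cfg$inputs$hits, namespace = ns,
                           platform = "rnai")
    collection <- read_gmt(cfg$inputs$gmt, namespace = ns)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (check the corresponding config section)",
                   name, conditionMessage(e)), call. = FALSE))
  }
  mat_f <- stage("filter", filter_low_expression(mat, floor = cfg$deg$floor))
  degs <- stage("deg", call_degs(mat_f, cfg$deg$timepoints,
                                 p_threshold = cfg$deg$p,
                                 fold_threshold = cfg$deg$fold,
                                 pseudo = cfg$deg$pseudo))
  deg_list <- switch(cfg$fusion$direction,
                     up = degs$up, down = degs$down,
                     any = gene_list(c(degs$up$members, degs$down$members),
                                     name = "deg_any",
                                     namespace = mat$namespace,
                                     platform = "expression"))
  fused <- stage("fuse", fuse_lists(deg_list, hits))
  universe <- rownames(mat_f$values)
  gene_venn <- venn(deg_list, hits)
  gene_p <- overlap_enrichment_p(gene_venn$size_intersection,
                                 length(deg_list$members),
                                 length(intersect(hits$members, universe)),
                                 length(universe))
  enr <- stage("enrich", lapply(
    list(microarray = deg_list, rnai = hits, fusion = fused),
    enrich, collection = collection, universe = universe))
  filt <- lapply(enr, filter_terms, p_max = cfg$enrichment$p,
                 fdr_max = cfg$enrichment$fdr,
                 blocklist = cfg$enrichment$blocklist)
  comparison <- stage("compare", build_comparison_table(filt, collection))
  path_ov <- if (all(vapply(filt[c("microarray", "rnai")], nrow,
                            integer(1)) > 0L))
    pathway_overlap(lapply(filt, `[[`, "term_id")) else NULL
  landscape <- NULL
  if (isTRUE(cfg$landscape$enabled)) {
    landscape <- stage("landscape", {
      net <- if (cfg$mode == "files")
        read_string_links(cfg$landscape$network,
                          min_confidence = cfg$landscape$min_confidence,
                          namespace = mat$namespace)
      else {
        # synthetic mode: clique-per-planted-pathway demo network
        ed <- do.call(rbind, lapply(truth$planted_terms[1:2], function(id) {
          m <- head(collection$terms[[id]], 12L)
          cmb <- utils::combn(m, 2L)
          data.frame(from = cmb[1L, ], to = cmb[2L, ], confidence = 0.7,
                     stringsAsFactors = FALSE)
        }))
        interaction_network(ed, namespace = mat$namespace)
      }
      net <- annotate_network(net, degs$up, degs$down, hits)
      coords <- layout_network(net, seed = cfg$landscape$seed)
      mass <- node_mass_from_matrix(net, mat_f, "treated",
                                    cfg$landscape$timepoint)
      build_landscape(net, coords, mass,
                      resolution = cfg$landscape$resolution,
                      bandwidth = cfg$landscape$bandwidth,
                      edge_mode = cfg$landscape$edge_mode)
    })
  }
  report <- list(
    package_version = as.character(packageVersion("screenfuse")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    counts = list(
      genes_input = nrow(mat$values), genes_detected = length(universe),
      deg_up = length(degs$up$members), deg_down = length(degs$down$members),
      rnai_hits = length(hits$members), fused = length(fused$members)),
    gene_overlap = list(
      size_a = gene_venn$size_a, size_b = gene_venn$size_b,
      intersection = gene_venn$size_intersection,
      union = gene_venn$size_union,
      overlap_percent = gene_venn$overlap_percent,
      hypergeom_p = gene_p),
    enriched_terms = lapply(filt, `[[`, "term_id"),
    pathway_overlap = if (!is.null(path_ov))
      list(sizes = as.list(path_ov$sizes), shared = path_ov$shared,
           pairwise = path_ov$pairwise) else NULL,
    comparison_blocks = as.list(table(comparison$block)),
    landscape_mass = if (!is.null(landscape)) landscape$deposited_mass
                     else NULL,
    planted_terms = if (!is.null(truth)) truth$planted_terms else NULL)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_list(degs$up, file.path(cfg$out_dir, "deg_up.txt"))
    write_gene_list(degs$down, file.path(cfg$out_dir, "deg_down.txt"))
    write_gene_list(fused, file.path(cfg$out_dir, "fused.txt"))
    con <- file(file.path(cfg$out_dir, "deg_records.tsv"), "wb")
    write.table(degs$records, con, sep = "\t", quote = FALSE,
                row.names = FALSE, eol = "\n"); close(con)
    for (src in names(filt))
      write_enrichment(filt[[src]],
                       file.path(cfg$out_dir,
                                 paste0("enrichment_", src, ".tsv")))
    con <- file(file.path(cfg$out_dir, "comparison_table.tsv"), "wb")
    write.table(comparison, con, sep = "\t", quote = FALSE,
                row.names = FALSE, eol = "\n"); close(con)
    if (!is.null(landscape))
      write_landscape(landscape, file.path(cfg$out_dir, "landscape.tsv"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  report$tables <- list(comparison = comparison, enrichment = filt,
                        deg_records = degs$records)
  invisible(report)
}
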