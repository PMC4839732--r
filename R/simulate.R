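# Planted-signal synthetic data.  The stated world mirrors the study's
# designs: ~12,000 detectable genes (scaled to the 12,363 array-detected
# set), quadruplicate control/treated groups over an 8/24/72 h course,
# and a genome-wide screen whose defaults (sensitivity 0.5 over planted
# essential genes, genome-wide false-positive rate 0.03) reproduce a
# ~1,000-gene hit list of which roughly 40% are false positives.
# Expression is lognormal: baseline log2 abundance ~ Normal(4, 2),
# treatment adds a fixed log2 effect to responsive genes, Gaussian noise
# on the log2 scale; a "disjointness" knob forces the responsive and the
# essential members of doubly-planted pathways apart, reproducing the
# observed chance-level gene overlap between platforms.

#' Generate a synthetic gene universe with pathway structure
#'
#' Pathway sizes are log-uniform within `size_range`; a fraction of each
#' pathway's members is drawn from genes already used by earlier pathways
#' (controlled by `overlap_fraction`), the rest from fresh genes until the
#' pool runs out.
#'
#' @param n_genes universe size (default 12000).
#' @param n_pathways number of terms (default 150).
#' @param size_range integer range of term sizes (default c(10, 300)).
#' @param overlap_fraction fraction of each term drawn from already-used
#'   genes (default 0.2; 0 keeps pathways disjoint while fresh genes
#'   remain).
#' @param seed integer RNG seed.
#' @return a [gene_set_collection] in namespace `"syn"` whose universe is
#'   all `n_genes` genes.
#' @export
make_universe <- function(n_genes = 12000L, n_pathways = 150L,
                          size_range = c(10L, 300L), overlap_fraction = 0.2,
                          seed = 1L) {
  if (size_range[1L] < 2L || size_range[2L] > n_genes ||
      size_range[1L] > size_range[2L])
    stop("size_range must lie within [2, n_genes]", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  sizes <- round(exp(runif(n_pathways, log(size_range[1L]),
                           log(size_range[2L]))))
  sizes <- pmin(pmax(sizes, size_range[1L]), size_range[2L])
  used <- character()
  terms <- vector("list", n_pathways)
  names(terms) <- sprintf("path%03d", seq_len(n_pathways))
  for (i in seq_len(n_pathways)) {
    fresh <- setdiff(genes, used)
    n_over <- min(round(overlap_fraction * sizes[i]), length(used))
    n_new <- min(sizes[i] - n_over, length(fresh))
    members <- c(if (n_over > 0L) sample(used, n_over),
                 if (n_new > 0L) sample(fresh, n_new))
    short <- sizes[i] - length(members)
    if (short > 0L)  # fresh pool exhausted; top up from anywhere
      members <- c(members, sample(setdiff(genes, members), short))
    terms[[i]] <- sort(members)
    used <- union(used, members)
  }
  gene_set_collection(
    terms,
    term_names = sprintf("Synthetic pathway %03d", seq_len(n_pathways)),
    universe = genes, name = sprintf("synthetic_universe_seed%d", seed),
    namespace = "syn")
}

#' Simulate a replicated expression time course with planted signal
#'
#' Control and treated arms at each timepoint, `replicates` each.
#' Baseline log2 abundance is Normal(`baseline_mean`, `baseline_sd`) per
#' gene; a `low_fraction` of non-responsive genes is drawn below the
#' RPKM-2 floor to exercise low-expression filtering; treated samples add
#' `effect_log2` to the responsive genes at every requested timepoint;
#' i.i.d. Gaussian noise of sd `noise_sd` is added on the log2 scale; the
#' exported matrix is linear scale.
#'
#' @param collection a [gene_set_collection] (defines genes/universe).
#' @param planted_terms term ids whose members respond transcriptionally.
#' @param effect_log2 planted log2 fold change (default 2).
#' @param responsive_fraction fraction of each planted term that responds
#'   (default 0.5; must be in (0, 1\]).
#' @param noise_sd log2-scale noise sd (default 0.5).
#' @param replicates per-arm replicates (default 4, the array design).
#' @param timepoints treated/control timepoints in hours (default 8, 24, 72).
#' @param baseline_mean,baseline_sd log2 baseline distribution (4, 2).
#' @param low_fraction fraction of genes planted below the abundance
#'   floor (default 0.1).
#' @param seed integer RNG seed.
#' @param responsive_genes optional explicit responsive set overriding the
#'   per-term draw (used by [simulate_study()] to control disjointness).
#' @return list with `matrix` (an [expression_matrix]) and `truth` (class
#'   `synthetic_truth`).
#' @export
simulate_expression <- function(collection, planted_terms,
                                effect_log2 = 2, responsive_fraction = 0.5,
                                noise_sd = 0.5, replicates = 4L,
                                timepoints = c(8, 24, 72),
                                baseline_mean = 4, baseline_sd = 2,
                                low_fraction = 0.1, seed = 1L,
                                responsive_genes = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  bad <- setdiff(planted_terms, names(collection$terms))
  if (length(bad))
    stop("planted terms not in collection: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (responsive_fraction <= 0 || responsive_fraction > 1)
    stop("responsive_fraction must lie in (0, 1]", call. = FALSE)
  set.seed(seed)
  genes <- collection$universe
  n <- length(genes)
  if (is.null(responsive_genes)) {
    responsive_genes <- unique(unlist(lapply(planted_terms, function(id) {
      m <- collection$terms[[id]]
      sample(m, max(1L, round(responsive_fraction * length(m))))
    })))
  } else {
    responsive_genes <- intersect(responsive_genes, genes)
  }
  baseline <- rnorm(n, baseline_mean, baseline_sd)
  n_low <- round(low_fraction * n)
  low_pool <- setdiff(genes, responsive_genes)
  low_genes <- if (n_low > 0L) sample(low_pool, min(n_low, length(low_pool)))
               else character()
  baseline[match(low_genes, genes)] <- rnorm(length(low_genes), -0.5, 0.3)
  effect <- ifelse(genes %in% responsive_genes, effect_log2, 0)
  samples <- expand.grid(replicate = seq_len(replicates),
                         timepoint = timepoints,
                         condition = c("control", "treated"),
                         stringsAsFactors = FALSE)[, c("condition",
                                                       "timepoint",
                                                       "replicate")]
  mu <- outer(baseline, rep(1, nrow(samples))) +
    outer(effect, as.numeric(samples$condition == "treated"))
  logvals <- mu + matrix(rnorm(n * nrow(samples), 0, noise_sd), n)
  values <- 2^logvals
  rownames(values) <- genes
  mat <- expression_matrix(values, samples, namespace = collection$namespace,
                           scale_tag = "linear")
  truth <- structure(list(
    kind = "expression", seed = seed, n_genes = n,
    planted_transcriptional = setNames(
      lapply(planted_terms, function(id)
        intersect(collection$terms[[id]], responsive_genes)),
      planted_terms),
    responsive_genes = responsive_genes, effect_log2 = effect_log2,
    responsive_fraction = responsive_fraction, noise_sd = noise_sd,
    replicates = replicates, timepoints = timepoints,
    low_genes = low_genes), class = "synthetic_truth")
  list(matrix = mat, truth = truth)
}

#' Simulate a genome-wide RNAi survival screen
#'
#' Every essential gene becomes a hit with probability `sensitivity`;
#' every other universe gene with probability `genome_fpr`.  The defaults
#' on the default universe yield a hit list of roughly a thousand genes
#' with ~40% false positives, matching reported screen characteristics.
#'
#' @param collection a [gene_set_collection].
#' @param essential_terms term ids whose members are survival-essential.
#' @param sensitivity true-positive rate over essential genes (default 0.5).
#' @param genome_fpr false-positive rate over the remaining genome
#'   (default 0.03).
#' @param seed integer RNG seed.
#' @param essential_genes optional explicit essential set overriding the
#'   term union (used by [simulate_study()]).
#' @return list with `hits` (a [gene_list], platform `"rnai"`) and
#'   `truth` (class `synthetic_truth`).
#' @export
simulate_rnai_screen <- function(collection, essential_terms,
                                 sensitivity = 0.5, genome_fpr = 0.03,
                                 seed = 1L, essential_genes = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  bad <- setdiff(essential_terms, names(collection$terms))
  if (length(bad))
    stop("essential terms not in collection: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (r in c(sensitivity, genome_fpr))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  genes <- collection$universe
  if (is.null(essential_genes))
    essential_genes <- unique(unlist(collection$terms[essential_terms]))
  essential_genes <- intersect(essential_genes, genes)
  is_ess <- genes %in% essential_genes
  prob <- ifelse(is_ess, sensitivity, genome_fpr)
  hit <- rbinom(length(genes), 1L, prob) == 1L
  hits <- gene_list(genes[hit], name = "rnai_hits",
                    namespace = collection$namespace, platform = "rnai",
                    direction = "any")
  truth <- structure(list(
    kind = "rnai", seed = seed, n_genes = length(genes),
    planted_essential = setNames(
      lapply(essential_terms, function(id)
        intersect(collection$terms[[id]], essential_genes)),
      essential_terms),
    essential_genes = essential_genes, sensitivity = sensitivity,
    genome_fpr = genome_fpr,
    true_hits = genes[hit & is_ess],
    false_hits = genes[hit & !is_ess]), class = "synthetic_truth")
  list(hits = hits, truth = truth)
}

#' Simulate an ortholog map and target-species collection
#'
#' A conserved 1:1 ortholog pair is created for `conservation` of the
#' source genes (target ids prefixed `h_`); pathway membership is
#' preserved at the term level for conserved genes.  With
#' `scramble_within_pathway` the flag is recorded in the truth so that
#' downstream simulations re-draw which member genes respond in the
#' target species — pathway identity is conserved, gene identity is not.
#'
#' @param collection_source a [gene_set_collection].
#' @param conservation fraction of genes with a conserved ortholog
#'   (default 0.95).
#' @param scramble_within_pathway logical flag (see above).
#' @param seed integer RNG seed.
#' @return list with `map` (an [ortholog_map]), `collection`
#'   (target-species [gene_set_collection], namespace `"syn_target"`) and
#'   `truth`.
#' @export
simulate_orthologs <- function(collection_source, conservation = 0.95,
                               scramble_within_pathway = FALSE, seed = 1L) {
  stopifnot(inherits(collection_source, "gene_set_collection"))
  if (conservation < 0 || conservation > 1)
    stop("conservation must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  genes <- collection_source$universe
  conserved <- genes[runif(length(genes)) < conservation]
  target_of <- setNames(paste0("h_", conserved), conserved)
  map <- ortholog_map(data.frame(source = conserved,
                                 target = unname(target_of),
                                 stringsAsFactors = FALSE),
                      source_namespace = collection_source$namespace,
                      target_namespace = "syn_target")
  terms_t <- lapply(collection_source$terms, function(m)
    unname(target_of[intersect(m, conserved)]))
  terms_t <- terms_t[lengths(terms_t) > 0L]
  coll_t <- gene_set_collection(
    terms_t,
    term_names = collection_source$term_names[names(terms_t)],
    universe = unname(target_of),
    name = paste0(collection_source$name, "_target"),
    namespace = "syn_target")
  truth <- structure(list(kind = "orthologs", seed = seed,
                          conservation = conservation,
                          scramble_within_pathway = scramble_within_pathway,
                          conserved_genes = conserved),
                     class = "synthetic_truth")
  list(map = map, collection = coll_t, truth = truth)
}

#' Simulate a paired expression + RNAi-screen study with controlled
#' disjointness
#'
#' For each doubly-planted pathway, a responsive subset (transcriptional
#' signal) and an essential subset (screen signal) of its members are
#' drawn.  `disjointness` d in \[0, 1\] controls how strictly the two
#' signals are kept apart: with probability d a gene follows a single
#' global role (responsive XOR essential, shared across pathways, so
#' genes sitting in several planted pathways cannot leak between
#' signals), and with probability 1 - d its roles are drawn
#' independently per pathway.  At d = 1 the two signals share no genes — the regime where gene-level overlap
#' between platforms sits at chance while fused lists still concentrate
#' in the planted pathways.
#'
#' @param collection a [gene_set_collection].
#' @param planted_terms doubly-planted term ids.
#' @param disjointness d in \[0, 1\] (default 1).
#' @param responsive_fraction,essential_fraction fractions of each planted
#'   term assigned to the two signals (defaults 0.5 each).
#' @param sensitivity,genome_fpr screen parameters (0.5, 0.03).
#' @inheritParams simulate_expression
#' @return list with `matrix`, `hits`, `collection`, and `truth` (merged
#'   bookkeeping incl. per-term responsive/essential subsets and the two
#'   stage seeds derived from `seed`).
#' @export
simulate_study <- function(collection, planted_terms, disjointness = 1,
                           responsive_fraction = 0.5,
                           essential_fraction = 0.5,
                           effect_log2 = 2, noise_sd = 0.5, replicates = 4L,
                           timepoints = c(8, 24, 72), low_fraction = 0.1,
                           sensitivity = 0.5, genome_fpr = 0.03, seed = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (disjointness < 0 || disjointness > 1)
    stop("disjointness must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  # Disjointness is enforced through a GLOBAL role per planted gene, so a
  # gene shared by two planted pathways cannot be responsive in one and
  # essential in the other at d = 1.  Each gene-in-term uses the global
  # role with probability d and an independent per-term draw otherwise.
  planted_genes <- unique(unlist(collection$terms[planted_terms]))
  p_resp <- responsive_fraction / (responsive_fraction + essential_fraction)
  global_responsive <- setNames(runif(length(planted_genes)) < p_resp,
                                planted_genes)
  responsive <- list(); essential <- list()
  for (id in planted_terms) {
    m <- collection$terms[[id]]
    use_global <- runif(length(m)) < disjointness
    is_resp <- ifelse(use_global, global_responsive[m],
                      runif(length(m)) < responsive_fraction)
    is_ess <- ifelse(use_global, !global_responsive[m],
                     runif(length(m)) < essential_fraction)
    if (!any(is_resp)) is_resp[sample.int(length(m), 1L)] <- TRUE
    if (!any(is_ess & !is_resp)) {
      cand <- which(!is_resp)
      if (length(cand)) is_ess[cand[sample.int(length(cand), 1L)]] <- TRUE
    }
    responsive[[id]] <- m[is_resp]
    essential[[id]] <- m[is_ess]
  }
  expr <- simulate_expression(
    collection, planted_terms, effect_log2 = effect_log2,
    responsive_fraction = responsive_fraction, noise_sd = noise_sd,
    replicates = replicates, timepoints = timepoints,
    low_fraction = low_fraction, seed = sub_seeds[1L],
    responsive_genes = unique(unlist(responsive)))
  screen <- simulate_rnai_screen(
    collection, planted_terms, sensitivity = sensitivity,
    genome_fpr = genome_fpr, seed = sub_seeds[2L],
    essential_genes = unique(unlist(essential)))
  truth <- structure(list(
    kind = "study", seed = seed, stage_seeds = sub_seeds,
    disjointness = disjointness, planted_terms = planted_terms,
    responsive_by_term = responsive, essential_by_term = essential,
    expression = expr$truth, screen = screen$truth),
    class = "synthetic_truth")
  list(matrix = expr$matrix, hits = screen$hits, collection = collection,
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth kind=%s seed=%d>\n", x$kind, x$seed))
  invisible(x)
}
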