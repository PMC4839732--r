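# Cross-platform and cross-species comparison statistics: per-pathway
# genes-in-pathway proportion tests (fusion vs each single platform),
# the grouped comparison table, pathway-level Venn overlaps, and shared
# conserved terms across species.

#' One-tailed Fisher test comparing genes-in-pathway proportions
#'
#' For a pathway of `T` genes with `k_fusion` members found by the fused
#' list and `k_other` by a single platform, tests the 2x2 table
#' `[[k_fusion, T - k_fusion], [k_other, T - k_other]]` with the
#' alternative that the fusion proportion is greater.  An `NA` (pathway
#' not detected by the single platform) is treated as `k_other = 0` and
#' flagged via the `nd_comparison` attribute.
#'
#' @param T pathway size (positive integer).
#' @param k_fusion,k_other member counts, each `<= T`; `k_other` may be
#'   `NA` (not detected).
#' @param tail `"greater"` (default) or `"less"`.
#' @return one-tailed Fisher exact p-value.
#' @examples
#' proportion_fisher(180, 24, 13)  # 0.041
#' @export
proportion_fisher <- function(T, k_fusion, k_other, tail = c("greater",
                                                             "less")) {
  tail <- match.arg(tail)
  stopifnot(length(T) == 1L, T >= 1, k_fusion >= 0)
  nd <- is.na(k_other)
  if (nd) k_other <- 0L
  if (k_fusion > T || k_other > T)
    stop("counts cannot exceed the pathway size T", call. = FALSE)
  # Conditional on both margins the (1,1) cell is hypergeometric:
  # X ~ Hypergeom(N = 2T, K = k_fusion + k_other, n = T)
  p <- if (tail == "greater")
    phyper(k_fusion - 1, k_fusion + k_other, 2 * T - k_fusion - k_other, T,
           lower.tail = FALSE)
  else
    phyper(k_fusion, k_fusion + k_other, 2 * T - k_fusion - k_other, T)
  attr(p, "nd_comparison") <- nd
  p
}

#' Build the fusion-vs-platform pathway comparison table
#'
#' One row per pathway detected (post-filter) by at least one source,
#' grouped into four blocks by which single platforms detected it:
#' `"microarray_and_rnai"`, `"rnai_and_fusion"`, `"microarray_and_fusion"`
#' and `"fusion_only"`.  Counts are each source's genes-in-pathway `k`
#' (`NA` = not detected); the two p-value columns come from
#' [proportion_fisher()], with not-detected sources compared at `k = 0`
#' and flagged.
#'
#' @param enrichments_by_source named list with elements `microarray`,
#'   `rnai` and `fusion`, each a (typically [filter_terms()]-filtered)
#'   `enrichment_result` computed against the same collection and
#'   universe.
#' @param collection the shared [gene_set_collection] (used for term
#'   names and a consistency check).
#' @return data.frame with columns `term_id`, `term_name`, `total_genes`,
#'   `count_microarray`, `count_rnai`, `count_fusion`,
#'   `p_fusion_vs_microarray`, `p_fusion_vs_rnai`, `nd_microarray`,
#'   `nd_rnai`, `block`.
#' @export
build_comparison_table <- function(enrichments_by_source, collection) {
  need <- c("microarray", "rnai", "fusion")
  if (!all(need %in% names(enrichments_by_source)))
    stop("enrichments_by_source must have elements: ",
         paste(need, collapse = ", "), call. = FALSE)
  stopifnot(inherits(collection, "gene_set_collection"))
  colls <- unlist(lapply(enrichments_by_source[need], attr, "collection"))
  if (length(unique(colls)) > 1L)
    stop("enrichment runs come from different collections: ",
         paste(unique(colls), collapse = " vs "), call. = FALSE)
  srcs <- enrichments_by_source[need]
  all_terms <- sort(unique(unlist(lapply(srcs, `[[`, "term_id"))))
  if (!length(all_terms))
    return(data.frame(term_id = character(), term_name = character(),
                      total_genes = integer(), count_microarray = integer(),
                      count_rnai = integer(), count_fusion = integer(),
                      p_fusion_vs_microarray = numeric(),
                      p_fusion_vs_rnai = numeric(),
                      nd_microarray = logical(), nd_rnai = logical(),
                      block = character(), stringsAsFactors = FALSE))
  get_row <- function(src, id) src[match(id, src$term_id), , drop = FALSE]
  rows <- lapply(all_terms, function(id) {
    rs <- lapply(srcs, get_row, id = id)
    Tsize <- stats::na.omit(vapply(rs, function(r) r$K[1L], numeric(1)))[1L]
    k <- vapply(rs, function(r) if (is.na(r$term_id[1L])) NA_integer_
                                else as.integer(r$k[1L]), integer(1))
    kf <- if (is.na(k[["fusion"]])) 0L else k[["fusion"]]
    p_m <- proportion_fisher(Tsize, kf, k[["microarray"]])
    p_r <- proportion_fisher(Tsize, kf, k[["rnai"]])
    block <- if (!is.na(k[["microarray"]]) && !is.na(k[["rnai"]]))
      "microarray_and_rnai"
    else if (!is.na(k[["rnai"]])) "rnai_and_fusion"
    else if (!is.na(k[["microarray"]])) "microarray_and_fusion"
    else "fusion_only"
    tn <- if (id %in% names(collection$term_names))
      unname(collection$term_names[[id]]) else id
    data.frame(term_id = id, term_name = tn, total_genes = as.integer(Tsize),
               count_microarray = k[["microarray"]],
               count_rnai = k[["rnai"]], count_fusion = k[["fusion"]],
               p_fusion_vs_microarray = as.numeric(p_m),
               p_fusion_vs_rnai = as.numeric(p_r),
               nd_microarray = is.na(k[["microarray"]]),
               nd_rnai = is.na(k[["rnai"]]),
               block = block, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  block_order <- c("microarray_and_rnai", "rnai_and_fusion",
                   "microarray_and_fusion", "fusion_only")
  out <- out[order(match(out$block, block_order), out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Pathway-level overlap across platforms
#'
#' @param term_sets named list (>= 2 elements) of post-filter term-id
#'   sets (character vectors or `enrichment_result`s, whose `term_id`
#'   column is used).
#' @return list with `sizes` (per-set term counts), `pairwise` (a
#'   data.frame of all pairwise Venn counts with `overlap_percent`),
#'   and `shared` (terms present in every set).
#' @export
pathway_overlap <- function(term_sets) {
  if (!is.list(term_sets) || length(term_sets) < 2L ||
      is.null(names(term_sets)))
    stop("term_sets must be a named list with >= 2 elements", call. = FALSE)
  sets <- lapply(term_sets, function(s)
    unique(if (is.data.frame(s)) s$term_id else as.character(s)))
  nm <- names(sets)
  combos <- utils::combn(nm, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1L, i]; b <- combos[2L, i]
    vc <- .venn_counts(length(sets[[a]]), length(sets[[b]]),
                       length(intersect(sets[[a]], sets[[b]])))
    data.frame(set_a = a, set_b = b, size_a = vc$size_a, size_b = vc$size_b,
               size_intersection = vc$size_intersection,
               size_union = vc$size_union,
               overlap_percent = vc$overlap_percent,
               stringsAsFactors = FALSE)
  }))
  list(sizes = lengths(sets), pairwise = pairwise,
       shared = Reduce(intersect, sets))
}

#' Terms shared across all species
#'
#' @param per_species_term_sets named list (>= 2 elements) of term-id
#'   sets, harmonized to one collection naming scheme.
#' @return list with `shared` (the full intersection) and `support`
#'   (logical term x species matrix over the union of terms).
#' @export
cross_species_shared_terms <- function(per_species_term_sets) {
  if (!is.list(per_species_term_sets) || length(per_species_term_sets) < 2L)
    stop("need term sets for >= 2 species", call. = FALSE)
  sets <- lapply(per_species_term_sets, function(s)
    unique(if (is.data.frame(s)) s$term_id else as.character(s)))
  union_terms <- sort(unique(unlist(sets)))
  support <- vapply(sets, function(s) union_terms %in% s,
                    logical(length(union_terms)))
  if (is.null(dim(support)))
    support <- matrix(support, nrow = length(union_terms),
                      dimnames = list(union_terms, names(sets)))
  else rownames(support) <- union_terms
  list(shared = Reduce(intersect, sets), support = support)
}
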