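# List fusion and gene-level overlap statistics.  "Fusion" is the set
# union of an RNAi-screen hit list with a DEG list (by default the
# up-regulated DEGs) taken before pathway enrichment, so that a pathway's
# essential-but-static and dynamic-but-nonessential members are tested as
# one list.

#' Fuse two gene lists by set union
#'
#' @param a,b [gene_list]s in the same namespace.
#' @return a [gene_list] with platform `"fusion"`; attribute `provenance`
#'   is a data.frame recording which source(s) contributed each member.
#' @export
fuse_lists <- function(a, b) {
  stopifnot(inherits(a, "gene_list"), inherits(b, "gene_list"))
  .check_same_namespace(a, b)
  members <- union(a$members, b$members)
  out <- gene_list(members, name = paste(a$name, b$name, sep = "+"),
                   namespace = a$namespace, platform = "fusion",
                   direction = "any",
                   timepoints = union(a$timepoints, b$timepoints))
  attr(out, "provenance") <- data.frame(
    member = out$members,
    from_a = out$members %in% a$members,
    from_b = out$members %in% b$members,
    stringsAsFactors = FALSE)
  out
}

.venn_counts <- function(size_a, size_b, size_intersection,
                         universe_size = NA_integer_,
                         intersection = character()) {
  size_union <- size_a + size_b - size_intersection
  structure(list(
    size_a = size_a, size_b = size_b,
    size_intersection = size_intersection, size_union = size_union,
    universe_size = universe_size,
    overlap_percent = if (size_union > 0) 100 * size_intersection / size_union
                      else 0,
    intersection = intersection), class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("<venn_counts> |A|=%d |B|=%d |A∩B|=%d |A∪B|=%d (%.1f%%)",
              x$size_a, x$size_b, x$size_intersection, x$size_union,
              x$overlap_percent))
  if (!is.na(x$universe_size)) cat(" universe =", x$universe_size)
  cat("\n")
  invisible(x)
}

#' Pairwise overlap (Venn) counts of two gene lists
#'
#' `overlap_percent` is `100 * |A intersect B| / |A union B|`, kept at full
#' precision; round only for presentation.
#'
#' @param a,b [gene_list]s (or character vectors) in the same namespace.
#' @param universe optional [gene_list] or character vector; when given,
#'   both lists must be subsets of it and its size is recorded.
#' @return a `venn_counts` object (sizes, union, percent, intersection
#'   members).
#' @export
venn <- function(a, b, universe = NULL) {
  .check_same_namespace(a, b)
  ma <- .as_members(a); mb <- .as_members(b)
  universe_size <- NA_integer_
  if (!is.null(universe)) {
    .check_same_namespace(a, universe, "list and universe")
    mu <- .as_members(universe)
    offenders <- setdiff(c(ma, mb), mu)
    if (length(offenders))
      stop("members outside the universe: ",
           paste(head(offenders, 5L), collapse = ", "),
           if (length(offenders) > 5L) ", ...", call. = FALSE)
    universe_size <- length(mu)
  }
  inter <- intersect(ma, mb)
  .venn_counts(length(ma), length(mb), length(inter), universe_size, inter)
}

#' Venn counts from printed sizes
#'
#' Builds a `venn_counts` record directly from `|A|`, `|B|` and
#' `|A intersect B|`, for replicating overlap arithmetic quoted in a
#' publication without the underlying membership lists.
#'
#' @param size_a,size_b,size_intersection non-negative integers with
#'   `size_intersection <= min(size_a, size_b)`.
#' @param universe_size optional positive integer.
#' @return a `venn_counts` object.
#' @examples
#' venn_from_counts(1011, 957, 78)$overlap_percent  # 4.1...
#' @export
venn_from_counts <- function(size_a, size_b, size_intersection,
                             universe_size = NA_integer_) {
  stopifnot(size_a >= 0, size_b >= 0, size_intersection >= 0)
  if (size_intersection > min(size_a, size_b))
    stop("intersection exceeds a set size", call. = FALSE)
  .venn_counts(as.integer(size_a), as.integer(size_b),
               as.integer(size_intersection), as.integer(universe_size))
}

#' Hypergeometric tail probability of a list overlap
#'
#' For two sets of sizes `size_a` and `size_b` drawn from a universe of
#' `N` genes, the overlap `X ~ Hypergeom(N, size_a, size_b)`.
#' `tail = "greater"` returns `P(X >= k)` (enrichment),
#' `tail = "less"` returns `P(X <= k)` (depletion).
#'
#' @param k observed intersection size, `k <= min(size_a, size_b)`.
#' @param size_a,size_b set sizes, each `<= N`.
#' @param N universe size.
#' @param tail `"greater"` or `"less"`.
#' @return tail probability in (0, 1\].
#' @export
overlap_enrichment_p <- function(k, size_a, size_b, N,
                                 tail = c("greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(k >= 0, size_a >= 0, size_b >= 0, N >= 1)
  if (size_a > N || size_b > N)
    stop("set sizes cannot exceed the universe size", call. = FALSE)
  if (k > min(size_a, size_b))
    stop("k cannot exceed min(size_a, size_b)", call. = FALSE)
  if (k < size_a + size_b - N)
    stop("impossible counts: k < size_a + size_b - N", call. = FALSE)
  if (tail == "greater")
    phyper(k - 1, size_a, N - size_a, size_b, lower.tail = FALSE)
  else
    phyper(k, size_a, N - size_a, size_b)
}
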