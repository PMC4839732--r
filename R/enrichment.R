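# Pathway enrichment analysis: right-tailed Fisher exact test of a gene
# list against each term of a GMT collection within an explicit universe,
# followed by Benjamini-Hochberg FDR adjustment across the collection's
# terms and threshold/blocklist filtering.

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` on the sorted p-values, clipped
#' to 1, with the input order restored on return.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Right-tailed Fisher exact enrichment of a gene list against a collection
#'
#' For each term with `K >= 1` members inside the universe, tests whether
#' the list hits the term more often than a random draw:
#' `p_right = P(X >= k)` with `X ~ Hypergeom(N, K, n)`, where `N` is the
#' universe size, `n` the list size inside the universe and `k` the
#' list-term intersection.  BH q-values are computed across all tested
#' terms of the collection.
#'
#' @param list a [gene_list]; members outside the universe are dropped
#'   (count recorded in attribute `n_dropped`).
#' @param collection a [gene_set_collection].
#' @param universe explicit gene universe ([gene_list] or character);
#'   defaults to the collection's universe.
#' @return data.frame of class `enrichment_result`, one row per term,
#'   sorted by `p_right` ascending with ties broken by `term_id`; columns
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_right`, `q`, `genes`
#'   (comma-joined contributing ids).  Attribute `collection` records the
#'   collection name.
#' @export
enrich <- function(list, collection, universe = NULL) {
  stopifnot(inherits(list, "gene_list"),
            inherits(collection, "gene_set_collection"))
  if (!identical(list$namespace, collection$namespace))
    stop(sprintf("list namespace '%s' does not match collection namespace '%s'",
                 list$namespace, collection$namespace), call. = FALSE)
  uni <- if (is.null(universe)) collection$universe else .as_members(universe)
  if (!length(uni)) stop("empty universe", call. = FALSE)
  members <- intersect(list$members, uni)
  n_dropped <- length(list$members) - length(members)
  if (!length(members))
    stop("gene list is empty after intersecting with the universe",
         call. = FALSE)
  N <- length(uni); n <- length(members)
  rows <- lapply(names(collection$terms), function(id) {
    term <- intersect(collection$terms[[id]], uni)
    K <- length(term)
    if (K == 0L) return(NULL)
    contrib <- sort(intersect(members, term))
    k <- length(contrib)
    data.frame(term_id = id,
               term_name = unname(collection$term_names[[id]]),
               k = k, K = K, n = n, N = N,
               p_right = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               genes = paste(contrib, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no terms overlap the universe", call. = FALSE)
  out$q <- bh_fdr(out$p_right)
  out <- out[order(out$p_right, out$term_id),
             c("term_id", "term_name", "k", "K", "n", "N", "p_right", "q",
               "genes")]
  rownames(out) <- NULL
  attr(out, "collection") <- collection$name
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter enriched terms by p, FDR and a name blocklist
#'
#' Retains rows with `p_right < p_max` and `q < fdr_max` whose term name
#' matches no blocklist pattern.  Patterns containing `*` or `?` are
#' treated as anchored globs, all others as case-insensitive substrings —
#' typically used to drop uninformative disease- or cell-line-specific
#' terms from curated knowledgebases.
#'
#' @param rows an `enrichment_result` from [enrich()].
#' @param p_max,fdr_max thresholds (defaults 0.05 and 0.10).
#' @param blocklist character vector of patterns, or a path to a text
#'   file with one pattern per line (`#` comments allowed); empty by
#'   default.
#' @return the retained rows; attribute `removed` is a data.frame of
#'   `term_id` and `reason` (`"p"`, `"fdr"` or `"blocklist"`).
#' @export
filter_terms <- function(rows, p_max = 0.05, fdr_max = 0.10,
                         blocklist = character()) {
  stopifnot(inherits(rows, "data.frame"))
  if (is.character(blocklist) && length(blocklist) == 1L &&
      file.exists(blocklist)) {
    blocklist <- trimws(readLines(blocklist, warn = FALSE))
    blocklist <- blocklist[nzchar(blocklist) & !startsWith(blocklist, "#")]
  }
  blocked <- rep(FALSE, nrow(rows))
  for (pat in blocklist) {
    hit <- if (grepl("[*?]", pat)) {
      tryCatch(grepl(glob2rx(pat), rows$term_name, ignore.case = TRUE),
               error = function(e)
                 stop("malformed blocklist pattern '", pat, "': ",
                      conditionMessage(e), call. = FALSE))
    } else {
      grepl(tolower(pat), tolower(rows$term_name), fixed = TRUE)
    }
    blocked <- blocked | hit
  }
  reason <- rep(NA_character_, nrow(rows))
  reason[blocked] <- "blocklist"
  reason[rows$q >= fdr_max] <- "fdr"
  reason[rows$p_right >= p_max] <- "p"
  keep <- is.na(reason)
  removed <- data.frame(term_id = rows$term_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  attr(out, "collection") <- attr(rows, "collection")
  class(out) <- class(rows)
  out
}

#' Write an enrichment result as TSV
#'
#' @param rows an `enrichment_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(as.data.frame(rows), con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(path)
}
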