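#' Construct an ortholog map
#'
#' A deduplicated, possibly many-to-many set of (source, target) gene-id
#' pairs bridging two namespaces (e.g. FlyBase ids to human symbols).
#'
#' @param pairs data.frame with columns `source` and `target`.
#' @param source_namespace,target_namespace namespace tags of the two
#'   sides; must differ.
#' @return an object of class `ortholog_map` with a `summary` field
#'   counting 1:1, 1:many, many:1 and many:many relations.
#' @export
ortholog_map <- function(pairs, source_namespace, target_namespace) {
  .check_namespace(source_namespace)
  .check_namespace(target_namespace)
  if (identical(source_namespace, target_namespace))
    stop("source and target namespaces must differ", call. = FALSE)
  pairs <- data.frame(source = trimws(as.character(pairs$source)),
                      target = trimws(as.character(pairs$target)),
                      stringsAsFactors = FALSE)
  pairs <- pairs[nzchar(pairs$source) & nzchar(pairs$target), , drop = FALSE]
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  src_deg <- table(pairs$source)   # targets per source
  tgt_deg <- table(pairs$target)   # sources per target
  s_multi <- pairs$source %in% names(src_deg)[src_deg > 1L]
  t_multi <- pairs$target %in% names(tgt_deg)[tgt_deg > 1L]
  summary <- c(one_to_one   = sum(!s_multi & !t_multi),
               one_to_many  = sum(s_multi & !t_multi),
               many_to_one  = sum(!s_multi & t_multi),
               many_to_many = sum(s_multi & t_multi))
  structure(list(pairs = pairs,
                 source_namespace = source_namespace,
                 target_namespace = target_namespace,
                 summary = summary),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d pairs: %s -> %s\n", nrow(x$pairs),
              x$source_namespace, x$target_namespace))
  print(x$summary)
  invisible(x)
}

#' Read an ortholog map from a two-column TSV
#'
#' @param path TSV with exactly two tab-separated fields per row
#'   (source id, target id); an optional header row is skipped when
#'   `header = TRUE`.
#' @param source_namespace,target_namespace namespace tags.
#' @param header whether the first row is a header.
#' @return an [ortholog_map].
#' @export
read_ortholog_map <- function(path, source_namespace, target_namespace,
                              header = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (header && length(lines)) { lines <- lines[-1L]; offset <- 1L }
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nbad <- which(lengths(fields) != 2L)
  if (length(nbad))
    stop(sprintf("ortholog map parse error at line %d: expected 2 tab-separated fields, found %d",
                 nbad[1L] + offset, length(fields[[nbad[1L]]])), call. = FALSE)
  mat <- do.call(rbind, fields)
  ortholog_map(data.frame(source = mat[, 1L], target = mat[, 2L],
                          stringsAsFactors = FALSE),
               source_namespace, target_namespace)
}

#' Map a gene list across namespaces through an ortholog table
#'
#' @param list a [gene_list] in the map's source namespace.
#' @param map an [ortholog_map].
#' @param policy how to treat genes with several targets:
#'   `"expand"` (default; keep all targets, deduplicated),
#'   `"first"` (lexicographically smallest target), or
#'   `"drop_ambiguous"` (discard multi-target genes).
#' @return a [gene_list] in the target namespace; attribute
#'   `mapping_summary` records mapped / unmapped / ambiguous-dropped
#'   counts.
#' @export
map_namespace <- function(list, map, policy = c("expand", "first",
                                                "drop_ambiguous")) {
  policy <- match.arg(policy)
  stopifnot(inherits(list, "gene_list"), inherits(map, "ortholog_map"))
  if (!identical(list$namespace, map$source_namespace))
    stop(sprintf("list namespace '%s' does not match map source namespace '%s'",
                 list$namespace, map$source_namespace), call. = FALSE)
  tgt_by_src <- split(map$pairs$target, map$pairs$source)
  hits <- list$members %in% names(tgt_by_src)
  n_unmapped <- sum(!hits)
  mapped <- tgt_by_src[list$members[hits]]
  n_ambiguous <- sum(lengths(mapped) > 1L)
  members <- switch(policy,
    expand = unlist(mapped, use.names = FALSE),
    first = vapply(mapped, function(t) sort(t)[1L], character(1)),
    drop_ambiguous = unlist(mapped[lengths(mapped) == 1L], use.names = FALSE)
  )
  out <- gene_list(members, name = paste0(list$name, "_mapped"),
                   namespace = map$target_namespace,
                   platform = list$platform, direction = list$direction,
                   timepoints = list$timepoints)
  attr(out, "mapping_summary") <- c(
    input = length(list$members), mapped = sum(hits),
    unmapped = n_unmapped, ambiguous = n_ambiguous,
    dropped_ambiguous = if (policy == "drop_ambiguous") n_ambiguous else 0L,
    output = length(out$members))
  out
}

#' Write an ortholog map as a two-column TSV
#'
#' @param x an [ortholog_map].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(x, path) {
  stopifnot(inherits(x, "ortholog_map"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(x$pairs$source, x$pairs$target, sep = "\t"), con = con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}
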