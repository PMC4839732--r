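#' Construct a gene-set (pathway) collection
#'
#' Named pathway terms mapped to member gene sets, together with the
#' analysis universe the enrichment test conditions on.
#'
#' @param terms named list of character vectors; names are term ids,
#'   values the member gene ids (deduplicated).
#' @param term_names optional character vector of human-readable term
#'   descriptions, same names as `terms`; defaults to the term ids.
#' @param universe explicit gene universe; defaults to the union of all
#'   term members.
#' @param name collection label.
#' @param namespace gene-id namespace tag.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, term_names = NULL, universe = NULL,
                                name = "collection", namespace = "symbol") {
  .check_namespace(namespace)
  if (!is.list(terms) || is.null(names(terms)) || !all(nzchar(names(terms))))
    stop("terms must be a named list of member vectors", call. = FALSE)
  if (anyDuplicated(names(terms)))
    stop("duplicate term ids: ",
         paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "),
         call. = FALSE)
  terms <- lapply(terms, function(m) unique(trimws(as.character(m))))
  empty <- names(terms)[lengths(terms) == 0L]
  if (length(empty))
    stop("terms with no members: ", paste(empty, collapse = ", "),
         call. = FALSE)
  if (is.null(term_names)) {
    term_names <- setNames(names(terms), names(terms))
  } else {
    term_names <- setNames(as.character(term_names), names(terms))
  }
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  universe <- unique(trimws(as.character(universe)))
  structure(list(name = name, namespace = namespace, terms = terms,
                 term_names = term_names, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection '%s'> %d terms, universe %d genes [%s]\n",
              x$name, length(x$terms), length(x$universe), x$namespace))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$terms)

#' Replace the analysis universe of a collection
#'
#' @param collection a [gene_set_collection].
#' @param universe character vector or [gene_list] of gene ids.
#' @return the collection with the new universe.
#' @export
set_universe <- function(collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  collection$universe <- .as_members(universe)
  collection
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the standard tab-separated gene-set exchange format: one term
#' per line, fields `term_id`, `description`, then one member id per
#' remaining field.
#'
#' @param path GMT file.
#' @inheritParams gene_set_collection
#' @return a [gene_set_collection]; the universe defaults to the union of
#'   all members (override with [set_universe()]).
#' @export
read_gmt <- function(path, name = basename(path), namespace = "symbol") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  terms <- list(); term_names <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: need >= 3 tab-separated fields (term_id, description, members...)",
                   i), call. = FALSE)
    id <- trimws(f[1L])
    if (id %in% names(terms))
      stop(sprintf("GMT parse error at line %d: duplicate term id '%s'",
                   i, id), call. = FALSE)
    terms[[id]] <- unique(trimws(f[-(1:2)]))
    term_names[id] <- trimws(f[2L])
  }
  gene_set_collection(terms, term_names = term_names, name = name,
                      namespace = namespace)
}

#' Write a gene-set collection as GMT (UTF-8, LF endings)
#'
#' @param x a [gene_set_collection].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$terms), function(id) {
    paste(c(id, x$term_names[[id]], x$terms[[id]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
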