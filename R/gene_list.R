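# Gene identifier namespaces are matched by exact string within a registered
# tag; FlyBase ids are case-sensitive so no case folding is ever applied.

.ns_registry <- new.env(parent = emptyenv())
.default_namespaces <- c(
  "symbol", "FBgn", "ensembl", "entrez", "uniprot", "orf",
  "human_symbol", "mouse_symbol", "syn", "syn_target"
)

.known_namespaces <- function() {
  c(.default_namespaces, ls(.ns_registry))
}

#' Register an additional gene-identifier namespace
#'
#' The built-in registry covers the tags used by the shipped readers and the
#' synthetic generator (`"symbol"`, `"FBgn"`, `"ensembl"`, `"entrez"`,
#' `"uniprot"`, `"orf"`, `"human_symbol"`, `"mouse_symbol"`, `"syn"`,
#' `"syn_target"`).  Use this to admit project-specific tags.
#'
#' @param namespace character tag(s) to register.
#' @return the full set of known namespaces, invisibly.
#' @export
register_namespace <- function(namespace) {
  stopifnot(is.character(namespace), all(nzchar(namespace)))
  for (ns in namespace) assign(ns, TRUE, envir = .ns_registry)
  invisible(.known_namespaces())
}

.check_namespace <- function(namespace) {
  if (!is.character(namespace) || length(namespace) != 1L || !nzchar(namespace))
    stop("namespace must be a single non-empty string", call. = FALSE)
  if (!namespace %in% .known_namespaces())
    stop("unregistered namespace '", namespace,
         "'; see register_namespace()", call. = FALSE)
  namespace
}

#' Construct a gene list
#'
#' An ordered, deduplicated set of gene identifiers in a single namespace,
#' carrying provenance: which platform produced it (expression profiling,
#' RNAi screen, or their fusion), the regulation direction it represents,
#' and the treatment timepoints (hours) it covers.
#'
#' @param members character vector of gene ids; whitespace is trimmed,
#'   empty strings dropped, duplicates collapsed keeping first occurrence.
#' @param name list label.
#' @param namespace registered identifier namespace tag.
#' @param platform one of `"expression"`, `"rnai"`, `"fusion"`.
#' @param direction one of `"any"`, `"up"`, `"down"`.
#' @param timepoints numeric hours the list refers to (may be empty).
#' @return an object of class `gene_list`.
#' @examples
#' gene_list(c("Gclc", "GstE3", "Gclc"), name = "demo")
#' @export
gene_list <- function(members = character(),
                      name = "gene_list",
                      namespace = "symbol",
                      platform = c("expression", "rnai", "fusion"),
                      direction = c("any", "up", "down"),
                      timepoints = numeric()) {
  platform <- match.arg(platform)
  direction <- match.arg(direction)
  .check_namespace(namespace)
  members <- trimws(as.character(members))
  members <- unique(members[nzchar(members)])
  structure(
    list(name = as.character(name)[1L],
         namespace = namespace,
         members = members,
         platform = platform,
         direction = direction,
         timepoints = sort(unique(as.numeric(timepoints)))),
    class = "gene_list"
  )
}

#' @export
length.gene_list <- function(x) length(x$members)

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list '%s'> %d ids [%s] platform=%s direction=%s\n",
              x$name, length(x$members), x$namespace, x$platform,
              x$direction))
  if (length(x$timepoints))
    cat("  timepoints:", paste(x$timepoints, collapse = ", "), "h\n")
  cat("  ", paste(head(x$members, 6L), collapse = ", "),
      if (length(x$members) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

.as_members <- function(x) {
  if (inherits(x, "gene_list")) x$members else unique(trimws(as.character(x)))
}

.check_same_namespace <- function(a, b, what = "gene lists") {
  if (inherits(a, "gene_list") && inherits(b, "gene_list") &&
      !identical(a$namespace, b$namespace))
    stop(sprintf("namespace mismatch between %s: '%s' vs '%s'",
                 what, a$namespace, b$namespace), call. = FALSE)
  invisible(TRUE)
}

#' Read a gene list from a one-id-per-line text file
#'
#' @param path file with one identifier per line; blank lines and lines
#'   starting with `#` are skipped.
#' @inheritParams gene_list
#' @return a [gene_list].
#' @export
read_gene_list <- function(path, name = basename(path), namespace = "symbol",
                           platform = "expression", direction = "any",
                           timepoints = numeric()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_list(lines, name = name, namespace = namespace, platform = platform,
            direction = direction, timepoints = timepoints)
}

#' Write a gene list as one id per line (UTF-8, LF endings)
#'
#' @param x a [gene_list].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_list"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(x$members, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
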