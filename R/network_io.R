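#' Construct an interaction network
#'
#' An undirected gene/protein interaction network with per-edge confidence
#' in \[0, 1\] (STRING combined score / 1000).  Self-loops are removed and
#' duplicated pairs collapsed keeping the maximum confidence, matching
#' STRING conventions.  Backed by an igraph graph (field `graph`).
#'
#' @param edges data.frame with columns `from`, `to`, `confidence`.
#' @param nodes optional character vector of node ids (to keep isolated
#'   nodes); defaults to the edge endpoints.
#' @param namespace gene-id namespace tag.
#' @return an object of class `interaction_network`.
#' @export
interaction_network <- function(edges, nodes = NULL, namespace = "symbol") {
  .check_namespace(namespace)
  edges <- data.frame(from = trimws(as.character(edges$from)),
                      to = trimws(as.character(edges$to)),
                      confidence = as.numeric(edges$confidence),
                      stringsAsFactors = FALSE)
  if (any(is.na(edges$confidence)) ||
      any(edges$confidence < 0) || any(edges$confidence > 1))
    stop("edge confidences must lie in [0, 1]", call. = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # drop self-loops
  # canonical order so undirected duplicates collapse
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, sep = "\r")
    conf <- tapply(edges$confidence, key, max)
    uk <- strsplit(names(conf), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(uk, `[`, character(1), 1L),
                        to = vapply(uk, `[`, character(1), 2L),
                        confidence = as.numeric(conf),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  vnames <- sort(unique(c(edges$from, edges$to, trimws(as.character(nodes)))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = vnames))
  igraph::V(g)$category <- "none"
  igraph::V(g)$mass <- 0
  structure(list(graph = g, namespace = namespace),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<interaction_network> %d nodes, %d edges [%s]\n",
              igraph::vcount(g), igraph::ecount(g), x$namespace))
  cats <- table(igraph::V(g)$category)
  if (any(names(cats) != "none"))
    cat("  categories:", paste(names(cats), cats, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Node ids of an interaction network
#' @param net an [interaction_network].
#' @return character vector of node ids.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::V(net$graph)$name
}

#' Edge table of an interaction network
#' @param net an [interaction_network].
#' @return data.frame with columns `from`, `to`, `confidence`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  el <- igraph::as_edgelist(net$graph)
  data.frame(from = el[, 1L], to = el[, 2L],
             confidence = igraph::E(net$graph)$confidence,
             stringsAsFactors = FALSE)
}

#' Read a STRING protein-links file into an interaction network
#'
#' Accepts the STRING protein-links dialect: whitespace-separated columns
#' `protein1 protein2 combined_score` with the combined score as an
#' integer in 0-1000.  Scores are divided by 1000; edges below
#' `min_confidence` are dropped; duplicated pairs keep the maximum score;
#' nodes left without edges are dropped unless `keep_isolated`.
#'
#' @param path STRING links file (optionally with a header row).
#' @param min_confidence minimum combined confidence in \[0, 1\];
#'   0.400 ("medium") and 0.700 ("high") are the conventional cutoffs.
#' @param keep_isolated keep nodes whose every edge fell below the cutoff.
#' @param namespace gene-id namespace tag.
#' @return an [interaction_network].
#' @export
read_string_links <- function(path, min_confidence = 0.4,
                              keep_isolated = FALSE, namespace = "symbol") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!is.numeric(min_confidence) || length(min_confidence) != 1L ||
      is.na(min_confidence) || min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must be a single number in [0, 1]", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty STRING links file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("STRING links parse error at line %d: expected 3 columns",
                 bad[1L]), call. = FALSE)
  mat <- do.call(rbind, lapply(fields, `[`, 1:3))
  # tolerate a header row
  if (suppressWarnings(is.na(as.numeric(mat[1L, 3L])))) mat <- mat[-1L, , drop = FALSE]
  if (!nrow(mat)) stop("no data rows in STRING links file", call. = FALSE)
  score <- suppressWarnings(as.numeric(mat[, 3L]))
  if (any(is.na(score)) || any(score != round(score)) ||
      any(score < 0) || any(score > 1000))
    stop("combined_score must be an integer in 0-1000", call. = FALSE)
  all_nodes <- unique(c(mat[, 1L], mat[, 2L]))
  keep <- score / 1000 >= min_confidence
  edges <- data.frame(from = mat[keep, 1L], to = mat[keep, 2L],
                      confidence = score[keep] / 1000,
                      stringsAsFactors = FALSE)
  interaction_network(edges,
                      nodes = if (keep_isolated) all_nodes else NULL,
                      namespace = namespace)
}
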