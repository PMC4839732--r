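#' Construct an annotated expression matrix
#'
#' Genes x samples abundances with per-sample (condition, timepoint,
#' replicate) annotations.  Storage is linear scale (RPKM or array
#' intensity); log2 transformation happens inside the testing functions.
#'
#' @param values numeric matrix, rownames = gene ids, one column per sample.
#' @param samples data.frame with columns `condition` (`"control"` or
#'   `"treated"`), `timepoint` (hours, >= 0) and `replicate` (positive
#'   integer); one row per column of `values`.
#' @param namespace gene-id namespace tag.
#' @param scale_tag `"linear"` (default) or `"log2"`; linear matrices must
#'   be non-negative.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, namespace = "symbol",
                              scale_tag = c("linear", "log2")) {
  scale_tag <- match.arg(scale_tag)
  .check_namespace(namespace)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("values must have gene ids as rownames", call. = FALSE)
  rn <- trimws(rownames(values))
  dup <- unique(rn[duplicated(rn)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(head(dup, 5L), collapse = ", "),
         call. = FALSE)
  rownames(values) <- rn
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("condition", "timepoint", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples must have columns condition, timepoint, replicate",
         call. = FALSE)
  if (nrow(samples) != ncol(values))
    stop("samples rows (", nrow(samples), ") != matrix columns (",
         ncol(values), ")", call. = FALSE)
  if (!all(samples$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'", call. = FALSE)
  samples$timepoint <- as.numeric(samples$timepoint)
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$timepoint < 0) || any(is.na(samples$timepoint)))
    stop("timepoints must be numeric hours >= 0", call. = FALSE)
  if (any(samples$replicate < 1L) || any(is.na(samples$replicate)))
    stop("replicates must be positive integers", call. = FALSE)
  key <- paste(samples$condition, samples$timepoint, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicate (condition, timepoint, replicate) triples: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  if (scale_tag == "linear" && any(values < 0))
    stop("negative abundances in a linear-scale matrix", call. = FALSE)
  colnames(values) <- paste(samples$condition, samples$timepoint,
                            samples$replicate, sep = "_")
  structure(list(values = values, samples = samples, namespace = namespace,
                 scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s scale, %s)\n",
              nrow(x$values), ncol(x$values), x$scale_tag, x$namespace))
  tp <- sort(unique(x$samples$timepoint))
  cat("  timepoints:", paste(tp, collapse = ", "), "h;",
      "conditions:", paste(sort(unique(x$samples$condition)), collapse = "/"),
      "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

.em_timepoints <- function(x) sort(unique(x$samples$timepoint))

.em_cols <- function(x, condition, timepoint) {
  which(x$samples$condition == condition & x$samples$timepoint == timepoint)
}

# Parse a sample header of the form <condition>_<timepoint>_<replicate>,
# e.g. "treated_8_2".  Returns the samples data.frame or stops naming the
# offending column.
.parse_sample_headers <- function(headers) {
  parts <- strsplit(headers, "_", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 3L, logical(1))
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != 3L)
      stop("cannot parse sample column '", headers[i],
           "' (expected condition_timepoint_replicate)", call. = FALSE)
    tp <- suppressWarnings(as.numeric(p[2L]))
    rep <- suppressWarnings(as.integer(p[3L]))
    if (is.na(tp) || is.na(rep))
      stop("cannot parse sample column '", headers[i],
           "' (expected condition_timepoint_replicate)", call. = FALSE)
    data.frame(condition = p[1L], timepoint = tp, replicate = rep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read an annotated expression matrix from a TSV file
#'
#' The first column holds gene ids.  Sample annotations come either from
#' the header micro-grammar `condition_timepoint_replicate` (e.g.
#' `treated_8_2`) or from a sidecar TSV with columns `sample`, `condition`,
#' `timepoint`, `replicate` keyed by header name.
#'
#' @param path TSV file.
#' @param annotation `"header"` (default) or `"sidecar"`.
#' @param sidecar path to the sidecar annotation TSV when
#'   `annotation = "sidecar"`.
#' @inheritParams expression_matrix
#' @return an [expression_matrix].
#' @export
read_expression_table <- function(path, annotation = c("header", "sidecar"),
                                  sidecar = NULL, namespace = "symbol",
                                  scale_tag = "linear") {
  annotation <- match.arg(annotation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs >= 1 sample column",
                           call. = FALSE)
  ids <- trimws(as.character(tab[[1L]]))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene rows: ", paste(head(dup, 5L), collapse = ", "),
         call. = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  headers <- colnames(values)
  samples <- if (annotation == "header") {
    .parse_sample_headers(headers)
  } else {
    if (is.null(sidecar)) stop("sidecar annotation file required",
                               call. = FALSE)
    ann <- read.delim(sidecar, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("sample", "condition", "timepoint", "replicate")
    if (!all(need %in% names(ann)))
      stop("sidecar must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    miss <- setdiff(headers, ann$sample)
    if (length(miss))
      stop("sidecar is missing annotations for column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    ann[match(headers, ann$sample), c("condition", "timepoint", "replicate")]
  }
  if (any(is.na(values)))
    stop("missing values in expression table", call. = FALSE)
  expression_matrix(values, samples, namespace = namespace,
                    scale_tag = scale_tag)
}

#' Write an expression matrix as a TSV with self-describing headers
#'
#' Columns are named `condition_timepoint_replicate`, so the file
#' round-trips through [read_expression_table()] exactly.
#'
#' @param x an [expression_matrix].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
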