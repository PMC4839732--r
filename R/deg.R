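# Differential-expression rule: Welch two-sample t-test on
# log2(abundance + pseudo), control vs treated, combined with a signed
# fold-change threshold on linear group means.  No multiple-testing
# correction is applied at this stage.

#' Remove genes with low abundance in both conditions
#'
#' A gene is kept iff its mean linear abundance reaches `floor` in at
#' least one (condition, timepoint) group — i.e. genes below the floor in
#' both control and treated arms everywhere are dropped.  The RNA-seq
#' convention is RPKM < 2 in both conditions.
#'
#' @param matrix a linear-scale [expression_matrix].
#' @param floor abundance floor (default 2, the RPKM rule).
#' @return the filtered [expression_matrix]; attribute `removed` lists the
#'   dropped gene ids.
#' @export
filter_low_expression <- function(matrix, floor = 2) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale_tag != "linear")
    stop("filter_low_expression requires a linear-scale matrix", call. = FALSE)
  if (!is.numeric(floor) || floor < 0)
    stop("floor must be >= 0", call. = FALSE)
  grp <- interaction(matrix$samples$condition, matrix$samples$timepoint,
                     drop = TRUE)
  any_high <- rep(FALSE, nrow(matrix$values))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    any_high <- any_high |
      rowMeans(matrix$values[, cols, drop = FALSE]) >= floor
  }
  removed <- rownames(matrix$values)[!any_high]
  matrix$values <- matrix$values[any_high, , drop = FALSE]
  attr(matrix, "removed") <- removed
  matrix
}

#' Signed fold change between two linear-scale group means
#'
#' Computes `f = (treated + pseudo) / (control + pseudo)` and returns `f`
#' when `f >= 1` and `-1/f` otherwise, so the magnitude is always >= 1 and
#' the sign encodes direction (+ up in treated, - down).
#'
#' @param control_mean,treated_mean non-negative linear means (vectorized).
#' @param pseudo positive pseudo-count guarding against zeros.
#' @return signed fold change(s).
#' @examples
#' signed_fold(10, 40, pseudo = 1e-9)  # +4
#' signed_fold(40, 10, pseudo = 1e-9)  # -4
#' @export
signed_fold <- function(control_mean, treated_mean, pseudo = 0.1) {
  if (any(control_mean < 0) || any(treated_mean < 0))
    stop("group means must be non-negative", call. = FALSE)
  if (!is.numeric(pseudo) || pseudo <= 0)
    stop("pseudo must be > 0", call. = FALSE)
  f <- (treated_mean + pseudo) / (control_mean + pseudo)
  ifelse(f >= 1, f, -1 / f)
}

# Vectorized Welch two-sample t-test over matrix rows.
# Returns two-sided p-values; rows where both groups have zero variance
# get p = 1 when the means are equal and p = 0 otherwise.
.welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, length(m1))
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  ok <- !degenerate
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1L) + (v2[ok] / n2)^2 / (n2 - 1L))
  p[ok] <- 2 * pt(-abs(tstat), df)
  p
}

#' Test control vs treated at one timepoint
#'
#' Per gene: Welch (unequal-variance) two-sample t-test on
#' `log2(value + pseudo)`, two-sided, plus [signed_fold()] on the linear
#' group means.  A gene passes iff `p < p_threshold` and
#' `|signed_fold| > fold_threshold`.
#'
#' @param matrix a linear-scale [expression_matrix] with >= 2 replicates
#'   per condition at `timepoint`.
#' @param timepoint hours; must be present in the matrix.
#' @param p_threshold,fold_threshold,pseudo rule parameters (defaults
#'   0.05, 2, 0.1).
#' @return data.frame (one row per gene) with columns `gene`, `timepoint`,
#'   `control_mean`, `treated_mean`, `signed_fold`, `p_value`, `passes`.
#' @export
test_timepoint <- function(matrix, timepoint, p_threshold = 0.05,
                           fold_threshold = 2, pseudo = 0.1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale_tag != "linear")
    stop("test_timepoint requires a linear-scale matrix", call. = FALSE)
  tps <- .em_timepoints(matrix)
  if (!timepoint %in% tps)
    stop("timepoint ", timepoint, " not present; available: ",
         paste(tps, collapse = ", "), call. = FALSE)
  cc <- .em_cols(matrix, "control", timepoint)
  tc <- .em_cols(matrix, "treated", timepoint)
  if (length(cc) < 2L || length(tc) < 2L)
    stop("need >= 2 replicates per condition at timepoint ", timepoint,
         call. = FALSE)
  ctrl <- matrix$values[, cc, drop = FALSE]
  trt <- matrix$values[, tc, drop = FALSE]
  p <- .welch_rows(log2(ctrl + pseudo), log2(trt + pseudo))
  cm <- rowMeans(ctrl); tm <- rowMeans(trt)
  sf <- signed_fold(cm, tm, pseudo = pseudo)
  data.frame(gene = rownames(matrix$values), timepoint = timepoint,
             control_mean = cm, treated_mean = tm, signed_fold = sf,
             p_value = p,
             passes = p < p_threshold & abs(sf) > fold_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes across timepoints
#'
#' A gene enters the `up` list iff it passes the rule with
#' `signed_fold > fold_threshold` at >= 1 requested timepoint, and the
#' `down` list analogously; timepoint-specific lists are combined by
#' union, mirroring pooling of e.g. 8/24/72 h DEGs into one list before
#' enrichment.  A gene may land in both lists (up at one timepoint, down
#' at another); such genes are flagged in the record table.
#'
#' @inheritParams test_timepoint
#' @param timepoints hours to test and pool (non-empty).
#' @param floor abundance floor applied via [filter_low_expression()]
#'   before testing; `NULL` skips filtering.
#' @return list with elements `up` and `down` ([gene_list]s carrying
#'   timepoint provenance), and `records` (the per-gene, per-timepoint
#'   data.frame with a `both_directions` flag).
#' @export
call_degs <- function(matrix, timepoints, p_threshold = 0.05,
                      fold_threshold = 2, pseudo = 0.1, floor = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  timepoints <- unique(as.numeric(timepoints))
  if (!length(timepoints)) stop("empty timepoint set", call. = FALSE)
  missing_tp <- setdiff(timepoints, .em_timepoints(matrix))
  if (length(missing_tp))
    stop("timepoint(s) not present: ", paste(missing_tp, collapse = ", "),
         "; available: ", paste(.em_timepoints(matrix), collapse = ", "),
         call. = FALSE)
  if (!is.null(floor)) matrix <- filter_low_expression(matrix, floor = floor)
  records <- do.call(rbind, lapply(timepoints, function(tp)
    test_timepoint(matrix, tp, p_threshold = p_threshold,
                   fold_threshold = fold_threshold, pseudo = pseudo)))
  pass <- records[records$passes, , drop = FALSE]
  up_ids <- unique(pass$gene[pass$signed_fold > fold_threshold])
  down_ids <- unique(pass$gene[pass$signed_fold < -fold_threshold])
  both <- intersect(up_ids, down_ids)
  records$both_directions <- records$gene %in% both
  if (length(both))
    warning(length(both),
            " gene(s) pass in both directions across timepoints",
            call. = FALSE)
  ns <- matrix$namespace
  list(
    up = gene_list(up_ids, name = "deg_up", namespace = ns,
                   platform = "expression", direction = "up",
                   timepoints = timepoints),
    down = gene_list(down_ids, name = "deg_down", namespace = ns,
                     platform = "expression", direction = "down",
                     timepoints = timepoints),
    records = records
  )
}
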