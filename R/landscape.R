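# Interaction-network annotation and mass-conserving expression
# landscapes.  Per-gene expression mass is distributed over a 2D network
# layout with truncated-and-renormalized Gaussian kernels (optionally also
# along edges), so that the grid total equals the deposited mass exactly —
# the testable contract replacing the undocumented interpolation of
# legacy landscape tools.

#' Annotate network nodes with hit / DEG status
#'
#' Each node receives a category: `"hit_and_deg"` when in the hit list and
#' either DEG list, else `"hit"`, `"deg_up"`, `"deg_down"` or `"none"`.
#' Genes present in both DEG lists count as DEG for the purpose of the
#' `hit_and_deg` rule; pure DEG nodes in both lists are labelled
#' `"deg_up"` (up takes precedence).  Idempotent.
#'
#' @param net an [interaction_network].
#' @param deg_up,deg_down,hits [gene_list]s in the network's namespace.
#' @return the annotated [interaction_network].
#' @export
annotate_network <- function(net, deg_up, deg_down, hits) {
  stopifnot(inherits(net, "interaction_network"))
  for (l in list(deg_up, deg_down, hits)) {
    if (inherits(l, "gene_list") && !identical(l$namespace, net$namespace))
      stop(sprintf("list namespace '%s' does not match network namespace '%s'",
                   l$namespace, net$namespace), call. = FALSE)
  }
  nodes <- network_nodes(net)
  in_hit <- nodes %in% .as_members(hits)
  in_up <- nodes %in% .as_members(deg_up)
  in_down <- nodes %in% .as_members(deg_down)
  category <- rep("none", length(nodes))
  category[in_up] <- "deg_up"
  category[in_down & !in_up] <- "deg_down"
  category[in_hit] <- "hit"
  category[in_hit & (in_up | in_down)] <- "hit_and_deg"
  igraph::V(net$graph)$category <- category
  net
}

#' Deterministic force-directed layout in the unit square
#'
#' Vertices are canonically ordered by id and each connected component is
#' laid out with the Fruchterman-Reingold algorithm under a fixed RNG
#' seed, then rescaled into its cell of a square grid packing (largest
#' component first).  The same graph and seed always give identical
#' coordinates, regardless of input vertex order.
#'
#' @param net an [interaction_network] (non-empty).
#' @param seed integer RNG seed.
#' @return data.frame with columns `node`, `x`, `y`; coordinates in
#'   \[0, 1\]^2.
#' @export
layout_network <- function(net, seed = 1L) {
  stopifnot(inherits(net, "interaction_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  perm <- order(igraph::V(g)$name)
  g <- igraph::permute(g, order(perm))  # canonical vertex order by name
  comp <- igraph::components(g)
  # components ordered by size (desc), ties by smallest member id
  comp_ids <- seq_len(comp$no)
  first_name <- vapply(comp_ids, function(ci)
    min(igraph::V(g)$name[comp$membership == ci]), character(1))
  comp_ids <- comp_ids[order(-comp$csize, first_name)]
  ncell <- ceiling(sqrt(length(comp_ids)))
  cell <- 1 / ncell
  margin <- 0.08 * cell
  set.seed(seed)
  out <- vector("list", length(comp_ids))
  for (i in seq_along(comp_ids)) {
    ci <- comp_ids[i]
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    xy <- if (igraph::vcount(sub) == 1L) matrix(0.5, 1L, 2L)
          else igraph::layout_with_fr(sub)
    # rescale to [0,1] within the component, guard constant axes
    rng <- apply(xy, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    xy <- sweep(sweep(xy, 2L, rng[1L, ]), 2L, span, "/")
    row <- (i - 1L) %/% ncell; col <- (i - 1L) %% ncell
    out[[i]] <- data.frame(
      node = igraph::V(sub)$name,
      x = col * cell + margin + xy[, 1L] * (cell - 2 * margin),
      y = row * cell + margin + xy[, 2L] * (cell - 2 * margin),
      stringsAsFactors = FALSE)
  }
  coords <- do.call(rbind, out)
  coords <- coords[order(coords$node), ]
  rownames(coords) <- NULL
  coords
}

#' Per-node expression mass from a matrix
#'
#' Node mass is the mean of replicate linear-scale values for the chosen
#' condition/timepoint; network genes absent from the matrix get mass 0
#' with a warning.
#'
#' @param net an [interaction_network].
#' @param matrix a linear-scale [expression_matrix].
#' @param condition,timepoint sample group to average.
#' @return named numeric vector of masses over the network nodes.
#' @export
node_mass_from_matrix <- function(net, matrix, condition = "treated",
                                  timepoint) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(matrix, "expression_matrix"))
  cols <- .em_cols(matrix, condition, timepoint)
  if (!length(cols))
    stop("no samples for ", condition, " at ", timepoint, " h", call. = FALSE)
  means <- rowMeans(matrix$values[, cols, drop = FALSE])
  nodes <- network_nodes(net)
  mass <- setNames(rep(0, length(nodes)), nodes)
  found <- intersect(nodes, names(means))
  mass[found] <- means[found]
  if (length(found) < length(nodes))
    warning(length(nodes) - length(found),
            " network gene(s) absent from the matrix; mass set to 0",
            call. = FALSE)
  mass
}

# Deposit Gaussian kernels at points (x, y) with per-point masses onto an
# nx x ny grid over [0,1]^2.  Kernels are separable; each is renormalized
# over the truncated grid so every point contributes exactly its mass.
.deposit <- function(x, y, mass, nx, ny, bandwidth) {
  cx <- (seq_len(nx) - 0.5) / nx
  cy <- (seq_len(ny) - 0.5) / ny
  wx <- exp(-outer(x, cx, function(a, b) (a - b)^2) / (2 * bandwidth^2))
  wy <- exp(-outer(y, cy, function(a, b) (a - b)^2) / (2 * bandwidth^2))
  norm <- rowSums(wx) * rowSums(wy)
  scaled <- mass / norm
  # grid[i, j] = sum_p scaled_p * wy[p, i] * wx[p, j]  (rows = y, cols = x)
  t(wy * scaled) %*% wx
}

#' Build a mass-conserving expression landscape over a network layout
#'
#' Each node deposits a Gaussian kernel of total mass equal to its mean
#' expression; with `edge_mode = "nodes_and_edges"` each edge additionally
#' deposits `confidence * (mass_u + mass_v) / 2`, spread uniformly over
#' `edge_points` sample points along its segment.  All kernels are
#' renormalized after truncation to the unit-square grid, so
#' `sum(cell_values) == deposited_mass` to within floating-point error.
#'
#' @param net an [interaction_network].
#' @param coords layout data.frame from [layout_network()] (columns
#'   `node`, `x`, `y`); every node must have a coordinate.
#' @param node_mass named non-negative vector of per-node masses (e.g.
#'   from [node_mass_from_matrix()]); nodes absent from the vector get 0.
#' @param resolution grid size, a single integer or `c(nx, ny)`.
#' @param bandwidth Gaussian kernel sd as a fraction of the unit layout
#'   extent (> 0; default 0.05).
#' @param edge_mode `"nodes_only"` (default) or `"nodes_and_edges"`.
#' @param edge_points sample points per edge (>= 16 recommended).
#' @return object of class `landscape_grid`: list with `values`
#'   (ny x nx matrix, rows = y), `resolution`, `bandwidth`, `edge_mode`
#'   and `deposited_mass`.
#' @export
build_landscape <- function(net, coords, node_mass,
                            resolution = c(128L, 128L), bandwidth = 0.05,
                            edge_mode = c("nodes_only", "nodes_and_edges"),
                            edge_points = 16L) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(inherits(net, "interaction_network"))
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be > 0", call. = FALSE)
  resolution <- as.integer(rep(resolution, length.out = 2L))
  if (any(resolution < 1L)) stop("resolution must be positive", call. = FALSE)
  nx <- resolution[1L]; ny <- resolution[2L]
  nodes <- network_nodes(net)
  miss <- setdiff(nodes, coords$node)
  if (length(miss))
    stop("nodes without coordinates: ", paste(head(miss, 5L), collapse = ", "),
         call. = FALSE)
  mass <- setNames(rep(0, length(nodes)), nodes)
  common <- intersect(nodes, names(node_mass))
  mass[common] <- node_mass[common]
  if (any(mass < 0)) stop("node masses must be >= 0", call. = FALSE)
  idx <- match(nodes, coords$node)
  px <- coords$x[idx]; py <- coords$y[idx]; pm <- unname(mass)
  if (edge_mode == "nodes_and_edges") {
    ed <- network_edges(net)
    if (nrow(ed)) {
      edge_points <- max(2L, as.integer(edge_points))
      em <- ed$confidence * (mass[ed$from] + mass[ed$to]) / 2
      frac <- (seq_len(edge_points) - 0.5) / edge_points
      i1 <- match(ed$from, nodes); i2 <- match(ed$to, nodes)
      ex <- as.vector(outer(frac, px[i2] - px[i1]) + rep(px[i1], each = edge_points))
      ey <- as.vector(outer(frac, py[i2] - py[i1]) + rep(py[i1], each = edge_points))
      epm <- rep(em / edge_points, each = edge_points)
      px <- c(px, ex); py <- c(py, ey); pm <- c(pm, unname(epm))
    }
  }
  keep <- pm > 0
  values <- if (any(keep))
    .deposit(px[keep], py[keep], pm[keep], nx, ny, bandwidth)
  else matrix(0, ny, nx)
  structure(list(values = values, resolution = c(nx = nx, ny = ny),
                 bandwidth = bandwidth, edge_mode = edge_mode,
                 deposited_mass = sum(pm)),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %dx%d cells, bandwidth %.3f, mode %s, mass %.4g\n",
              x$resolution["nx"], x$resolution["ny"], x$bandwidth,
              x$edge_mode, x$deposited_mass))
  invisible(x)
}

#' Contrast two landscapes cell-wise
#'
#' @param grid_treated,grid_control `landscape_grid`s with identical
#'   resolution.
#' @param mode `"difference"` (treated - control) or `"log_ratio"`
#'   (`log2((t + epsilon) / (c + epsilon))`).
#' @param epsilon positive stabilizer for the log ratio.
#' @return a signed `landscape_grid` with metadata fields `mode` and
#'   `epsilon`; `deposited_mass` is `NA` (contrasts do not conserve mass).
#' @export
landscape_contrast <- function(grid_treated, grid_control,
                               mode = c("difference", "log_ratio"),
                               epsilon = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid_treated, "landscape_grid"),
            inherits(grid_control, "landscape_grid"))
  if (!identical(dim(grid_treated$values), dim(grid_control$values)))
    stop("landscape grids have different shapes", call. = FALSE)
  values <- if (mode == "difference")
    grid_treated$values - grid_control$values
  else
    log2((grid_treated$values + epsilon) / (grid_control$values + epsilon))
  structure(list(values = values, resolution = grid_treated$resolution,
                 bandwidth = grid_treated$bandwidth,
                 edge_mode = grid_treated$edge_mode,
                 deposited_mass = NA_real_, mode = mode, epsilon = epsilon),
            class = "landscape_grid")
}

#' Write a landscape grid as a TSV matrix
#'
#' @param grid a `landscape_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(grid$values, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Quick heatmap of a landscape grid
#'
#' @param grid a `landscape_grid`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the grid.
#' @export
plot_landscape <- function(grid, ...) {
  stopifnot(inherits(grid, "landscape_grid"))
  image(t(grid$values), useRaster = TRUE, ...)
  invisible(grid)
}
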