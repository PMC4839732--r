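# Network annotation, deterministic layout and mass-conserving
# landscapes.

toy_net <- function(edges = data.frame(from = c("a", "b", "c"),
                                       to = c("b", "c", "d"),
                                       confidence = c(0.9, 0.8, 0.7)),
                    ...) {
  interaction_network(edges, ...)
}

test_that("annotate_network applies the category rules", {
  net <- toy_net()
  net <- annotate_network(net,
                          deg_up = gene_list("a"),
                          deg_down = gene_list("b"),
                          hits = gene_list(c("b", "c")))
  cats <- setNames(igraph::V(net$graph)$category, network_nodes(net))
  expect_equal(unname(cats["a"]), "deg_up")
  expect_equal(unname(cats["b"]), "hit_and_deg")
  expect_equal(unname(cats["c"]), "hit")
  expect_equal(unname(cats["d"]), "none")
  # idempotent
  net2 <- annotate_network(net, gene_list("a"), gene_list("b"),
                           gene_list(c("b", "c")))
  expect_equal(igraph::V(net2$graph)$category,
               igraph::V(net$graph)$category)
  expect_error(annotate_network(net, gene_list("a", namespace = "FBgn"),
                                gene_list("b"), gene_list("c")),
               "namespace")
})

test_that("annotation counts equal the Venn partition of the lists", {
  set.seed(13)
  nodes <- paste0("n", 1:50)
  ed <- data.frame(from = sample(nodes, 80, TRUE),
                   to = sample(nodes, 80, TRUE), confidence = 0.5)
  ed <- ed[ed$from != ed$to, ]
  net <- interaction_network(ed, nodes = nodes)
  up <- sample(nodes, 15); down <- sample(nodes, 10)
  hits <- sample(nodes, 20)
  net <- annotate_network(net, gene_list(up), gene_list(down),
                          gene_list(hits))
  cats <- setNames(igraph::V(net$graph)$category, network_nodes(net))
  nn <- network_nodes(net)
  deg <- union(intersect(nn, up), intersect(nn, down))
  hit <- intersect(nn, hits)
  expect_equal(sum(cats == "hit_and_deg"), length(intersect(hit, deg)))
  expect_equal(sum(cats == "hit"), length(setdiff(hit, deg)))
  expect_equal(sum(cats %in% c("deg_up", "deg_down")),
               length(setdiff(deg, hit)))
})

test_that("layout_network is deterministic and order-invariant", {
  ed <- data.frame(from = c("a", "b", "c", "x"), to = c("b", "c", "a", "y"),
                   confidence = 0.5)
  net <- interaction_network(ed)
  c1 <- layout_network(net, seed = 3)
  c2 <- layout_network(net, seed = 3)
  expect_equal(c1, c2)
  # permuted input order, same seed -> identical coordinates after matching
  net_perm <- interaction_network(ed[c(4, 2, 1, 3), ])
  c3 <- layout_network(net_perm, seed = 3)
  expect_equal(c1, c3)
  expect_true(all(c1$x >= 0 & c1$x <= 1 & c1$y >= 0 & c1$y <= 1))

  two <- interaction_network(data.frame(from = "a", to = "b",
                                        confidence = 1))
  ctwo <- layout_network(two, seed = 1)
  expect_false(isTRUE(all.equal(ctwo[1, c("x", "y")],
                                ctwo[2, c("x", "y")],
                                check.attributes = FALSE)))
  empty <- interaction_network(data.frame(from = character(),
                                          to = character(),
                                          confidence = numeric()))
  expect_error(layout_network(empty, 1), "empty")
})

test_that("landscapes conserve deposited mass", {
  net <- toy_net()
  coords <- layout_network(net, seed = 1)
  grid <- build_landscape(net, coords, c(a = 5), resolution = 64)
  expect_equal(sum(grid$values), 5, tolerance = 1e-6)
  expect_equal(grid$deposited_mass, 5)

  zero <- build_landscape(net, coords, c(a = 0, b = 0, c = 0, d = 0),
                          resolution = 32)
  expect_true(all(zero$values == 0))

  edges_grid <- build_landscape(net, coords,
                                c(a = 1, b = 2, c = 3, d = 4),
                                resolution = 48,
                                edge_mode = "nodes_and_edges")
  expect_equal(sum(edges_grid$values), edges_grid$deposited_mass,
               tolerance = 1e-6 * edges_grid$deposited_mass)
  expect_gt(edges_grid$deposited_mass, 10)  # nodes + edge mass

  expect_error(build_landscape(net, coords, c(a = 1), bandwidth = 0),
               "bandwidth")
  expect_error(build_landscape(net, coords[-1, ], c(a = 1)),
               "coordinates")
})

test_that("mirror-placed equal masses give a symmetric landscape", {
  net <- interaction_network(data.frame(from = "a", to = "b",
                                        confidence = 1))
  coords <- data.frame(node = c("a", "b"), x = c(0.25, 0.75),
                       y = c(0.5, 0.5))
  grid <- build_landscape(net, coords, c(a = 2, b = 2), resolution = 64,
                          bandwidth = 0.08)
  expect_lt(max(abs(grid$values - grid$values[, 64:1])), 1e-9)
})

test_that("landscape is linear in node masses", {
  set.seed(17)
  nodes <- paste0("n", 1:12)
  ed <- data.frame(from = sample(nodes, 20, TRUE),
                   to = sample(nodes, 20, TRUE), confidence = 0.6)
  ed <- ed[ed$from != ed$to, ]
  net <- interaction_network(ed, nodes = nodes)
  coords <- layout_network(net, seed = 2)
  m <- setNames(runif(12, 0, 10), nodes)
  g1 <- build_landscape(net, coords, m, resolution = 40)
  g3 <- build_landscape(net, coords, 3 * m, resolution = 40)
  expect_equal(g3$values, 3 * g1$values, tolerance = 1e-9)
})

test_that("landscape_contrast modes and error handling", {
  net <- toy_net()
  coords <- layout_network(net, seed = 1)
  g1 <- build_landscape(net, coords, c(a = 1, b = 2), resolution = 32)
  g2 <- build_landscape(net, coords, c(a = 2, b = 1), resolution = 32)
  same <- landscape_contrast(g1, g1, "log_ratio")
  expect_true(all(same$values == 0))
  zero <- build_landscape(net, coords, c(a = 0), resolution = 32)
  expect_equal(landscape_contrast(g1, zero, "difference")$values, g1$values)
  d12 <- landscape_contrast(g1, g2, "difference")
  d21 <- landscape_contrast(g2, g1, "difference")
  expect_equal(d12$values, -d21$values)
  g_small <- build_landscape(net, coords, c(a = 1), resolution = 16)
  expect_error(landscape_contrast(g1, g_small), "shapes")
})

test_that("node_mass_from_matrix averages replicates and warns on gaps", {
  mat <- toy_matrix(genes = c("a", "b"), effects = list(a = 1), seed = 5)
  net <- toy_net()
  expect_warning(mass <- node_mass_from_matrix(net, mat, "treated", 8),
                 "absent")
  cols <- mat$samples$condition == "treated"
  expect_equal(unname(mass["a"]), mean(mat$values["a", cols]))
  expect_equal(unname(mass[c("c", "d")]), c(0, 0))
})
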