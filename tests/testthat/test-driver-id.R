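test_that("edges orient from hubs to periphery with lexicographic ties", {
  edges <- data.frame(a = c("h", "h", "h"), b = c("x", "y", "z"))
  deg <- c(h = 3, x = 1, y = 1, z = 1)
  arcs <- orient_edges(edges, deg)
  expect_true(all(arcs$tail == "h"))

  tie <- orient_edges(data.frame(a = "b", b = "a"), c(a = 1, b = 1))
  expect_identical(tie$tail, "a")
  expect_identical(tie$head, "b")

  again <- orient_edges(edges, deg)
  expect_identical(arcs, again)
})

test_that("differential networks appear only where correlation rewires", {
  set.seed(5)
  v <- matrix(rnorm(10 * 18), 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:18)))
  design <- stats::setNames(rep(c("A", "B"), each = 9), colnames(v))
  v[, 10:18] <- v[, 1:9]            # identical expression in both groups
  st <- expression_study(v, design)
  expect_warning(net <- build_condition_network(rownames(v), st, c("A", "B")),
                 "no differential edges")
  expect_equal(nrow(net$arcs), 0L)

  sim <- generate_study(study_config(
    n_genes = 80L, deg_fraction = 0,
    module_specs = list(planted_module("m", 25L, "Combo", 0.9)), seed = 6L))
  net2 <- build_condition_network(sim$truth$modules$m, sim$study,
                                  c("Combo", "Vehicle"))
  n_pairs <- choose(25, 2)
  expect_gt(nrow(net2$arcs) / n_pairs, 0.5)
  expect_warning(build_condition_network(sim$truth$modules$m, sim$study,
                                         c("Combo", "Vehicle"),
                                         corr_threshold = 2.1),
                 "no differential edges")
})

test_that("minimum driver sets follow the matching hand examples", {
  iso <- dimscreen:::new_directed_network(
    c("a", "b", "c"), data.frame(tail = character(0), head = character(0)))
  ds <- minimum_driver_set(iso)
  expect_setequal(ds$drivers, c("a", "b", "c"))
  expect_equal(ds$n_drivers, 3L)

  path <- dimscreen:::new_directed_network(
    c("n1", "n2", "n3"), data.frame(tail = c("n1", "n2"), head = c("n2", "n3")))
  dsp <- minimum_driver_set(path)
  expect_equal(dsp$matching_size, 2L)
  expect_identical(dsp$drivers, "n1")

  star <- dimscreen:::new_directed_network(
    c("h", "l1", "l2", "l3"),
    data.frame(tail = "h", head = c("l1", "l2", "l3")))
  dss <- minimum_driver_set(star)
  expect_equal(dss$matching_size, 1L)
  expect_equal(dss$n_drivers, 3L)
  expect_true("h" %in% dss$drivers)
  expect_length(dss$drivers, 3L)

  # perfect matching on a 2-cycle: one padded driver, cycle still actuated
  cyc <- dimscreen:::new_directed_network(
    c("a", "b"), data.frame(tail = c("a", "b"), head = c("b", "a")))
  dsc <- minimum_driver_set(cyc)
  expect_equal(dsc$n_drivers, 1L)
  expect_true(dsc$padded)

  expect_error(minimum_driver_set(
    dimscreen:::new_directed_network(character(0),
                                     data.frame(tail = character(0),
                                                head = character(0)))),
    "empty node set")
})

test_that("matching size is maximal: exhaustive and igraph cross-checks", {
  for (seed in 1:30) {
    net <- random_digraph(seed)
    m <- dimscreen:::max_matching(net$nodes, net$arcs)
    expect_equal(length(m), match_brute(net$arcs), info = paste("seed", seed))
    if (nrow(net$arcs)) {
      # igraph bipartite oracle on the out-copy/in-copy expansion
      g <- igraph::graph_from_data_frame(
        data.frame(from = paste0("out_", net$arcs$tail),
                   to = paste0("in_", net$arcs$head)), directed = FALSE)
      types <- startsWith(igraph::V(g)$name, "in_")
      ig <- igraph::max_bipartite_match(g, types = types)
      expect_equal(length(m), ig$matching_size, info = paste("seed", seed))
    }
  }
})

test_that("adding an arc never increases the number of drivers", {
  for (seed in 31:50) {
    net <- random_digraph(seed, max_arcs = 8)
    nd <- minimum_driver_set(net)$n_drivers
    pairs <- expand.grid(tail = net$nodes, head = net$nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$tail != pairs$head, ]
    key <- paste(pairs$tail, pairs$head)
    free <- pairs[!key %in% paste(net$arcs$tail, net$arcs$head), ]
    if (!nrow(free)) next
    set.seed(seed)
    new_arc <- free[sample(nrow(free), 1), ]
    new_arc$weight <- 1
    net2 <- dimscreen:::new_directed_network(net$nodes,
                                             rbind(net$arcs, new_arc))
    expect_lte(minimum_driver_set(net2)$n_drivers, nd)
  }
})

test_that("possible drivers contain the deterministic set and are reproducible", {
  net <- random_digraph(7)
  ds <- minimum_driver_set(net)
  pos <- possible_drivers(net, k = 10, seed = 3)
  expect_true(all(ds$drivers %in% pos))
  expect_identical(pos, possible_drivers(net, k = 10, seed = 3))
})

test_that("synergistic drivers are the sorted intersection", {
  expect_identical(synergistic_drivers(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
                   c("g2", "g3"))
  expect_warning(out <- synergistic_drivers(c("g1"), c("g2")), "disjoint")
  expect_length(out, 0L)
})

test_that("node importance matches closed forms and brute-force betweenness", {
  path <- dimscreen:::new_directed_network(
    c("a", "b", "c"), data.frame(tail = c("a", "b"), head = c("b", "c")))
  imp <- node_importance(path)
  expect_equal(imp$degree, c(0.5, 1, 0.5))
  expect_equal(imp$betweenness, c(0, 1, 0))
  expect_equal(imp$closeness, c(2 / 3, 1, 2 / 3))
  expect_equal(sum(imp$pagerank), 1, tolerance = 1e-10)

  ring <- dimscreen:::new_directed_network(
    sprintf("r%d", 1:6),
    data.frame(tail = sprintf("r%d", 1:6), head = sprintf("r%d", c(2:6, 1))))
  impr <- node_importance(ring)
  expect_equal(impr$pagerank, rep(1 / 6, 6), tolerance = 1e-8)

  net <- random_digraph(101, max_nodes = 10, max_arcs = 20)
  if (nrow(net$arcs) >= 3) {
    imp2 <- node_importance(net)
    g <- igraph::as_undirected(dimscreen:::as_igraph(net), mode = "collapse")
    adj <- (as.matrix(igraph::as_adjacency_matrix(g)) > 0) + 0
    adj <- adj[net$nodes, net$nodes]
    expect_equal(imp2$betweenness, betweenness_brute(adj), tolerance = 1e-10)
    eig <- igraph::eigen_centrality(g, weights = NA)$vector[net$nodes]
    if (max(eig) > 0)
      expect_equal(imp2$eigenvector, unname(eig), tolerance = 1e-5)
  }
})

test_that("driver validation reproduces the exact rank-sum example and deciles", {
  imp <- data.frame(node = sprintf("n%d", 1:8),
                    degree = c(8, 7, 6, 5, 4, 3, 2, 1) / 7,
                    eigenvector = (8:1) / 8, betweenness = (8:1) / 28,
                    pagerank = (8:1) / 36, closeness = (8:1) / 8)
  val <- validate_drivers(imp, c("n1", "n2", "n3"))  # drivers hold the top 3
  expect_equal(val$tests$p[val$tests$metric == "degree"], 1 / choose(8, 3),
               tolerance = 1e-12)
  expect_true(all(val$deciles$degree %in% 1:10))
  expect_equal(val$deciles$degree[1], 10L)

  const <- imp
  const[, -1] <- 1
  valc <- validate_drivers(const, c("n1", "n2"))
  expect_true(all(valc$tests$p == 1))

  expect_error(validate_drivers(imp, character(0)), "proper subset")
  expect_error(validate_drivers(imp, imp$node), "proper subset")
})

test_that("rank-sum p-values are uniform when drivers are arbitrary", {
  ps <- vapply(1:20, function(seed) {
    set.seed(seed)
    imp <- data.frame(node = sprintf("n%d", 1:30), degree = rnorm(30),
                      eigenvector = rnorm(30), betweenness = rnorm(30),
                      pagerank = rnorm(30), closeness = rnorm(30))
    validate_drivers(imp, sample(imp$node, 10))$tests$p[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
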