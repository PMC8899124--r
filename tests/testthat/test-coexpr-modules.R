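test_that("correlation matrix matches an independent covariance computation", {
  st <- random_study(5, "G", 9, seed = 4)
  cm <- correlation_matrix(st, "G")
  x <- st$values[, st$design == "G"]
  for (i in 1:5) for (j in 1:5) {
    ci <- x[i, ] - mean(x[i, ]); cj <- x[j, ] - mean(x[j, ])
    expect_equal(cm[i, j], sum(ci * cj) / sqrt(sum(ci^2) * sum(cj^2)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(cm)), rep(1, 5))

  # perfect correlation / anticorrelation and the constant-gene convention
  v <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1), g4 = c(5, 5, 5))
  colnames(v) <- paste0("s", 1:3)
  st2 <- expression_study(v, stats::setNames(rep("G", 3), colnames(v)))
  cm2 <- correlation_matrix(st2, "G")
  expect_equal(cm2["g1", "g2"], 1)
  expect_equal(cm2["g1", "g3"], -1)
  expect_equal(unname(cm2["g4", c("g1", "g2", "g3")]), c(0, 0, 0))

  st3 <- random_study(4, "G", 2, seed = 1)
  expect_error(correlation_matrix(st3, "G"), "< 3 samples")
})

test_that("soft-threshold selection behaves on forced, scale-free and degenerate input", {
  st <- random_study(30, "G", 9, seed = 8)
  cm <- correlation_matrix(st, "G")
  expect_equal(pick_soft_threshold(cm, candidate_powers = 6)$power, 6)

  # power-law connectivity gives a high signed scale-free fit
  k <- 1000 * (1:60)^-1.5
  expect_gte(dimscreen:::scale_free_fit(k, 10L), 0.8)

  zero <- matrix(0, 4, 4); diag(zero) <- 1
  expect_error(pick_soft_threshold(zero), "degenerate")

  flat <- matrix(0.5, 5, 5); diag(flat) <- 1
  expect_warning(res <- pick_soft_threshold(flat, 2:5), "falling back")
  expect_equal(res$power, 2)
})

test_that("TOM matches its definition: triangle, empty net, brute force", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(tom_similarity(tri)), matrix(1, 3, 3))

  zero <- matrix(0, 4, 4)
  tz <- tom_similarity(zero)
  expect_equal(unname(tz[upper.tri(tz)]), rep(0, 6))

  for (seed in c(1, 2, 3)) {
    n <- c(6, 13, 20)[seed]
    a <- random_adjacency(n, seed)
    tm <- tom_similarity(a)
    expect_lt(max(abs(tm - tom_brute(a))), 1e-12)
    expect_true(all(tm >= 0 & tm <= 1))
    expect_equal(tm, t(tm))
  }
  expect_error(tom_similarity(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("clustering with size-aware cuts recovers planted blocks", {
  tom <- two_block_tom(12, 10)
  cands <- cluster_and_cut(tom, min_module_size = 5)
  best <- select_optimal_partition(cands, structure(
    list(adjacency = tom - diag(diag(tom)), genes = rownames(tom)),
    class = "coexpression_network"))
  mm <- module_members(best)
  expect_length(mm, 2L)
  expect_setequal(mm[[1]], rownames(tom)[1:12])
  expect_setequal(mm[[2]], rownames(tom)[13:22])

  expect_warning(res <- cluster_and_cut(tom, min_module_size = 30),
                 "unassigned")
  expect_true(all(res[[1]]$membership == 0L))

  # explicit height 0: every gene its own cluster, then merged per size rule
  z <- cluster_and_cut(tom, min_module_size = 5, candidate_heights = 0)
  expect_true(all(z[[1]]$membership == 0L))
  expect_error(cluster_and_cut(tom, 5, candidate_heights = numeric(0)), "empty")
})

test_that("modularity Q matches Newman closed forms and brute force", {
  # two disjoint unit triangles, partitioned as the triangles: Q = 0.5
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1; diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:6), paste0("g", 1:6))
  part <- dimscreen:::new_module_partition(
    stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(a)), 0.5, 3L)
  expect_equal(as.numeric(modularity_q(a, part)), 0.5, tolerance = 1e-12)

  # one community on a connected graph: exactly 0
  b <- random_adjacency(8, 5); b[b < 0.2] <- 0.2
  one <- dimscreen:::new_module_partition(
    stats::setNames(rep(1L, 8), rownames(b)), 0.9, 3L)
  expect_lt(abs(as.numeric(modularity_q(b, one))), 1e-12)

  # random partitions match the double sum; label permutation invariance
  for (seed in 1:3) {
    set.seed(seed)
    adj <- random_adjacency(8, seed + 10)
    memb <- sample(0:3, 8, replace = TRUE)
    p1 <- dimscreen:::new_module_partition(
      stats::setNames(memb, rownames(adj)), 0.5, 3L)
    q1 <- as.numeric(modularity_q(adj, p1))
    expect_equal(q1, q_brute(adj, memb), tolerance = 1e-12)
    relab <- c(0L, 3L, 1L, 2L)[memb + 1L]   # permute labels, keep 0
    p2 <- dimscreen:::new_module_partition(
      stats::setNames(relab, rownames(adj)), 0.5, 3L)
    expect_equal(as.numeric(modularity_q(adj, p2)), q1, tolerance = 1e-12)
  }

  # splitting one triangle of the optimal two-triangle partition lowers Q
  refined <- dimscreen:::new_module_partition(
    stats::setNames(c(1L, 1L, 3L, 2L, 2L, 2L), rownames(a)), 0.5, 3L)
  expect_lt(as.numeric(modularity_q(a, refined)), 0.5)

  empty <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  pe <- dimscreen:::new_module_partition(
    stats::setNames(rep(1L, 3), rownames(empty)), 0.5, 3L)
  expect_warning(qe <- modularity_q(empty, pe), "empty network")
  expect_equal(as.numeric(qe), 0)
})

test_that("optimal-partition selection maximises Q with documented tie-breaks", {
  tom <- two_block_tom(8, 8)
  net <- structure(list(adjacency = tom - diag(diag(tom)),
                        genes = rownames(tom)), class = "coexpression_network")
  cands <- cluster_and_cut(tom, min_module_size = 4)
  single <- select_optimal_partition(cands[1], net)
  expect_identical(single$membership, cands[[1]]$membership)
  best <- select_optimal_partition(cands, net)
  qs <- vapply(cands, function(p) as.numeric(modularity_q(net, p)), numeric(1))
  expect_equal(best$q, max(qs), tolerance = 1e-12)
  expect_error(select_optimal_partition(list(), net), "no candidate")
})

test_that("Z_summary flags a planted dense block as preserved", {
  make_net <- function(seed) {
    set.seed(seed)
    sim <- generate_study(study_config(
      n_genes = 80L, deg_fraction = 0,
      module_specs = list(planted_module("m", 20L, c("Vehicle", "Combo"), 0.85)),
      seed = seed))
    list(ref = build_network(sim$study, "Combo", power = 6),
         test = build_network(sim$study, "Vehicle", power = 6),
         mod = sim$truth$modules$m)
  }
  nets <- make_net(21)
  z <- z_summary(nets$mod, nets$ref, nets$test, n_perm = 200, seed = 1)
  expect_gte(z$z_summary, 2)
  expect_true(z$preserved)
  # deterministic given the seed
  z2 <- z_summary(nets$mod, nets$ref, nets$test, n_perm = 200, seed = 1)
  expect_identical(z$z_summary, z2$z_summary)

  # density Z matches an independent replication of the permutation scheme
  obs <- mean(nets$test$adjacency[nets$mod, nets$mod][upper.tri(diag(20))])
  pool <- intersect(nets$ref$genes, nets$test$genes)
  set.seed(1)
  perm <- replicate(200, {
    gs <- sample(pool, 20)
    m <- nets$test$adjacency[gs, gs]
    c(mean(m[upper.tri(m)]),
      stats::cor(rowSums(nets$ref$adjacency[gs, gs]), rowSums(m)))
  })
  expect_equal(z$z_density, (obs - mean(perm[1, ])) / stats::sd(perm[1, ]),
               tolerance = 1e-10)

  expect_error(z_summary(nets$mod[1:2], nets$ref, nets$test), ">= 3")
  expect_error(z_summary(nets$mod, nets$ref, nets$test, n_perm = 50), "n_perm")
})
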