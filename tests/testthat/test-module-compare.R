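test_that("Jaccard index handles the worked example and edge cases", {
  a <- sprintf("a%03d", 1:79)
  b <- c(a[1:47], sprintf("b%03d", 1:289))      # |b| = 336, overlap 47
  expect_equal(round(set_jaccard(a, b), 3), 0.128)
  expect_equal(set_jaccard(a, b), 47 / 368, tolerance = 1e-12)
  expect_equal(set_jaccard(letters, letters), 1)
  expect_equal(set_jaccard(letters[1:3], letters[4:6]), 0)
  expect_equal(set_jaccard(character(0), character(0)), 0)
  expect_equal(set_jaccard(letters[1:4], letters[3:6]), 2 / 6)
})

make_partition <- function(memb) {
  dimscreen:::new_module_partition(memb, 0.5, 3L)
}

test_that("module similarity matrix is a cross-tabulated Jaccard with row maxima", {
  memb1 <- stats::setNames(c(rep(1L, 4), rep(2L, 4), 0L),
                           sprintf("g%02d", 1:9))
  p1 <- make_partition(memb1)
  sim_self <- module_similarity_matrix(p1, p1)
  expect_equal(unname(apply(sim_self$B, 1, max)), c(1, 1))
  expect_equal(unname(sim_self$s), c(1, 1))

  memb2 <- stats::setNames(c(0L, 0L, rep(1L, 4), rep(2L, 3)),
                           sprintf("g%02d", 1:9))
  p2 <- make_partition(memb2)
  s12 <- module_similarity_matrix(p1, p2)
  expect_equal(s12$B["1", "1"], 2 / 6)          # {g1..g4} vs {g3..g6}
  expect_equal(s12$B, t(module_similarity_matrix(p2, p1)$B))

  # brute force over random partitions
  set.seed(9)
  for (rep_i in 1:3) {
    m1 <- stats::setNames(sample(0:3, 30, replace = TRUE), sprintf("x%02d", 1:30))
    m2 <- stats::setNames(sample(0:2, 30, replace = TRUE), sprintf("x%02d", 1:30))
    q1 <- make_partition(m1); q2 <- make_partition(m2)
    B <- module_similarity_matrix(q1, q2)$B
    for (i in rownames(B)) for (j in colnames(B)) {
      gi <- names(m1)[m1 == as.integer(i)]
      gj <- names(m2)[m2 == as.integer(j)]
      expect_equal(B[i, j], length(intersect(gi, gj)) / length(union(gi, gj)))
    }
  }
  empty <- make_partition(stats::setNames(rep(0L, 5), letters[1:5]))
  expect_error(module_similarity_matrix(p1, empty), "proper module")
})

test_that("module classification follows the strict theta thresholds", {
  s <- c(m1 = 0.05, m2 = 0.50, m3 = 0.95)
  cls <- classify_modules(s, 0.1, 0.1)
  expect_identical(cls$label, c("on-module", "intermediate", "conserved"))

  expect_warning(amb <- classify_modules(c(a = 0.4, b = 0.4, c = 0.4), 0.1, 0.1),
                 "ambiguous")
  expect_true(all(amb$label == "ambiguous"))

  # strict inequalities at theta = 0: extremes get no label
  strict <- classify_modules(c(a = 0.2, b = 0.8), 0, 0)
  expect_identical(strict$label, c("intermediate", "intermediate"))
})

test_that("Add-modules are the combination-specific On-module intersection", {
  cls <- function(mods, on) data.frame(
    module = mods, s = ifelse(mods %in% on, 0.01, 0.9),
    label = ifelse(mods %in% on, "on-module", "conserved"))
  mods <- c("M1", "M4", "M7")
  res <- identify_add_modules(c("M1", "M4"), cls(mods, c("M4", "M7")),
                              cls(mods, "M4"))
  expect_identical(res$add_modules, "M4")

  res_empty <- identify_add_modules(c("M1", "M4"), cls(mods, character(0)),
                                    cls(mods, "M4"))
  expect_length(res_empty$add_modules, 0L)

  expect_error(identify_add_modules("M1", cls(mods, "M4"), cls(c("M1"), "M1")),
               "module ids differ")

  genes <- list(M1 = letters[1:5], M4 = letters[6:12], M7 = letters[13:15])
  res2 <- identify_add_modules(c("M1", "M4"), cls(mods, c("M4", "M7")),
                               cls(mods, "M4"), module_genes = genes,
                               specific_degs = letters[6:9])
  expect_equal(res2$deg_overlap$n_overlap, 4L)
  expect_equal(res2$deg_overlap$jaccard, 4 / 7)
  expect_equal(res2$deg_overlap$overlap_pct, round(100 * 4 / 7))
})

test_that("over-representation p equals the hypergeometric tail and Fisher's exact", {
  universe <- sprintf("u%03d", 1:100)
  module <- universe[1:10]
  coll <- list(hit = universe[1:10], half = universe[6:25],
               null = universe[51:70])
  res <- enrich_gene_sets(module, universe, coll)
  expect_equal(res$p[res$set == "hit"], 1 / choose(100, 10), tolerance = 1e-9)
  for (s in names(coll)) {
    ov <- length(intersect(module, coll[[s]]))
    tab <- matrix(c(ov, length(coll[[s]]) - ov, 10 - ov, 100 - length(coll[[s]]) - 10 + ov), 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    expect_equal(res$p[res$set == s], ft$p.value, tolerance = 1e-9)
  }
  expect_true(all(res$p_adjusted >= res$p - 1e-12))
  expect_gt(res$p[res$set == "null"], 0.2)
  expect_error(enrich_gene_sets(c(module, "zzz"), universe, coll), "subset")
  expect_error(enrich_gene_sets(module, character(0), coll), "empty universe")
})

test_that("BH adjustment reproduces the step-up hand example", {
  universe <- sprintf("u%03d", 1:60)
  # engineer three sets whose raw p values are distinct, then check BH math
  p <- c(0.01, 0.02, 0.03)
  expect_equal(stats::p.adjust(p, "BH"), c(0.03, 0.03, 0.03))
})

test_that("GMT collections round-trip through read_gmt", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst set\tg1\tg2\tg3",
               "setB\tsecond\tg2\tg4"), path)
  gmt <- read_gmt(path)
  expect_identical(names(gmt), c("setA", "setB"))
  expect_identical(gmt$setB, c("g2", "g4"))
  writeLines("bad\tonly-two-fields", path)
  expect_error(read_gmt(path), "fewer than 3")
})
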