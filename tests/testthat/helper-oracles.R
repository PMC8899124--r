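# independent brute-force oracles and small fixtures used across the suite

# study with given per-group value vectors for a single gene
one_gene_study <- function(group_values) {
  groups <- rep(names(group_values), lengths(group_values))
  samples <- paste0("s", seq_along(groups))
  values <- matrix(unlist(group_values), nrow = 1,
                   dimnames = list("g1", samples))
  expression_study(values, stats::setNames(groups, samples))
}

random_study <- function(n_genes, groups, n_per_group, seed) {
  set.seed(seed)
  design <- rep(groups, each = n_per_group)
  samples <- paste0(design, "_", seq_len(n_per_group))
  values <- matrix(rnorm(n_genes * length(samples)), n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  expression_study(values, stats::setNames(design, samples))
}

# symmetric random adjacency in [0,1], zero diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

# double-loop TOM evaluation straight from the definition
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- sum(vapply(seq_len(n), function(u) a[i, u] * a[u, j], numeric(1)))
    out[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# double-sum Newman modularity; memb uses 0 for unassigned
q_brute <- function(a, memb) {
  m2 <- sum(a)
  k <- rowSums(a)
  q <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (memb[i] != 0 && memb[i] == memb[j])
      q <- q + (a[i, j] - k[i] * k[j] / m2) / m2
  }
  unname(q)
}

# exhaustive maximum bipartite matching size over arc subsets
match_brute <- function(arcs) {
  n <- nrow(arcs)
  if (n == 0) return(0L)
  best <- 0L
  rec <- function(i, tails, heads, size) {
    if (size + (n - i + 1L) <= best) return()
    if (i > n) { best <<- max(best, size); return() }
    a_t <- arcs$tail[i]; a_h <- arcs$head[i]
    if (!(a_t %in% tails) && !(a_h %in% heads))
      rec(i + 1L, c(tails, a_t), c(heads, a_h), size + 1L)
    rec(i + 1L, tails, heads, size)
  }
  rec(1L, character(0), character(0), 0L)
  best
}

random_digraph <- function(seed, max_nodes = 7, max_arcs = 12) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  nodes <- sprintf("v%d", 1:n)
  pairs <- expand.grid(tail = nodes, head = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tail != pairs$head, ]
  m <- sample(0:min(max_arcs, nrow(pairs)), 1)
  arcs <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  arcs$weight <- rep(1, nrow(arcs))
  dimscreen:::new_directed_network(nodes, arcs, "random")
}

# Kalman rank test: linear dynamics with random weights on arcs, one input
# column per driver signal attached at the recorded nodes
kalman_rank <- function(net, attachments, seed) {
  set.seed(seed)
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  rw <- function(m) runif(m, 0.5, 1.5) * sample(c(-1, 1), m, replace = TRUE)
  if (nrow(net$arcs))
    a[cbind(net$arcs$head, net$arcs$tail)] <- rw(nrow(net$arcs))
  b <- matrix(0, n, length(attachments), dimnames = list(net$nodes, NULL))
  for (i in seq_along(attachments))
    b[attachments[[i]], i] <- rw(length(attachments[[i]]))
  ctrb <- b
  pw <- b
  for (k in seq_len(n - 1)) {
    pw <- a %*% pw
    ctrb <- cbind(ctrb, pw)
  }
  # normalise columns: Krylov blocks are ill-conditioned and would otherwise
  # defeat the QR rank tolerance even when structurally full rank
  norms <- sqrt(colSums(ctrb^2))
  ctrb <- ctrb[, norms > 1e-12, drop = FALSE]
  ctrb <- sweep(ctrb, 2, sqrt(colSums(ctrb^2)), "/")
  qr(ctrb)$rank
}

# betweenness by explicit BFS shortest-path counting on an unweighted
# undirected graph given as an adjacency matrix
betweenness_brute <- function(adj) {
  n <- nrow(adj)
  bt <- numeric(n)
  dist_paths <- function(s) {
    d <- rep(Inf, n); d[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- union(nxt, w) }
        if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
      frontier <- nxt
    }
    list(d = d, sigma = sigma)
  }
  info <- lapply(seq_len(n), dist_paths)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || is.infinite(info[[s]]$d[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (info[[s]]$d[v] + info[[v]]$d[t] == info[[s]]$d[t])
        bt[v] <- bt[v] + info[[s]]$sigma[v] * info[[v]]$sigma[t] / info[[s]]$sigma[t]
    }
  }
  bt / ((n - 1) * (n - 2) / 2)     # undirected pair normalisation
}

# pair-counting adjusted Rand index, independent of any package
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expected <- si * sj / comb2(sum(tab))
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small two-block TOM fixture: dense within, weak between
two_block_tom <- function(n1 = 12, n2 = 10, within = 0.9, between = 0.05) {
  n <- n1 + n2
  tom <- matrix(between, n, n)
  tom[1:n1, 1:n1] <- within
  tom[(n1 + 1):n, (n1 + 1):n] <- within
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  tom
}

# pipeline fixture small enough for fast tests but with every planted class
small_pipeline_config <- function(seed, out_dir = tempfile(), ...) {
  g <- c("Sham", "Vehicle", "DrugA", "DrugB", "Combo")
  specs <- list(
    planted_module("conserved", 30L, g, loading = 0.8),
    planted_module("sharedA", 25L, c("DrugA", "Combo"), loading = 0.8),
    planted_module("sharedB", 25L, c("DrugB", "Combo"), loading = 0.8),
    planted_module("combo1", 30L, "Combo", loading = 0.8, n_drivers = 1L)
  )
  pipeline_config(
    study_config = study_config(n_genes = 800L, module_specs = specs),
    min_module_size = 8L, n_perm = 100L, seed = seed, out_dir = out_dir, ...)
}
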