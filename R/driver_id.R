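new_directed_network <- function(nodes, arcs, comparison = NA_character_,
                                 orientation = "hub_out") {
  arcs <- as.data.frame(arcs)
  if (nrow(arcs)) {
    if (any(arcs$tail == arcs$head)) stop_config("self-loops are not allowed")
    key <- paste(arcs$tail, arcs$head)
    if (anyDuplicated(key)) stop_config("duplicate arcs are not allowed")
    arcs <- arcs[order(arcs$tail, arcs$head), , drop = FALSE]
    rownames(arcs) <- NULL
  }
  structure(list(nodes = sort(unique(nodes)), arcs = arcs,
                 comparison = comparison, orientation = orientation),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d arcs (%s)\n",
              length(x$nodes), nrow(x$arcs), x$comparison))
  invisible(x)
}

as_igraph <- function(net, directed = TRUE) {
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$arcs))
    g <- igraph::add_edges(g, rbind(net$arcs$tail, net$arcs$head),
                           weight = net$arcs$weight %||% 1)
  g
}

#' Orient undirected edges from hubs towards the periphery
#'
#' Each edge is directed from its higher-degree endpoint to the lower; ties
#' are broken lexicographically (the smaller node id becomes the tail).
#' Deterministic, so repeated runs give identical arc lists.
#'
#' @param edges data.frame with columns `a`, `b` (and optionally `weight`).
#' @param degrees named degree vector covering every endpoint.
#' @return data.frame with columns `tail`, `head` (and `weight`), sorted.
#' @export
orient_edges <- function(edges, degrees) {
  if (nrow(edges) == 0L)
    return(data.frame(tail = character(0), head = character(0),
                      weight = numeric(0)))
  a <- as.character(edges$a); b <- as.character(edges$b)
  da <- degrees[a]; db <- degrees[b]
  a_first <- da > db | (da == db & a < b)
  out <- data.frame(tail = ifelse(a_first, a, b),
                    head = ifelse(a_first, b, a),
                    weight = edges$weight %||% rep(1, nrow(edges)))
  out <- out[order(out$tail, out$head), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential co-expression network between two conditions
#'
#' On the given module genes, Pearson correlations are computed within each
#' of the two conditions; an undirected edge is kept where the absolute
#' correlation difference reaches `corr_threshold` (rewired co-expression).
#' Edges are then oriented hub-out by [orient_edges()], yielding the
#' directed network required by the controllability analysis.
#'
#' @param module_genes genes of the (Add-)module under study.
#' @param study an `expression_study`.
#' @param condition_groups two group labels, e.g. combination arm and one
#'   monotherapy arm.
#' @param corr_threshold minimum `|corr_A - corr_B|` for an edge
#'   (default 0.5).
#' @param orientation `"hub_out"` (default) or `"bidirectional"` (each edge
#'   becomes two opposite arcs).
#' @return a `directed_network`; empty (with a warning) when no pair passes
#'   the threshold.
#' @export
build_condition_network <- function(module_genes, study, condition_groups,
                                    corr_threshold = 0.5,
                                    orientation = c("hub_out", "bidirectional")) {
  orientation <- match.arg(orientation)
  if (length(condition_groups) != 2L) stop_config("need exactly two condition groups")
  corr_threshold <- check_number(corr_threshold, "corr_threshold", 0, Inf)
  c1 <- correlation_matrix(study, condition_groups[1L], module_genes)
  c2 <- correlation_matrix(study, condition_groups[2L], module_genes)
  d <- abs(c1 - c2)
  keep <- which(upper.tri(d) & d >= corr_threshold, arr.ind = TRUE)
  comparison <- paste(condition_groups, collapse = " vs ")
  if (nrow(keep) == 0L) {
    warning(sprintf("no differential edges at threshold %g (%s)",
                    corr_threshold, comparison))
    return(new_directed_network(module_genes,
                                data.frame(tail = character(0), head = character(0),
                                           weight = numeric(0)),
                                comparison, orientation))
  }
  g <- rownames(d)
  edges <- data.frame(a = g[keep[, 1L]], b = g[keep[, 2L]],
                      weight = d[keep])
  if (orientation == "bidirectional") {
    arcs <- data.frame(tail = c(edges$a, edges$b), head = c(edges$b, edges$a),
                       weight = c(edges$weight, edges$weight))
  } else {
    # hub-out by node strength: the weighted degree keeps the magnitude of
    # the correlation rewiring that the 0/1 edge indicator discards
    strength <- vapply(g, function(v)
      sum(edges$weight[edges$a == v | edges$b == v]), numeric(1))
    arcs <- orient_edges(edges, strength)
  }
  new_directed_network(module_genes, arcs, comparison, orientation)
}

# maximum bipartite matching between arc tails (out-copies) and arc heads
# (in-copies) by Kuhn's augmenting-path algorithm; arcs are processed in
# lexicographic order so the matching is deterministic
max_matching <- function(nodes, arcs) {
  if (nrow(arcs) == 0L)
    return(stats::setNames(character(0), character(0)))
  max_matching_ordered(nodes, arcs[order(arcs$tail, arcs$head), , drop = FALSE])
}

#' Minimum driver set by structural controllability
#'
#' Computes a maximum matching on the bipartite out-copy/in-copy
#' representation of the directed network. Nodes whose in-copy is unmatched
#' are the driver nodes: independent control inputs at these nodes render
#' the network structurally controllable under the minimum-inputs principle
#' (`N_D = max(N - |M*|, 1)`). When the matching is perfect the driver set
#' is padded with the first node. Components not reachable from any driver
#' (perfectly matched cycles) do not add drivers; instead an existing input
#' signal is attached to one node of each such component, recorded in
#' `input_attachments`.
#'
#' @param net a `directed_network` with at least one node.
#' @return a `driver_set`: `drivers`, `matching` (head -> tail map as a
#'   data.frame), `matching_size`, `n_drivers`, `input_attachments` (list,
#'   one character vector of actuated nodes per input signal).
#' @export
minimum_driver_set <- function(net) {
  if (length(net$nodes) == 0L) stop_config("empty node set")
  nodes <- net$nodes
  m <- max_matching(nodes, net$arcs)
  matched_heads <- names(m)
  drivers <- setdiff(nodes, matched_heads)
  padded <- length(drivers) == 0L
  if (padded) drivers <- nodes[1L]
  drivers <- sort(drivers)
  n_d <- max(length(nodes) - length(m), 1L)
  attachments <- lapply(drivers, identity)
  # accessibility: attach an input to one node of every component that no
  # driver can reach (matched cycles disconnected from the drivers)
  if (nrow(net$arcs)) {
    reach <- reachable_from(net, unlist(attachments))
    while (!all(nodes %in% reach)) {
      left <- setdiff(nodes, reach)
      sub_arcs <- net$arcs[net$arcs$tail %in% left & net$arcs$head %in% left, ]
      pick <- pick_source_node(left, sub_arcs)
      attachments[[1L]] <- sort(c(attachments[[1L]], pick))
      reach <- reachable_from(net, unlist(attachments))
    }
  }
  structure(list(nodes = nodes, drivers = drivers,
                 matching = data.frame(tail = unname(m), head = names(m)),
                 matching_size = length(m), n_drivers = n_d,
                 padded = padded, input_attachments = attachments),
            class = "driver_set")
}

#' @export
print.driver_set <- function(x, ...) {
  cat(sprintf("driver_set: N = %d, |matching| = %d, N_D = %d\n",
              length(x$nodes), x$matching_size, x$n_drivers))
  cat("drivers:", paste(x$drivers, collapse = ", "), "\n")
  invisible(x)
}

reachable_from <- function(net, start) {
  adj <- split(net$arcs$head, factor(net$arcs$tail, levels = net$nodes))
  seen <- stats::setNames(rep(FALSE, length(net$nodes)), net$nodes)
  queue <- intersect(start, net$nodes)
  seen[queue] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(adj[queue], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  names(seen)[seen]
}

# lexicographically smallest node of a source strongly connected component
# of the subgraph on `left`
pick_source_node <- function(left, sub_arcs) {
  if (nrow(sub_arcs) == 0L) return(sort(left)[1L])
  g <- igraph::graph_from_data_frame(sub_arcs[, c("tail", "head")],
                                     directed = TRUE,
                                     vertices = data.frame(name = left))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  cond <- igraph::contract(g, memb)
  cond <- igraph::simplify(cond)
  indeg <- igraph::degree(cond, mode = "in")
  src <- which(indeg == 0)[1L]
  sort(names(memb)[memb == src])[1L]
}

#' Union of driver sets over random arc permutations
#'
#' Different maximum matchings can leave different (equally minimal) node
#' sets unmatched; this reports every node that turns up as a driver across
#' `k` seeded random permutations of the arc order — the "possible drivers".
#'
#' @param net a `directed_network`.
#' @param k number of permutations (default 10).
#' @param seed RNG seed.
#' @return sorted character vector of possible driver nodes.
#' @export
possible_drivers <- function(net, k = 10L, seed = 1L) {
  k <- check_count(k, "k")
  base <- minimum_driver_set(net)$drivers
  extra <- with_seed(seed, {
    unlist(lapply(seq_len(k), function(i) {
      perm <- net$arcs[sample(nrow(net$arcs)), , drop = FALSE]
      m <- max_matching_ordered(net$nodes, perm)
      setdiff(net$nodes, names(m))
    }))
  })
  sort(unique(c(base, extra)))
}

# Kuhn matching honouring the given arc order (no lexicographic re-sort)
max_matching_ordered <- function(nodes, arcs) {
  if (nrow(arcs) == 0L) return(stats::setNames(character(0), character(0)))
  out_adj <- split(arcs$head, factor(arcs$tail, levels = nodes))
  match_head <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  visited <- NULL
  augment <- function(tail) {
    for (h in out_adj[[tail]]) {
      if (visited[[h]]) next
      visited[[h]] <<- TRUE
      if (is.na(match_head[[h]]) || augment(match_head[[h]])) {
        match_head[[h]] <<- tail
        return(TRUE)
      }
    }
    FALSE
  }
  for (tail in unique(arcs$tail)) {
    visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
    augment(tail)
  }
  m <- match_head[!is.na(match_head)]
  stats::setNames(as.character(m), names(m))
}

#' Synergistic drivers: intersection across the two monotherapy comparisons
#'
#' @param drivers_vs_monoA,drivers_vs_monoB `driver_set` objects or bare
#'   character vectors of driver genes.
#' @return sorted character vector; a warning is emitted when empty.
#' @export
synergistic_drivers <- function(drivers_vs_monoA, drivers_vs_monoB) {
  a <- if (inherits(drivers_vs_monoA, "driver_set")) drivers_vs_monoA$drivers else drivers_vs_monoA
  b <- if (inherits(drivers_vs_monoB, "driver_set")) drivers_vs_monoB$drivers else drivers_vs_monoB
  out <- sort(intersect(a, b))
  if (length(out) == 0L) warning("driver sets are disjoint: no synergistic drivers")
  out
}

#' Node-importance indicators on the undirected network view
#'
#' Degree centrality (`degree / (N - 1)`), eigenvector centrality (power
#' iteration to 1e-8, max-normalised), betweenness (normalised by the pair
#' count), PageRank (damping 0.85), and closeness with disconnected
#' components handled by reachable-set scaling (the Wasserman-Faust
#' improved formula).
#'
#' @param net a `directed_network` with >= 2 nodes.
#' @return data.frame: `node`, `degree`, `eigenvector`, `betweenness`,
#'   `pagerank`, `closeness`.
#' @export
node_importance <- function(net) {
  n <- length(net$nodes)
  if (n < 2L) stop_config("need >= 2 nodes")
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  deg <- igraph::degree(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  a <- (a > 0) + 0
  eig <- eigenvector_power(a)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE, weights = NA)
  pr <- igraph::page_rank(g, damping = 0.85, weights = NA)$vector
  d <- igraph::distances(g, weights = NA)
  clo <- apply(d, 1L, function(row) {
    row <- row[is.finite(row) & row > 0]
    r <- length(row)
    if (r == 0L) return(0)
    (r / (n - 1)) * (r / sum(row))
  })
  data.frame(node = net$nodes,
             degree = unname(deg[net$nodes]) / (n - 1),
             eigenvector = unname(eig[net$nodes]),
             betweenness = unname(btw[net$nodes]),
             pagerank = unname(pr[net$nodes]),
             closeness = unname(clo[net$nodes]),
             row.names = NULL)
}

# leading-eigenvector centrality by power iteration, max-normalised
eigenvector_power <- function(a, tol = 1e-8, max_iter = 10000L) {
  n <- nrow(a)
  if (sum(a) == 0) return(stats::setNames(rep(0, n), rownames(a)))
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.vector(a %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(stats::setNames(rep(0, n), rownames(a)))
    w <- w / nw
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v <- abs(v)
  stats::setNames(v / max(v), rownames(a))
}

#' Compare driver and non-driver nodes on each importance indicator
#'
#' One-sided Mann-Whitney rank-sum test per indicator (drivers greater than
#' non-drivers), exact when the combined sample is at most 20 and tie-free,
#' otherwise the normal approximation with tie correction. Also reports
#' each node's decile per indicator (decile 10 = top). If every value of an
#' indicator is identical the p-value is 1 by convention.
#'
#' @param importance table from [node_importance()].
#' @param drivers character vector of driver nodes; must be a non-empty
#'   proper subset of the table's nodes.
#' @return a `driver_validation` list: `tests` (metric, p, stars) and
#'   `deciles` (node x metric, plus `is_driver`).
#' @export
validate_drivers <- function(importance, drivers) {
  nodes <- importance$node
  drivers <- intersect(drivers, nodes)
  if (length(drivers) == 0L || length(drivers) == length(nodes))
    stop_config("drivers must be a non-empty proper subset of the network's nodes (got %d of %d)",
                length(drivers), length(nodes))
  metrics <- c("degree", "eigenvector", "betweenness", "pagerank", "closeness")
  is_drv <- nodes %in% drivers
  tests <- do.call(rbind, lapply(metrics, function(m) {
    x <- importance[[m]][is_drv]
    y <- importance[[m]][!is_drv]
    p <- rank_sum_greater(x, y)
    data.frame(metric = m, p = p, stars = p_stars(p))
  }))
  deciles <- as.data.frame(lapply(importance[metrics], function(v) {
    r <- rank(v, ties.method = "average")
    pmin(10L, pmax(1L, ceiling(10 * r / length(v))))
  }))
  deciles <- cbind(node = nodes, deciles, is_driver = is_drv)
  structure(list(tests = tests, deciles = deciles, drivers = sort(drivers)),
            class = "driver_validation")
}

rank_sum_greater <- function(x, y) {
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L) return(1)      # all tied
  exact <- (length(x) + length(y) <= 20L) && !anyDuplicated(all_v)
  suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                      exact = exact)$p.value)
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.driver_validation <- function(x, ...) {
  cat("rank-sum tests (drivers > non-drivers):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
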