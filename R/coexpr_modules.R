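#' Pearson correlation matrix of a gene subset within one group
#'
#' @param study an `expression_study`.
#' @param group group label (needs >= 3 samples).
#' @param genes gene subset (default: all genes).
#' @return symmetric correlation matrix with unit diagonal; genes with zero
#'   variance get correlation 0 to all others by convention.
#' @export
correlation_matrix <- function(study, group, genes = NULL) {
  if (!inherits(study, "expression_study")) stop_config("'study' must be an expression_study")
  samples <- group_samples(study, group)
  if (length(samples) < 3L) stop_config("group '%s' has < 3 samples", group)
  genes <- genes %||% study$gene_ids
  missing <- setdiff(genes, study$gene_ids)
  if (length(missing)) stop_config("unknown gene(s): %s", paste(utils::head(missing, 5), collapse = ", "))
  if (length(genes) < 2L) stop_config("need >= 2 genes")
  x <- t(study$values[genes, samples, drop = FALSE])
  cm <- suppressWarnings(stats::cor(x))
  cm[is.na(cm)] <- 0          # constant genes
  diag(cm) <- 1
  cm
}

#' Pick the soft-thresholding power by the scale-free fit criterion
#'
#' For each candidate power the adjacency `|corr|^power` is formed and the
#' scale-free topology fit index computed: connectivities are binned
#' (`n_bins` equal-width bins), and the index is the squared correlation of
#' `log10` bin frequency versus `log10` mean bin connectivity, signed so
#' that only a negative slope (a decreasing degree distribution) counts.
#' Returns the smallest power whose signed fit reaches `rsq_cut`, otherwise
#' the power maximising the fit.
#'
#' @param corr correlation matrix.
#' @param candidate_powers candidate powers (default 1..20).
#' @param rsq_cut target signed fit (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return list with `power` (the selection) and `fits` (per-candidate
#'   signed fit table).
#' @export
pick_soft_threshold <- function(corr, candidate_powers = 1:20, rsq_cut = 0.8,
                                n_bins = 10L) {
  if (length(candidate_powers) < 1L) stop_config("empty candidate power list")
  a0 <- abs(corr)
  diag(a0) <- 0
  if (max(a0) <= 0) stop_config("degenerate network: all correlations are zero")
  fits <- vapply(candidate_powers, function(beta) {
    k <- rowSums(a0^beta)
    scale_free_fit(k, n_bins)
  }, numeric(1))
  ok <- which(!is.na(fits) & fits >= rsq_cut)
  if (length(ok)) {
    power <- candidate_powers[ok[1L]]
  } else if (all(is.na(fits))) {
    warning("scale-free fit undefined for every candidate power; falling back to the smallest")
    power <- min(candidate_powers)
  } else {
    power <- candidate_powers[which.max(ifelse(is.na(fits), -Inf, fits))]
  }
  list(power = power,
       fits = data.frame(power = candidate_powers, fit = fits))
}

# signed scale-free topology fit index of a connectivity vector
scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 2L) return(NA_real_)
  lx <- log10(kmean[keep])
  ly <- log10(freq[keep])
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NA_real_)
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[["lx"]]) * r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with `TOM_ii = 1`, where `k` is the weighted connectivity
#' (adjacency row sum). High topological overlap means two genes share
#' neighbours besides being directly connected.
#'
#' @param adjacency symmetric matrix in \[0,1\] with zero diagonal.
#' @return symmetric TOM matrix in \[0,1\] with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  check_symmetric_unit(adjacency, "adjacency")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  pmin(pmax(tom, 0), 1)
}

#' Build the weighted co-expression network for one condition
#'
#' Unsigned soft-thresholded network: adjacency `|corr|^power` (zero
#' diagonal) with the power chosen by [pick_soft_threshold()] unless given,
#' plus the derived topological overlap matrix.
#'
#' @inheritParams correlation_matrix
#' @param power fixed soft power; default NULL picks it by scale-free fit.
#' @param candidate_powers candidates for the automatic choice.
#' @return a `coexpression_network`: gene ids, `adjacency`, `power`, `tom`.
#' @export
build_network <- function(study, group, genes = NULL, power = NULL,
                          candidate_powers = 1:20) {
  cm <- correlation_matrix(study, group, genes)
  if (is.null(power)) power <- pick_soft_threshold(cm, candidate_powers)$power
  adjacency <- abs(cm)^power
  diag(adjacency) <- 0
  structure(list(genes = rownames(cm), adjacency = adjacency,
                 power = power, tom = tom_similarity(adjacency),
                 group = group),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, soft power %s, group %s\n",
              length(x$genes), format(x$power), x$group %||% "?"))
  invisible(x)
}

new_module_partition <- function(membership, cut_height, min_module_size,
                                 q = NA_real_, q_per_module = NULL) {
  structure(list(membership = membership, cut_height = cut_height,
                 min_module_size = min_module_size, q = q,
                 q_per_module = q_per_module),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  k <- sum(unique(x$membership) != 0L)
  cat(sprintf("module_partition: %d modules over %d genes (%d unassigned), cut height %.3g, Q = %.4g\n",
              k, length(x$membership), sum(x$membership == 0L),
              x$cut_height, x$q))
  invisible(x)
}

#' Module gene lists of a partition
#' @param partition a `module_partition`.
#' @return named list of character vectors, one per module (unassigned
#'   genes excluded), named `"1"`, `"2"`, ... by decreasing size.
#' @export
module_members <- function(partition) {
  m <- partition$membership
  ids <- sort(unique(m[m != 0L]))
  stats::setNames(lapply(ids, function(i) sort(names(m)[m == i])),
                  as.character(ids))
}

#' Hierarchical clustering of a TOM with candidate static cuts
#'
#' Average-linkage clustering on dissimilarity `1 - TOM`; the tree is cut at
#' every candidate height, clusters smaller than `min_module_size` are
#' merged into the nearest proper cluster by average TOM (or set to the
#' unassigned module 0 when no proper cluster exists). Module ids are
#' ordinals by decreasing size; 0 is reserved for unassigned genes.
#'
#' By default the candidate heights adapt to the dendrogram: they are
#' `n_heights` quantiles of the tree's merge heights, so the grid resolves
#' the tree regardless of how the soft power compresses the TOM scale. Pass
#' an explicit `candidate_heights` vector to override.
#'
#' @param tom TOM matrix with gene ids as dimnames.
#' @param min_module_size smallest allowed module (>= 3, default 10).
#' @param candidate_heights cut heights to try; NULL (default) uses merge-
#'   height quantiles.
#' @param n_heights size of the default quantile grid (default 25).
#' @return list of `module_partition` candidates, one per height.
#' @export
cluster_and_cut <- function(tom, min_module_size = 10L,
                            candidate_heights = NULL, n_heights = 25L) {
  check_symmetric_unit(tom, "tom")
  min_module_size <- check_count(min_module_size, "min_module_size", min = 3L)
  if (!is.null(candidate_heights) && length(candidate_heights) < 1L)
    stop_config("empty candidate height list")
  genes <- rownames(tom)
  if (is.null(genes)) stop_config("'tom' must carry gene ids as dimnames")
  if (min_module_size > length(genes)) {
    warning("min_module_size exceeds the gene count; all genes unassigned")
    memb <- stats::setNames(rep(0L, length(genes)), genes)
    return(list(new_module_partition(memb, candidate_heights[1L] %||% NA_real_,
                                     min_module_size)))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # guard against tie-induced floating-point inversions in the merge heights
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  if (is.null(candidate_heights))
    candidate_heights <- unique(stats::quantile(
      tree$height, probs = seq(0.02, 0.98, length.out = n_heights),
      names = FALSE, type = 7))
  lapply(candidate_heights, function(h) {
    cl <- cut_at_height(tree, h, length(genes))
    memb <- merge_small_clusters(cl, tom, min_module_size)
    new_module_partition(stats::setNames(memb, genes), h, min_module_size)
  })
}

cut_at_height <- function(tree, h, n) {
  if (h <= 0) return(seq_len(n))            # every gene its own cluster
  stats::cutree(tree, h = h)
}

# merge undersized clusters into the proper cluster with maximal average
# TOM; all-undersized partitions become fully unassigned
merge_small_clusters <- function(cl, tom, min_size) {
  sizes <- table(cl)
  proper <- as.integer(names(sizes)[sizes >= min_size])
  out <- integer(length(cl))
  if (length(proper) == 0L) return(out)
  proper_idx <- lapply(proper, function(p) which(cl == p))
  for (c_id in as.integer(names(sizes))) {
    idx <- which(cl == c_id)
    if (c_id %in% proper) {
      out[idx] <- c_id
    } else {
      avg <- vapply(proper_idx, function(pi)
        mean(tom[idx, pi, drop = FALSE]), numeric(1))
      out[idx] <- proper[which.max(avg)]
    }
  }
  # relabel by decreasing size, 1..K
  sizes2 <- sort(table(out[out != 0L]), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes2), names(sizes2))
  ifelse(out == 0L, 0L, as.integer(relabel[as.character(out)]))
}

#' Newman modularity Q of a partition on a weighted network
#'
#' `Q = 1/(2n) * sum_ij [a_ij - k_i k_j / (2n)] * sigma(c_i, c_j)` with `2n`
#' the total adjacency weight, `k` the weighted connectivity and `sigma = 1`
#' only for pairs in the same proper module (pairs involving the unassigned
#' module contribute nothing).
#'
#' @param net a `coexpression_network` (or a bare adjacency matrix).
#' @param partition a `module_partition` covering the network's genes.
#' @return Q, with attribute `"per_module"` giving each module's
#'   contribution. An empty network (zero total weight) yields 0 with a
#'   warning.
#' @export
modularity_q <- function(net, partition) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else net
  check_symmetric_unit(a, "adjacency")
  diag(a) <- 0
  genes <- rownames(a) %||% names(partition$membership)
  memb <- partition$membership[genes]
  if (anyNA(memb)) stop_config("partition does not cover the network's genes")
  m2 <- sum(a)
  if (m2 <= 0) {
    warning("empty network: Q defined as 0")
    return(structure(0, per_module = numeric(0)))
  }
  k <- rowSums(a)
  ids <- sort(unique(memb[memb != 0L]))
  per <- vapply(ids, function(c_id) {
    i <- which(memb == c_id)
    (sum(a[i, i]) - sum(k[i])^2 / m2) / m2
  }, numeric(1))
  structure(sum(per), per_module = stats::setNames(per, as.character(ids)))
}

#' Select the modularity-optimal partition among candidates
#'
#' Returns the candidate with maximal Q; ties are broken by fewer unassigned
#' genes, then by lower cut height. The returned partition carries its Q and
#' per-module contributions.
#'
#' @param candidates list of `module_partition` objects (from
#'   [cluster_and_cut()]).
#' @param net the `coexpression_network` the candidates partition.
#' @return the winning `module_partition`.
#' @export
select_optimal_partition <- function(candidates, net) {
  if (length(candidates) < 1L) stop_config("no candidate partitions")
  qs <- lapply(candidates, function(p) modularity_q(net, p))
  qv <- vapply(qs, as.numeric, numeric(1))
  unassigned <- vapply(candidates, function(p) sum(p$membership == 0L), numeric(1))
  heights <- vapply(candidates, function(p) p$cut_height, numeric(1))
  best <- order(-qv, unassigned, heights)[1L]
  p <- candidates[[best]]
  p$q <- qv[best]
  p$q_per_module <- attr(qs[[best]], "per_module")
  p
}

#' Detect modules in a co-expression network
#'
#' Convenience wrapper: [cluster_and_cut()] over the height grid followed by
#' [select_optimal_partition()].
#'
#' @param net a `coexpression_network`.
#' @inheritParams cluster_and_cut
#' @return the modularity-optimal `module_partition`.
#' @export
detect_modules <- function(net, min_module_size = 10L,
                           candidate_heights = NULL) {
  candidates <- cluster_and_cut(net$tom, min_module_size, candidate_heights)
  select_optimal_partition(candidates, net)
}

#' Permutation Z_summary module-preservation statistic
#'
#' Compares a module's density (mean intramodular adjacency in the test
#' network) and connectivity preservation (correlation of intramodular
#' connectivity between reference and test network) against `n_perm` random
#' gene sets of equal size. `Z_summary` is the mean of the two Z scores;
#' `Z_summary >= 2` flags the module as preserved.
#'
#' @param module_genes gene set (>= 3 genes, present in both networks).
#' @param reference_net,test_net `coexpression_network` objects sharing the
#'   module's genes.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return a `preservation_result` list: `z_density`, `z_connectivity`,
#'   `z_summary`, `preserved`, `n_perm`, `seed`.
#' @export
z_summary <- function(module_genes, reference_net, test_net, n_perm = 200L,
                      seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  module_genes <- unique(module_genes)
  if (length(module_genes) < 3L) stop_config("module must have >= 3 genes")
  pool <- intersect(reference_net$genes, test_net$genes)
  if (!all(module_genes %in% pool))
    stop_config("module genes must be present in both networks")
  a_ref <- reference_net$adjacency
  a_test <- test_net$adjacency
  stat <- function(genes) {
    at <- a_test[genes, genes]
    ar <- a_ref[genes, genes]
    dens <- mean(at[upper.tri(at)])
    conn <- suppressWarnings(stats::cor(rowSums(ar), rowSums(at)))
    c(density = dens, connectivity = if (is.na(conn)) 0 else conn)
  }
  obs <- stat(module_genes)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stat(sample(pool, length(module_genes))),
           numeric(2))
  })
  mu <- rowMeans(perms)
  sdv <- apply(perms, 1L, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  zs <- mean(z)
  structure(list(z_density = unname(z["density"]),
                 z_connectivity = unname(z["connectivity"]),
                 z_summary = zs, preserved = zs >= 2,
                 observed = obs, n_perm = n_perm, seed = seed),
            class = "preservation_result")
}
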