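#' Jaccard index of two gene sets
#'
#' `|a intersect b| / |a union b|`; two empty sets give 0 by convention.
#'
#' @param a,b character vectors (duplicates ignored).
#' @return Jaccard index in \[0, 1\].
#' @examples
#' set_jaccard(letters[1:4], letters[3:6])  # 2/6
#' @export
set_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Cross-condition module similarity matrix B
#'
#' `B_ij` is the Jaccard index between the members of module i of the first
#' partition and module j of the second; unassigned genes are excluded. The
#' per-row response score is `s_i = max_j B_ij` — how well module i is
#' matched by its best counterpart.
#'
#' @param partition1,partition2 `module_partition` objects (each must have
#'   at least one proper module).
#' @return a `module_similarity` list with matrix `B` (rows: partition1
#'   modules) and vector `s`.
#' @export
module_similarity_matrix <- function(partition1, partition2) {
  m1 <- module_members(partition1)
  m2 <- module_members(partition2)
  if (length(m1) == 0L || length(m2) == 0L)
    stop_config("each partition needs at least one proper module")
  B <- matrix(0, length(m1), length(m2), dimnames = list(names(m1), names(m2)))
  for (i in seq_along(m1))
    for (j in seq_along(m2))
      B[i, j] <- set_jaccard(m1[[i]], m2[[j]])
  structure(list(B = B, s = apply(B, 1L, max)), class = "module_similarity")
}

#' @export
print.module_similarity <- function(x, ...) {
  cat(sprintf("module_similarity: %d x %d modules\n", nrow(x$B), ncol(x$B)))
  cat("response scores s:\n")
  print(round(x$s, 3))
  invisible(x)
}

#' Classify modules as conserved, On-, or intermediate
#'
#' A module with response score `s > max(s) - theta2` is conserved (its best
#' counterpart matches it well everywhere); one with `s < min(s) + theta1`
#' is drug-responsive (an On-module). Inequalities are strict. A module
#' eligible for both labels — possible when the score range is narrower than
#' `theta1 + theta2` — is labelled ambiguous with a warning.
#'
#' @param sim a `module_similarity` (or a bare named numeric vector of
#'   scores).
#' @param theta1,theta2 non-negative threshold offsets (default 0.1 each).
#' @return data.frame with columns `module`, `s`, `label` (one of
#'   `"on-module"`, `"conserved"`, `"intermediate"`, `"ambiguous"`), plus
#'   the thresholds used as attributes.
#' @export
classify_modules <- function(sim, theta1 = 0.1, theta2 = 0.1) {
  s <- if (inherits(sim, "module_similarity")) sim$s else sim
  theta1 <- check_number(theta1, "theta1", 0, Inf)
  theta2 <- check_number(theta2, "theta2", 0, Inf)
  lo <- min(s) + theta1
  hi <- max(s) - theta2
  on_elig <- s < lo
  cons_elig <- s > hi
  label <- rep("intermediate", length(s))
  label[on_elig] <- "on-module"
  label[cons_elig] <- "conserved"
  both <- on_elig & cons_elig
  if (any(both)) {
    warning(sprintf("score range narrower than theta1 + theta2: %d module(s) eligible for both labels, marked ambiguous",
                    sum(both)))
    label[both] <- "ambiguous"
  }
  out <- data.frame(module = names(s) %||% as.character(seq_along(s)),
                    s = unname(s), label = label, row.names = NULL)
  attr(out, "thresholds") <- c(theta1 = theta1, theta2 = theta2,
                               min_s = min(s), max_s = max(s))
  out
}

on_module_ids <- function(classification) {
  classification$module[classification$label == "on-module"]
}

#' Screen combination-specific additive modules
#'
#' Add-modules are combination-arm On-modules (versus the vehicle
#' background) that remain On-modules when the combination's partition is
#' compared against each monotherapy's partition — modules specific to the
#' combination, carriers of the additive effect.
#'
#' @param on_vs_vehicle module ids of the combination arm labelled
#'   on-module against the vehicle background.
#' @param class_vs_monoA,class_vs_monoB classification data.frames from
#'   [classify_modules()] of the combination partition against each
#'   monotherapy partition (same module universe).
#' @param module_genes named list of the combination partition's module
#'   gene sets (from [module_members()]).
#' @param specific_degs optional combination-specific DEG set for overlap
#'   statistics.
#' @return an `add_module_result` list: `add_modules`, per-module gene
#'   lists, and DEG-overlap statistics when `specific_degs` is given.
#' @export
identify_add_modules <- function(on_vs_vehicle, class_vs_monoA, class_vs_monoB,
                                 module_genes = NULL, specific_degs = NULL) {
  if (!setequal(class_vs_monoA$module, class_vs_monoB$module))
    stop_config("module ids differ between the two monotherapy classifications")
  if (!all(on_vs_vehicle %in% class_vs_monoA$module))
    stop_config("on_vs_vehicle contains module ids absent from the classifications")
  add <- intersect(on_vs_vehicle,
                   intersect(on_module_ids(class_vs_monoA),
                             on_module_ids(class_vs_monoB)))
  add <- sort(add)
  genes <- NULL
  overlap <- NULL
  if (!is.null(module_genes)) {
    if (!all(add %in% names(module_genes)))
      stop_config("module_genes is missing Add-module members")
    genes <- module_genes[add]
    if (!is.null(specific_degs)) {
      all_genes <- unique(unlist(genes, use.names = FALSE))
      ov <- intersect(all_genes, specific_degs)
      overlap <- list(n_add_genes = length(all_genes),
                      n_overlap = length(ov),
                      overlap_pct = if (length(all_genes))
                        round(100 * length(ov) / length(all_genes)) else 0,
                      jaccard = set_jaccard(all_genes, specific_degs),
                      genes = sort(ov))
    }
  }
  structure(list(add_modules = add, on_vs_vehicle = sort(on_vs_vehicle),
                 on_vs_monoA = sort(on_module_ids(class_vs_monoA)),
                 on_vs_monoB = sort(on_module_ids(class_vs_monoB)),
                 module_genes = genes, deg_overlap = overlap),
            class = "add_module_result")
}

#' @export
print.add_module_result <- function(x, ...) {
  cat(sprintf("Add-modules: %s\n",
              if (length(x$add_modules)) paste(x$add_modules, collapse = ", ") else "(none)"))
  cat(sprintf("On vs vehicle: %s | vs monoA: %s | vs monoB: %s\n",
              paste(x$on_vs_vehicle, collapse = ","),
              paste(x$on_vs_monoA, collapse = ","),
              paste(x$on_vs_monoB, collapse = ",")))
  if (!is.null(x$deg_overlap))
    cat(sprintf("%d of %d Add-module genes overlap the specific DEGs (%d%%), Jaccard %.3f\n",
                x$deg_overlap$n_overlap, x$deg_overlap$n_add_genes,
                x$deg_overlap$overlap_pct, x$deg_overlap$jaccard))
  invisible(x)
}

#' Gene-set over-representation of a module
#'
#' One-sided Fisher's exact (hypergeometric upper-tail) p per gene set from
#' the 2x2 table of module membership versus set membership within the
#' universe, with Benjamini-Hochberg adjustment across the collection.
#'
#' @param module_genes gene set to test (must lie within `universe`).
#' @param universe background gene universe.
#' @param collection named list of gene sets (e.g. from [read_gmt()]); each
#'   set is intersected with the universe first.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame sorted by p: `set`, `overlap`, `set_size`,
#'   `module_size`, `universe_size`, `p`, `p_adjusted`, `significant`.
#' @export
enrich_gene_sets <- function(module_genes, universe, collection, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_config("empty universe")
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    stop_config("module genes must be a subset of the universe")
  if (is.null(names(collection))) stop_config("'collection' must be named")
  n_u <- length(universe)
  n_m <- length(module_genes)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    ov <- length(intersect(module_genes, s))
    p <- stats::phyper(ov - 1L, length(s), n_u - length(s), n_m,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               module_size = n_m, universe_size = n_u, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
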