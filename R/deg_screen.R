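#' Per-gene one-way ANOVA across treatment groups
#'
#' Classical fixed-effects one-way ANOVA per gene, vectorised across the
#' expression matrix. Genes with zero total variance (identical values in
#' every sample) get `F = 0` and `p = 1` by convention; genes with zero
#' within-group variance but distinct group means get `p = 0`.
#'
#' @param study an `expression_study`.
#' @param groups group labels to compare (default: all groups in the
#'   design); each must have at least 2 samples.
#' @return data.frame with columns `gene`, `F`, `p`.
#' @examples
#' # hand example: groups (1,2,3), (2,3,4), (3,4,5) give F = 3
#' @export
anova_per_gene <- function(study, groups = NULL) {
  if (!inherits(study, "expression_study")) stop_config("'study' must be an expression_study")
  groups <- groups %||% unique(unname(study$design))
  if (length(groups) < 2L) stop_config("need >= 2 groups")
  if (!all(groups %in% study$design))
    stop_config("unknown group(s): %s", paste(setdiff(groups, study$design), collapse = ", "))
  samples <- study$sample_ids[study$design %in% groups]
  g <- factor(unname(study$design[samples]), levels = groups)
  n_g <- as.vector(table(g))
  if (any(n_g < 2L))
    stop_config("every group needs >= 2 samples (got: %s)",
                paste(sprintf("%s=%d", groups, n_g), collapse = ", "))
  x <- study$values[, samples, drop = FALSE]
  n <- length(samples)
  k <- length(groups)
  ind <- stats::model.matrix(~ g - 1)                 # samples x k
  means <- x %*% ind %*% diag(1 / n_g, k)             # genes x k group means
  grand <- rowMeans(x)
  ssb <- colSums(t(means - grand)^2 * n_g)
  fitted <- means %*% t(ind)
  ssw <- rowSums((x - fitted)^2)
  df1 <- k - 1L
  df2 <- n - k
  tol <- 1e-12 * pmax(1, rowMeans(x^2))
  fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  degenerate <- (ssb + ssw) <= tol                    # no variance at all
  fstat[degenerate] <- 0
  p[degenerate] <- 1
  exact <- !degenerate & ssw <= tol                   # perfect separation
  fstat[exact] <- Inf
  p[exact] <- 0
  data.frame(gene = study$gene_ids, F = fstat, p = p, row.names = NULL)
}

#' Per-gene fold change between two groups
#'
#' Expression values are log2-scale intensities; means are taken on the
#' linear scale (after `2^x`). The fold change is direction-symmetric:
#' `max(m_d / m_r, m_r / m_d)`, with `direction` `"up"` when the drug-arm
#' linear mean exceeds the reference mean.
#'
#' @param study an `expression_study`.
#' @param drug_group,reference_group group labels.
#' @param log_base base of the stored log intensities (default 2).
#' @return data.frame with columns `gene`, `fold_change`, `direction`.
#' @export
fold_change <- function(study, drug_group, reference_group, log_base = 2) {
  if (!inherits(study, "expression_study")) stop_config("'study' must be an expression_study")
  sd_ <- group_samples(study, drug_group)
  sr <- group_samples(study, reference_group)
  md <- rowMeans(log_base^study$values[, sd_, drop = FALSE])
  mr <- rowMeans(log_base^study$values[, sr, drop = FALSE])
  if (any(!is.finite(md)) || any(!is.finite(mr)) || any(md <= 0) || any(mr <= 0))
    stop_config("nonpositive or non-finite linear group mean")
  data.frame(gene = study$gene_ids,
             fold_change = pmax(md / mr, mr / md),
             direction = ifelse(md >= mr, "up", "down"),
             row.names = NULL)
}

#' Select differentially expressed genes
#'
#' Combines per-gene test p-values and fold changes into a DEG call:
#' multiplicity correction is applied across all tested genes first
#' (`bonferroni` default: `p_adj = min(1, m * p)`), then a gene is a DEG iff
#' `p_adj < alpha` and `fold_change > fc_threshold`.
#'
#' @param tests data.frame from [anova_per_gene()] (columns `gene`, `F`, `p`).
#' @param fc data.frame from [fold_change()] over the same gene universe.
#' @param alpha significance level (default 0.05).
#' @param fc_threshold fold-change threshold (default 1.5).
#' @param correction `"bonferroni"` (default), `"benjamini-hochberg"`, or
#'   `"none"`.
#' @param m number of tests for the correction; defaults to the number of
#'   genes in `tests` (override for an array-level universe).
#' @return data.frame sorted by `p` with columns `gene`, `F`, `p`,
#'   `p_adjusted`, `fold_change`, `direction`, `is_deg`.
#' @export
select_degs <- function(tests, fc, alpha = 0.05, fc_threshold = 1.5,
                        correction = c("bonferroni", "benjamini-hochberg", "none"),
                        m = NULL) {
  correction <- match.arg(correction)
  alpha <- check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  fc_threshold <- check_number(fc_threshold, "fc_threshold", 1, Inf)
  if (!setequal(tests$gene, fc$gene) || nrow(tests) != nrow(fc))
    stop_config("'tests' and 'fc' must cover the same gene universe")
  fc <- fc[match(tests$gene, fc$gene), ]
  m <- if (is.null(m)) nrow(tests) else check_count(m, "m")
  p_adj <- switch(correction,
    bonferroni = pmin(1, m * tests$p),
    `benjamini-hochberg` = stats::p.adjust(tests$p, method = "BH", n = m),
    none = tests$p)
  out <- data.frame(gene = tests$gene, F = tests$F, p = tests$p,
                    p_adjusted = p_adj,
                    fold_change = fc$fold_change, direction = fc$direction,
                    is_deg = p_adj < alpha & fc$fold_change > fc_threshold,
                    row.names = NULL)
  out[order(out$p, out$gene), , drop = FALSE]
}

#' Overlap statistics among DEG sets and a reference gene list
#'
#' Reports set sizes, all pairwise and higher-order intersection counts,
#' unique-per-set counts, and — when a reference list is given — per-set
#' overlap counts, per-set Jaccard indices, and the percentage of DEGs
#' (union) overlapping the reference, rounded to one decimal.
#'
#' @param deg_sets named list of character vectors.
#' @param reference optional reference gene list (e.g. known disease genes).
#' @return an `overlap_report` list.
#' @export
overlap_report <- function(deg_sets, reference = NULL) {
  if (is.null(names(deg_sets)) || any(!nzchar(names(deg_sets))))
    stop_config("'deg_sets' must be a named list")
  deg_sets <- lapply(deg_sets, unique)
  nm <- names(deg_sets)
  sizes <- lengths(deg_sets)
  intersections <- list()
  if (length(nm) >= 2L) {
    for (k in 2:length(nm)) {
      for (combo in utils::combn(nm, k, simplify = FALSE)) {
        key <- paste(combo, collapse = "&")
        intersections[[key]] <- length(Reduce(intersect, deg_sets[combo]))
      }
    }
  }
  union_all <- unique(unlist(deg_sets, use.names = FALSE))
  unique_counts <- vapply(nm, function(s)
    length(setdiff(deg_sets[[s]], unlist(deg_sets[setdiff(nm, s)], use.names = FALSE))),
    integer(1))
  ref <- NULL
  if (!is.null(reference)) {
    reference <- unique(reference)
    per_set <- vapply(deg_sets, function(s) length(intersect(s, reference)), integer(1))
    jac <- vapply(deg_sets, function(s) set_jaccard(s, reference), numeric(1))
    ov <- length(intersect(union_all, reference))
    ref <- list(reference_size = length(reference),
                overlap_per_set = per_set,
                jaccard_per_set = jac,
                union_overlap = ov,
                union_coverage_pct = round(100 * ov / length(reference), 1),
                shared_with_all_sets = length(Reduce(intersect, c(deg_sets, list(reference)))))
  }
  structure(list(sizes = sizes, intersections = unlist(intersections),
                 unique_counts = unique_counts, union_size = length(union_all),
                 reference = ref, members = deg_sets),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("DEG set sizes:\n")
  print(x$sizes)
  if (length(x$intersections)) {
    cat("intersections:\n")
    print(x$intersections)
  }
  cat("unique per set:\n")
  print(x$unique_counts)
  cat(sprintf("union size: %d\n", x$union_size))
  if (!is.null(x$reference))
    cat(sprintf("reference (n = %d): %d of the union overlap (%.1f%% of the reference)\n",
                x$reference$reference_size, x$reference$union_overlap,
                x$reference$union_coverage_pct))
  invisible(x)
}

#' One-stop DEG screen for every drug arm versus the reference arm
#'
#' Runs [anova_per_gene()] once across `anova_groups`, then per drug arm the
#' fold change versus the reference and the DEG selection.
#'
#' @param study an `expression_study`.
#' @param drug_groups drug-arm labels.
#' @param reference_group reference (vehicle) label.
#' @param anova_groups groups entering the ANOVA (default: all).
#' @inheritParams select_degs
#' @return named list per drug arm, each with the full `table` and the
#'   character vector `degs`.
#' @export
deg_screen <- function(study, drug_groups, reference_group,
                       anova_groups = NULL, alpha = 0.05, fc_threshold = 1.5,
                       correction = "bonferroni", m = NULL) {
  av <- anova_per_gene(study, anova_groups)
  out <- lapply(drug_groups, function(d) {
    tab <- select_degs(av, fold_change(study, d, reference_group),
                       alpha = alpha, fc_threshold = fc_threshold,
                       correction = correction, m = m)
    list(table = tab, degs = tab$gene[tab$is_deg])
  })
  stats::setNames(out, drug_groups)
}
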