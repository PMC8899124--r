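#' Specify a planted co-expression module
#'
#' Describes one module to be planted by [generate_study()]. Within every
#' group listed in `active_in`, the module's member genes co-vary through a
#' shared latent factor, so the expected Pearson correlation between two
#' ordinary members is `loading^2`; in all other groups the members are
#' independent noise. Designated driver genes are hub members whose loading
#' is boosted towards 1 (capped at 0.99) so that they acquire the top
#' intramodular connectivity.
#'
#' @param name module label, unique within a study configuration.
#' @param size number of member genes (>= 3).
#' @param active_in character vector of group names in which the members
#'   co-vary.
#' @param loading latent-factor loading of an ordinary member, strictly
#'   between 0 and 1; expected member-member correlation is `loading^2`.
#' @param n_drivers number of members designated as planted driver hubs.
#' @return A `planted_module` specification (a list).
#' @seealso [study_config()], [generate_study()]
#' @export
planted_module <- function(name, size, active_in, loading = 0.8, n_drivers = 0L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("'name' must be a non-empty string")
  size <- check_count(size, "size", min = 3L)
  if (!is.character(active_in) || length(active_in) < 1L)
    stop_config("'active_in' must name at least one group")
  loading <- check_number(loading, "loading", 0, 1, open_lower = TRUE, open_upper = TRUE)
  n_drivers <- check_count(n_drivers, "n_drivers", min = 0L)
  if (n_drivers > size)
    stop_config("module '%s': n_drivers exceeds module size", name)
  structure(list(name = name, size = size, active_in = active_in,
                 loading = loading, n_drivers = n_drivers),
            class = "planted_module")
}

#' Default planted-module layout for a five-arm study
#'
#' One module conserved across all arms, one module shared between each
#' monotherapy and the combination, and two combination-specific modules
#' carrying the planted driver hubs.
#'
#' @param group_names ordered group labels (sham, vehicle, two
#'   monotherapies, combination).
#' @return list of [planted_module()] specifications.
#' @export
default_module_specs <- function(group_names = c("Sham", "Vehicle", "DrugA",
                                                 "DrugB", "Combo")) {
  g <- group_names
  list(
    planted_module("conserved", 60L, g,                 loading = 0.8),
    planted_module("sharedA",   50L, c(g[3L], g[5L]),   loading = 0.8),
    planted_module("sharedB",   50L, c(g[4L], g[5L]),   loading = 0.8),
    planted_module("combo1",    60L, g[5L],             loading = 0.8, n_drivers = 2L),
    planted_module("combo2",    40L, g[5L],             loading = 0.8, n_drivers = 1L)
  )
}

#' Configure a synthetic multi-arm expression study
#'
#' The defaults emulate a five-arm rodent treatment study profiled on
#' two-channel arrays: five groups of nine samples, a few thousand genes on
#' a log2 intensity scale, ~5% of background genes differentially expressed
#' per drug arm at two-fold change, and planted co-expression modules with
#' condition-specific rewiring. The within-group replicate noise
#' (`noise_sd`, log2 scale) defaults to 0.3, a typical replicate standard
#' deviation for array intensities.
#'
#' @param n_genes total number of genes (default 2000).
#' @param n_samples_per_group samples per group (default 9).
#' @param group_names ordered group labels; the first two are the untreated
#'   arms (sham and vehicle), the rest are drug arms.
#' @param reference_group label of the vehicle arm used as the fold-change
#'   reference; must be one of `group_names`.
#' @param drug_groups labels of the treated arms; defaults to every group
#'   except the first two.
#' @param module_specs list of [planted_module()] specifications.
#' @param deg_fraction fraction of background (non-module) genes planted as
#'   differentially expressed in each drug arm, in \[0, 1).
#' @param deg_fold_change planted linear-scale fold change (> 1).
#' @param noise_sd within-group replicate standard deviation, log2 scale.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   intensities.
#' @param seed integer RNG seed; equal seeds give bit-identical studies.
#' @return A `study_config` object.
#' @export
study_config <- function(n_genes = 2000L,
                         n_samples_per_group = 9L,
                         group_names = c("Sham", "Vehicle", "DrugA", "DrugB", "Combo"),
                         reference_group = group_names[2L],
                         drug_groups = setdiff(group_names, group_names[1:2]),
                         module_specs = default_module_specs(group_names),
                         deg_fraction = 0.05,
                         deg_fold_change = 2.0,
                         noise_sd = 0.3,
                         baseline_mean = 8,
                         baseline_sd = 1.2,
                         seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples_per_group <- check_count(n_samples_per_group, "n_samples_per_group", min = 2L)
  if (!is.character(group_names) || length(group_names) < 2L ||
      anyDuplicated(group_names))
    stop_config("'group_names' must be >= 2 distinct labels")
  if (!reference_group %in% group_names)
    stop_config("reference_group '%s' is not a group", reference_group)
  if (!all(drug_groups %in% group_names) || reference_group %in% drug_groups)
    stop_config("'drug_groups' must be groups distinct from the reference")
  if (!is.list(module_specs) ||
      !all(vapply(module_specs, inherits, logical(1), "planted_module")))
    stop_config("'module_specs' must be a list of planted_module objects")
  for (m in module_specs)
    if (!all(m$active_in %in% group_names))
      stop_config("module '%s' is active in unknown group(s)", m$name)
  if (anyDuplicated(vapply(module_specs, `[[`, character(1), "name")))
    stop_config("module names must be unique")
  total <- sum(vapply(module_specs, `[[`, integer(1), "size"))
  if (total > n_genes)
    stop_config("module sizes total %d but only %d genes available", total, n_genes)
  deg_fraction <- check_number(deg_fraction, "deg_fraction", 0, 1, open_upper = TRUE)
  deg_fold_change <- check_number(deg_fold_change, "deg_fold_change", 1, Inf,
                                  open_lower = TRUE)
  noise_sd <- check_number(noise_sd, "noise_sd", 0, Inf, open_lower = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_genes = n_genes, n_samples_per_group = n_samples_per_group,
                 group_names = group_names, reference_group = reference_group,
                 drug_groups = drug_groups, module_specs = module_specs,
                 deg_fraction = deg_fraction, deg_fold_change = deg_fold_change,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = seed),
            class = "study_config")
}

#' Construct an expression study from a matrix and a design
#'
#' @param values numeric genes x samples matrix of log2 intensities, with
#'   gene ids as rownames and sample ids as colnames (both unique).
#' @param design named character vector mapping each sample id to its group.
#' @return an `expression_study`.
#' @export
expression_study <- function(values, design) new_expression_study(values, design)

new_expression_study <- function(values, design) {
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || anyDuplicated(gene_ids))
    stop_config("gene ids must be present and unique")
  if (is.null(sample_ids) || anyDuplicated(sample_ids))
    stop_config("sample ids must be present and unique")
  if (!setequal(names(design), sample_ids) || length(design) != ncol(values))
    stop_config("every sample must map to exactly one group")
  design <- design[sample_ids]
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 design = design, values = values),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  tab <- table(x$design)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

group_samples <- function(study, group) {
  s <- study$sample_ids[study$design == group]
  if (length(s) == 0L) stop_config("no samples in group '%s'", group)
  s
}

# loading boost for planted driver hubs: toward 1, capped at 0.99
driver_loading <- function(loading) pmin(0.99, loading + 0.95 * (1 - loading))

# half-angle (radians) between the two sub-program axes of a driver module
DRIVER_SPLIT_ANGLE <- pi / 9

# loading matrix (members x factor axes) of one module. Modules without a
# driver use a single axis with uniform loading. A module with a driver hub
# models the hub as an apex regulator coordinating two sub-programs: the
# ordinary members split into two halves loading on slightly rotated copies
# of the module axis (rotation +/- DRIVER_SPLIT_ANGLE in the plane of the
# two factors), while the driver loads on the shared axis with its boosted
# loading. The driver then has the strongest expected correlation to every
# member, while cross-half member correlations are damped by
# cos(2 * DRIVER_SPLIT_ANGLE) -- the hub tops intramodular connectivity.
module_loadings <- function(members, driver_genes, loading) {
  n <- length(members)
  if (length(driver_genes) == 0L)
    return(matrix(loading, n, 1L, dimnames = list(members, NULL)))
  lam <- matrix(0, n, 2L, dimnames = list(members, NULL))
  ordinary <- setdiff(members, driver_genes)
  half_a <- ordinary[seq_along(ordinary) %% 2L == 1L]
  half_b <- setdiff(ordinary, half_a)
  phi <- DRIVER_SPLIT_ANGLE
  lam[half_a, ] <- rep(c(loading * cos(phi),  loading * sin(phi)),
                       each = length(half_a))
  lam[half_b, ] <- rep(c(loading * cos(phi), -loading * sin(phi)),
                       each = length(half_b))
  lam[driver_genes, ] <- rep(c(driver_loading(loading), 0),
                             each = length(driver_genes))
  lam
}

# k latent factor vectors of length n with exact zero mean and unit sample
# variance; as many as possible (n - 1) are mutually orthogonal
group_factors <- function(n, k) {
  raw <- matrix(stats::rnorm(n * k), n, k)
  k_orth <- min(k, n - 1L)
  q <- qr.Q(qr(cbind(1, raw[, seq_len(k_orth), drop = FALSE])))[, -1L, drop = FALSE]
  raw[, seq_len(k_orth)] <- q * sqrt(n - 1)
  if (k > k_orth)
    raw[, (k_orth + 1L):k] <- scale(raw[, (k_orth + 1L):k, drop = FALSE])
  raw
}

#' Generate a synthetic expression study with known ground truth
#'
#' Simulates log2-scale expression values under a per-module
#' single-latent-factor model: within each group where a module is active,
#' member gene values are `loading * f + sqrt(1 - loading^2) * e` (scaled by
#' `noise_sd`) around the gene baseline, with a fresh factor `f` per group,
#' so two ordinary members have expected correlation `loading^2` in active
#' groups and 0 elsewhere. Factors are standardized to exact zero mean and
#' unit sample variance, and the factors of distinct modules active in the
#' same group are drawn mutually orthogonal, so planted programs remain
#' distinguishable at small sample sizes. Module members are additionally shifted by
#' `log2(deg_fold_change)` in the drug arms where the module is active (a
#' drug perturbs both the mean and the co-expression of its target module),
#' and a `deg_fraction` of background genes per drug arm receives the same
#' shift with random sign. Background genes are independent noise.
#'
#' @param config a [study_config()].
#' @return list with elements `study` (an `expression_study`) and `truth`
#'   (a `ground_truth` list: planted DEGs per drug arm, module membership,
#'   planted On-module labels per comparison, planted Add-modules and
#'   planted driver genes).
#' @examples
#' sim <- generate_study(study_config(n_genes = 300, seed = 7))
#' dim(sim$study$values)
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config")) stop_config("'config' must be a study_config")
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  ng <- config$n_genes
  ns <- config$n_samples_per_group
  groups <- config$group_names
  gene_ids <- sprintf("g%05d", seq_len(ng))
  design <- rep(groups, each = ns)
  sample_ids <- paste(design, rep(seq_len(ns), times = length(groups)), sep = "_")
  names(design) <- sample_ids

  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  values <- baseline + config$noise_sd *
    matrix(stats::rnorm(ng * length(sample_ids)), ng, length(sample_ids))
  dimnames(values) <- list(gene_ids, sample_ids)

  # assign module members from a random draw without replacement
  pool <- sample(gene_ids)
  offset <- 0L
  membership <- list()
  drivers <- list()
  shift <- log2(config$deg_fold_change)
  module_sign <- stats::setNames(
    sample(c(-1, 1), length(config$module_specs), replace = TRUE),
    vapply(config$module_specs, `[[`, character(1), "name"))

  for (spec in config$module_specs) {
    members <- sort(pool[offset + seq_len(spec$size)])
    offset <- offset + spec$size
    membership[[spec$name]] <- members
    drv <- if (spec$n_drivers > 0L) members[seq_len(spec$n_drivers)] else character(0)
    drivers[[spec$name]] <- drv
  }

  # standardized latent factors per active module per group, orthogonalised
  # within a group so that planted programs stay distinguishable at small n;
  # modules with a driver hub get two factor axes (see module_loadings)
  n_axes <- vapply(config$module_specs,
                   function(m) if (m$n_drivers > 0L) 2L else 1L, integer(1))
  names(n_axes) <- names(membership)
  factors <- list()
  for (g in groups) {
    active <- vapply(config$module_specs,
                     function(m) g %in% m$active_in, logical(1))
    if (!any(active)) next
    nm_act <- names(membership)[active]
    f <- group_factors(ns, sum(n_axes[nm_act]))
    colnames(f) <- rep(nm_act, n_axes[nm_act])
    factors[[g]] <- f
  }

  for (spec in config$module_specs) {
    members <- membership[[spec$name]]
    lam <- module_loadings(members, drivers[[spec$name]], spec$loading)
    for (g in spec$active_in) {
      cols <- sample_ids[design == g]
      f <- factors[[g]][, colnames(factors[[g]]) == spec$name, drop = FALSE]
      eps <- matrix(stats::rnorm(spec$size * ns), spec$size, ns)
      resid_sd <- sqrt(1 - rowSums(lam^2))
      values[members, cols] <- baseline[match(members, gene_ids)] +
        config$noise_sd * (lam %*% t(f) + resid_sd * eps)
    }
    # mean shift in the drug arms where the module is active
    for (g in intersect(spec$active_in, config$drug_groups)) {
      cols <- sample_ids[design == g]
      values[members, cols] <- values[members, cols] + module_sign[spec$name] * shift
    }
  }

  module_genes <- unlist(membership, use.names = FALSE)
  background <- setdiff(gene_ids, module_genes)
  deg_genes <- list()
  n_bg_deg <- floor(config$deg_fraction * length(background))
  for (g in config$drug_groups) {
    module_deg <- unlist(membership[vapply(config$module_specs,
      function(m) g %in% m$active_in, logical(1))], use.names = FALSE)
    bg <- if (n_bg_deg > 0L) sample(background, n_bg_deg) else character(0)
    if (length(bg)) {
      cols <- sample_ids[design == g]
      signs <- sample(c(-1, 1), length(bg), replace = TRUE)
      values[bg, cols] <- values[bg, cols] + signs * shift
    }
    deg_genes[[g]] <- sort(unique(c(module_deg, bg)))
  }

  truth <- ground_truth(config, membership, drivers, deg_genes)
  list(study = new_expression_study(values, design), truth = truth)
}

# planted classification of each module for every drug-vs-background
# comparison, plus the planted Add-modules and driver hubs
ground_truth <- function(config, membership, drivers, deg_genes) {
  specs <- config$module_specs
  active <- lapply(specs, `[[`, "active_in")
  names(active) <- names(membership)
  comparisons <- list()
  for (d in config$drug_groups) {
    for (o in setdiff(c(config$reference_group, config$drug_groups), d)) {
      key <- paste(d, "vs", o)
      in_d <- vapply(active, function(a) d %in% a, logical(1))
      in_o <- vapply(active, function(a) o %in% a, logical(1))
      comparisons[[key]] <- list(
        on = as.character(names(active)[in_d & !in_o]),
        conserved = as.character(names(active)[in_d & in_o]))
    }
  }
  combo <- config$drug_groups[length(config$drug_groups)]
  monos <- setdiff(config$drug_groups, combo)
  add <- as.character(names(active)[vapply(active, function(a)
    combo %in% a && !config$reference_group %in% a && !any(monos %in% a),
    logical(1))])
  structure(list(
    deg_genes = deg_genes,
    modules = membership,
    module_active_in = active,
    on_modules = comparisons,
    add_modules = add,
    driver_genes = as.character(sort(unlist(drivers[add], use.names = FALSE))),
    drivers_by_module = drivers,
    combo_group = combo, mono_groups = monos,
    reference_group = config$reference_group),
    class = "ground_truth")
}
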