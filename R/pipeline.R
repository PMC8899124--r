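#' Configure a full screening run
#'
#' Collects every stage parameter of the workflow: DEG screen (alpha, fold
#' change, correction), module detection (minimum module size, height grid,
#' candidate soft powers), module comparison (theta1/theta2), driver
#' identification (correlation-difference threshold), preservation
#' permutations, the group-role mapping, and the master seed. Stage seeds
#' are derived from the master seed by fixed offsets (simulation +0,
#' preservation +1) and recorded in the report.
#'
#' @param source `"simulate"` (default) or `"files"`.
#' @param study_config a [study_config()] used when `source = "simulate"`;
#'   its seed is overridden by `seed`.
#' @param expr_file,design_file input TSVs when `source = "files"`.
#' @param roles named list mapping the roles `vehicle`, `monoA`, `monoB`,
#'   `combo` to group labels; each role gets exactly one distinct label.
#' @param reference_genes optional known-disease-gene list for the DEG
#'   overlap report.
#' @param alpha,fc_threshold,correction DEG screen parameters (defaults
#'   0.05, 1.5, bonferroni).
#' @param min_module_size,candidate_heights,candidate_powers module
#'   detection parameters.
#' @param theta1,theta2 On-/conserved-module threshold offsets (default 0.1).
#' @param corr_threshold differential-correlation edge threshold (default 0.5).
#' @param driver_mode `"union"` (default) reports, per Add-module network,
#'   every gene appearing in some minimum driver configuration across
#'   `n_matchings` seeded arc-order permutations ([possible_drivers()]);
#'   `"single"` reports the single deterministic lexicographic matching's
#'   drivers ([minimum_driver_set()]).
#' @param n_matchings arc-order permutations for `driver_mode = "union"`.
#' @param n_perm preservation permutations (default 200).
#' @param compute_preservation compute Z_summary for the combination
#'   modules against the vehicle background (default TRUE).
#' @param seed master seed.
#' @param out_dir artifact directory (default: a fresh temporary directory).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(source = c("simulate", "files"),
                            study_config = dimscreen::study_config(),
                            expr_file = NULL, design_file = NULL,
                            roles = list(vehicle = "Vehicle", monoA = "DrugA",
                                         monoB = "DrugB", combo = "Combo"),
                            reference_genes = NULL,
                            alpha = 0.05, fc_threshold = 1.5,
                            correction = "bonferroni",
                            min_module_size = 10L,
                            candidate_heights = NULL,
                            candidate_powers = 1:20,
                            theta1 = 0.1, theta2 = 0.1,
                            corr_threshold = 0.5,
                            driver_mode = c("union", "single"),
                            n_matchings = 20L,
                            n_perm = 200L,
                            compute_preservation = TRUE,
                            seed = 1L,
                            out_dir = NULL) {
  source <- match.arg(source)
  needed <- c("vehicle", "monoA", "monoB", "combo")
  if (!all(needed %in% names(roles)))
    stop_config("role mapping must assign: %s (missing: %s)",
                paste(needed, collapse = ", "),
                paste(setdiff(needed, names(roles)), collapse = ", "))
  labels <- unlist(roles[needed])
  if (anyDuplicated(labels))
    stop_config("role mapping must assign distinct group labels")
  if (source == "files" && (is.null(expr_file) || is.null(design_file)))
    stop_config("source = 'files' needs expr_file and design_file")
  structure(list(source = source, study_config = study_config,
                 expr_file = expr_file, design_file = design_file,
                 roles = roles[needed], reference_genes = reference_genes,
                 alpha = check_number(alpha, "alpha", 0, 1, TRUE, TRUE),
                 fc_threshold = check_number(fc_threshold, "fc_threshold", 1, Inf),
                 correction = correction,
                 min_module_size = check_count(min_module_size, "min_module_size", 3L),
                 candidate_heights = candidate_heights,
                 candidate_powers = candidate_powers,
                 theta1 = check_number(theta1, "theta1", 0, Inf),
                 theta2 = check_number(theta2, "theta2", 0, Inf),
                 corr_threshold = check_number(corr_threshold, "corr_threshold", 0, Inf),
                 driver_mode = match.arg(driver_mode),
                 n_matchings = check_count(n_matchings, "n_matchings", 1L),
                 n_perm = check_count(n_perm, "n_perm", 100L),
                 compute_preservation = check_flag(compute_preservation, "compute_preservation"),
                 seed = check_count(seed, "seed", 0L),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys are [pipeline_config()] arguments; `study_config` may be
#' given as a nested mapping of [study_config()] arguments.
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$study_config))
    raw$study_config <- do.call(study_config, raw$study_config)
  if (is.data.frame(raw$roles)) raw$roles <- as.list(raw$roles)
  do.call(pipeline_config, raw)
}

pipeline_stage_error <- function(stage, fmt, ...) {
  stop(sprintf("[stage %s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

#' Run the full driver-induced modular screening workflow
#'
#' Stages, in order: obtain the study (simulate or read files); DEG screen
#' per drug arm versus vehicle (one-way ANOVA across all arms, fold change,
#' multiplicity correction); per-condition co-expression networks and
#' modularity-optimal module detection on each arm's own DEGs, plus a
#' vehicle background partition on the same genes; On-/conserved-module
#' classification by Jaccard similarity; Add-module screening (combination
#' On-modules that stay On against both monotherapies); optional Z_summary
#' preservation of the combination modules in the vehicle background;
#' minimum-control driver identification per Add-module against each
#' monotherapy, intersected into the synergistic driver set; and
#' node-importance validation of the drivers. Artifacts are written under
#' `config$out_dir` and the run is fully determined by the config and seed.
#'
#' @param config a [pipeline_config()].
#' @return a `dims_report` (also written as `report.json`): per-stage
#'   results, counts, artifact digests, seed and package version.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_config("'config' must be a pipeline_config")
  out_dir <- config$out_dir %||% tempfile("dims_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roles <- config$roles
  drugs <- c(roles$monoA, roles$monoB, roles$combo)

  # --- stage: input ---------------------------------------------------
  truth <- NULL
  if (config$source == "simulate") {
    sc <- config$study_config
    sc$seed <- config$seed
    sim <- generate_study(sc)
    study <- sim$study
    truth <- sim$truth
    write_study(study, file.path(out_dir, "study"), truth)
  } else {
    study <- read_study(expr_file = config$expr_file,
                        design_file = config$design_file)$study
  }
  for (lab in unlist(roles))
    if (!lab %in% study$design)
      pipeline_stage_error("input", "role label '%s' not present in the design", lab)

  # --- stage: DEG screen ----------------------------------------------
  message(sprintf("[deg] ANOVA across %d groups; alpha = %g, FC > %g, correction = %s",
                  length(unique(study$design)), config$alpha,
                  config$fc_threshold, config$correction))
  screen <- deg_screen(study, drugs, roles$vehicle,
                       alpha = config$alpha, fc_threshold = config$fc_threshold,
                       correction = config$correction)
  deg_sets <- lapply(screen, `[[`, "degs")
  for (d in drugs) {
    utils::write.table(screen[[d]]$table,
                       file.path(out_dir, sprintf("deg_%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[deg] %s: %d DEGs", d, length(deg_sets[[d]])))
  }
  overlap <- overlap_report(deg_sets, config$reference_genes)
  jsonlite::write_json(unclass(overlap), file.path(out_dir, "deg_overlap.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- stage: modules per condition -----------------------------------
  min_genes <- max(2L * config$min_module_size, 20L)
  nets <- list(); parts <- list(); veh_nets <- list(); veh_parts <- list()
  for (d in drugs) {
    genes <- deg_sets[[d]]
    if (length(genes) < min_genes)
      pipeline_stage_error("modules", "%s has %d DEGs; need >= %d to build a network",
                           d, length(genes), min_genes)
    nets[[d]] <- build_network(study, d, genes,
                               candidate_powers = config$candidate_powers)
    parts[[d]] <- detect_modules(nets[[d]], config$min_module_size,
                                 config$candidate_heights)
    veh_nets[[d]] <- build_network(study, roles$vehicle, genes,
                                   candidate_powers = config$candidate_powers)
    veh_parts[[d]] <- detect_modules(veh_nets[[d]], config$min_module_size,
                                     config$candidate_heights)
    message(sprintf("[modules] %s: power %d, %d modules, Q = %.3f",
                    d, nets[[d]]$power, length(module_members(parts[[d]])),
                    parts[[d]]$q))
    utils::write.table(
      data.frame(gene = names(parts[[d]]$membership),
                 module_id = unname(parts[[d]]$membership)),
      file.path(out_dir, sprintf("modules_%s.tsv", d)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: On-/conserved-module classification ----------------------
  classifications <- list()
  for (d in drugs) {
    sim_d <- module_similarity_matrix(parts[[d]], veh_parts[[d]])
    cls <- classify_modules(sim_d, config$theta1, config$theta2)
    key <- paste0(d, "_vs_", roles$vehicle)
    classifications[[key]] <- cls
    utils::write.table(cls, file.path(out_dir, sprintf("classification_%s.tsv", key)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(round(sim_d$B, 6),
                       file.path(out_dir, sprintf("similarity_%s.tsv", key)),
                       sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
    message(sprintf("[classify] %s vs %s: %d On, %d conserved (theta1 = %g, theta2 = %g)",
                    d, roles$vehicle, sum(cls$label == "on-module"),
                    sum(cls$label == "conserved"), config$theta1, config$theta2))
  }
  for (m in c(roles$monoA, roles$monoB)) {
    sim_m <- module_similarity_matrix(parts[[roles$combo]], parts[[m]])
    key <- paste0(roles$combo, "_vs_", m)
    classifications[[key]] <- classify_modules(sim_m, config$theta1, config$theta2)
    utils::write.table(classifications[[key]],
                       file.path(out_dir, sprintf("classification_%s.tsv", key)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: Add-modules ----------------------------------------------
  combo <- roles$combo
  combo_specific_degs <- setdiff(deg_sets[[combo]],
                                 union(deg_sets[[roles$monoA]], deg_sets[[roles$monoB]]))
  add <- identify_add_modules(
    on_vs_vehicle = on_module_ids(classifications[[paste0(combo, "_vs_", roles$vehicle)]]),
    class_vs_monoA = classifications[[paste0(combo, "_vs_", roles$monoA)]],
    class_vs_monoB = classifications[[paste0(combo, "_vs_", roles$monoB)]],
    module_genes = module_members(parts[[combo]]),
    specific_degs = combo_specific_degs)
  jsonlite::write_json(unclass(add), file.path(out_dir, "add_modules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[add] %d Add-module(s): %s", length(add$add_modules),
                  paste(add$add_modules, collapse = ", ")))

  # --- stage: preservation (optional) ----------------------------------
  preservation <- NULL
  if (config$compute_preservation) {
    preservation <- lapply(module_members(parts[[combo]]), function(genes) {
      unclass(z_summary(genes, nets[[combo]], veh_nets[[combo]],
                        n_perm = config$n_perm, seed = config$seed + 1L))
    })
    jsonlite::write_json(preservation, file.path(out_dir, "preservation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- stage: drivers ---------------------------------------------------
  driver_results <- list()
  driver_union <- list()
  union_arcs <- list()
  for (m in c("monoA", "monoB")) {
    lab <- roles[[m]]
    per_module <- lapply(add$module_genes, function(genes) {
      net <- suppressWarnings(
        build_condition_network(genes, study, c(combo, lab),
                                config$corr_threshold))
      ds <- minimum_driver_set(net)
      reported <- if (config$driver_mode == "union") {
        possible_drivers(net, k = config$n_matchings, seed = config$seed + 2L)
      } else ds$drivers
      list(net = net, drivers = ds, reported = reported)
    })
    driver_results[[m]] <- per_module
    driver_union[[m]] <- sort(unique(unlist(
      lapply(per_module, function(x) x$reported))))
    union_arcs[[m]] <- do.call(rbind, lapply(per_module, function(x) x$net$arcs))
    message(sprintf("[drivers] %s vs %s: %d driver(s) over %d Add-module network(s)",
                    combo, lab, length(driver_union[[m]]), length(per_module)))
  }
  syn_drivers <- if (length(add$add_modules)) {
    suppressWarnings(synergistic_drivers(driver_union$monoA, driver_union$monoB))
  } else character(0)
  message(sprintf("[drivers] synergistic drivers: %s",
                  if (length(syn_drivers)) paste(syn_drivers, collapse = ", ") else "(none)"))

  # --- stage: driver validation (per Add-module network) ----------------
  importance <- list()
  validation <- list()
  for (mod in add$add_modules) {
    arcs <- rbind(driver_results$monoA[[mod]]$net$arcs,
                  driver_results$monoB[[mod]]$net$arcs)
    arcs <- arcs[!duplicated(arcs[c("tail", "head")]), , drop = FALSE]
    net_m <- new_directed_network(add$module_genes[[mod]], arcs,
                                  comparison = sprintf("Add-module %s union", mod))
    if (length(net_m$nodes) < 2L) next
    importance[[mod]] <- node_importance(net_m)
    n_drv <- length(intersect(syn_drivers, net_m$nodes))
    if (n_drv > 0L && n_drv < length(net_m$nodes))
      validation[[mod]] <- validate_drivers(importance[[mod]], syn_drivers)
  }
  if (length(importance)) {
    imp_all <- do.call(rbind, Map(function(m, tab)
      cbind(module = m, tab), names(importance), importance))
    utils::write.table(imp_all, file.path(out_dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(validation)) {
    jsonlite::write_json(
      lapply(validation, unclass),
      file.path(out_dir, "driver_validation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }
  drivers_json <- list(
    vs_monoA = list(drivers = driver_union$monoA,
                    per_module = lapply(driver_results$monoA, function(x)
                      list(drivers = x$drivers$drivers,
                           matching_size = x$drivers$matching_size,
                           n_drivers = x$drivers$n_drivers))),
    vs_monoB = list(drivers = driver_union$monoB,
                    per_module = lapply(driver_results$monoB, function(x)
                      list(drivers = x$drivers$drivers,
                           matching_size = x$drivers$matching_size,
                           n_drivers = x$drivers$n_drivers))),
    synergistic = syn_drivers)
  jsonlite::write_json(drivers_json, file.path(out_dir, "drivers.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- report -----------------------------------------------------------
  counts <- data.frame(
    condition = drugs,
    n_deg = vapply(deg_sets[drugs], length, integer(1)),
    n_modules = vapply(parts[drugs], function(p) length(module_members(p)), integer(1)),
    n_on = vapply(drugs, function(d) sum(
      classifications[[paste0(d, "_vs_", roles$vehicle)]]$label == "on-module"),
      integer(1)),
    n_conserved = vapply(drugs, function(d) sum(
      classifications[[paste0(d, "_vs_", roles$vehicle)]]$label == "conserved"),
      integer(1)),
    row.names = NULL)
  artifact_files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                                 c("report.json", "summary.tsv")))
  digests <- tools::md5sum(file.path(out_dir, artifact_files))
  names(digests) <- artifact_files
  report <- structure(list(
    seed = config$seed,
    stage_seeds = c(simulate = config$seed, preservation = config$seed + 1L,
                    matchings = config$seed + 2L),
    version = as.character(utils::packageVersion("dimscreen")),
    roles = roles,
    parameters = config[c("alpha", "fc_threshold", "correction",
                          "min_module_size", "theta1", "theta2",
                          "corr_threshold", "driver_mode", "n_matchings",
                          "n_perm")],
    counts = counts,
    deg_sets = deg_sets,
    overlap = overlap,
    partitions = parts,
    vehicle_partitions = veh_parts,
    networks = nets,
    vehicle_networks = veh_nets,
    classifications = classifications,
    add = add,
    preservation = preservation,
    drivers = drivers_json,
    driver_networks = driver_results,
    importance = importance,
    validation = validation,
    truth = truth,
    artifacts = as.list(digests),
    out_dir = out_dir), class = "dims_report")
  report_json <- report[c("seed", "stage_seeds", "version", "roles",
                          "parameters", "counts", "drivers", "artifacts")]
  report_json$add_modules <- add$add_modules
  report_json$on_modules <- lapply(classifications, on_module_ids)
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.table(summarize_counts(report)$table,
                     file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report
}

#' @export
print.dims_report <- function(x, ...) {
  cat(summarize_counts(x)$text, sep = "\n")
  invisible(x)
}

#' Human-readable per-condition summary of a run report
#'
#' @param report a `dims_report` from [run_pipeline()].
#' @return list with `table` (per-condition counts data.frame, plus the
#'   Add-module and synergistic-driver counts as attributes carried in the
#'   extra rows) and `text` (aligned rendering).
#' @export
summarize_counts <- function(report) {
  needed <- c("counts", "add", "drivers")
  missing <- needed[!vapply(needed, function(f) !is.null(report[[f]]), logical(1))]
  if (length(missing))
    stop_config("incomplete report; missing stage output(s): %s",
                paste(missing, collapse = ", "))
  tab <- report$counts
  tab$n_add <- ifelse(tab$condition == report$roles$combo,
                      length(report$add$add_modules), NA_integer_)
  tab$n_drivers <- ifelse(tab$condition == report$roles$combo,
                          length(report$drivers$synergistic), NA_integer_)
  lines <- c(sprintf("dims run (seed %d)", report$seed),
             utils::capture.output(print(tab, row.names = FALSE)))
  if (length(report$add$add_modules) == 0L)
    lines <- c(lines, "note: no Add-modules identified")
  list(table = tab, text = lines)
}
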