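#' Write a study (and optional ground truth) to a directory
#'
#' Writes `expression.tsv` (first column `gene_id`, then one column per
#' sample), `design.tsv` (columns `sample`, `group`) and, when ground truth
#' is supplied, `ground_truth.json`. [read_study()] restores the files
#' losslessly.
#'
#' @param study an `expression_study`.
#' @param directory output directory, created if missing.
#' @param truth optional `ground_truth` from [generate_study()].
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, directory, truth = NULL) {
  if (!inherits(study, "expression_study")) stop_config("'study' must be an expression_study")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop_config("cannot create directory '%s'", directory)
  expr_path <- file.path(directory, "expression.tsv")
  design_path <- file.path(directory, "design.tsv")
  expr <- data.frame(gene_id = study$gene_ids, study$values, check.names = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = study$sample_ids,
                                group = unname(study$design[study$sample_ids])),
                     design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(expression = expr_path, design = design_path)
  if (!is.null(truth)) {
    truth_path <- file.path(directory, "ground_truth.json")
    jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, ground_truth = truth_path)
  }
  invisible(paths)
}

#' Read a study written by [write_study()], or raw expression/design TSVs
#'
#' @param directory directory containing `expression.tsv` and `design.tsv`
#'   (and optionally `ground_truth.json`); alternatively pass explicit
#'   `expr_file`/`design_file` paths.
#' @param expr_file,design_file explicit file paths overriding `directory`.
#' @return list with `study` (an `expression_study`) and `truth` (a
#'   `ground_truth` or NULL).
#' @export
read_study <- function(directory = NULL, expr_file = NULL, design_file = NULL) {
  if (!is.null(directory)) {
    expr_file <- expr_file %||% file.path(directory, "expression.tsv")
    design_file <- design_file %||% file.path(directory, "design.tsv")
  }
  if (is.null(expr_file) || is.null(design_file))
    stop_config("supply a directory or both expr_file and design_file")
  expr <- utils::read.table(expr_file, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(expr[[1L]]))
    stop_config("duplicate gene ids in '%s'", expr_file)
  values <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(values) <- as.character(expr[[1L]])
  storage.mode(values) <- "double"
  des <- utils::read.table(design_file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(des)))
    stop_config("design file must have columns 'sample' and 'group'")
  if (anyDuplicated(des$sample))
    stop_config("duplicate sample ids in '%s'", design_file)
  design <- stats::setNames(as.character(des$group), as.character(des$sample))
  study <- new_expression_study(values, design)
  truth <- NULL
  if (!is.null(directory)) {
    tp <- file.path(directory, "ground_truth.json")
    if (file.exists(tp)) {
      truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
      truth$deg_genes <- lapply(truth$deg_genes, as.character)
      truth$modules <- lapply(truth$modules, as.character)
      truth$drivers_by_module <- lapply(truth$drivers_by_module, as.character)
      truth$on_modules <- lapply(truth$on_modules, function(x)
        lapply(x, as.character))
      truth$module_active_in <- lapply(truth$module_active_in, as.character)
      truth$add_modules <- as.character(truth$add_modules)
      truth$driver_genes <- as.character(truth$driver_genes)
      class(truth) <- "ground_truth"
    }
  }
  list(study = study, truth = truth)
}

#' Read a one-symbol-per-line gene list
#' @param path text file, one gene id per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a GMT gene-set collection
#'
#' Tab-separated format: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (the descriptions are kept in
#'   attribute `"description"`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop_config("GMT line(s) with fewer than 3 fields: %s",
                            paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write a directed network as an edge-list TSV (tail, head, weight)
#' @param net a `directed_network`.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$arcs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a directed network as GraphML
#' @param net a `directed_network`.
#' @param path output `.graphml` file.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
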