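# Pipeline composition: one call from residual expression to a completed
# network bundle, plus bundle persistence as a directory of TSVs with a
# JSON manifest of md5 digests.

#' Run network construction and module detection
#'
#' Composes correlation -> soft-threshold adjacency -> TOM -> average-linkage
#' clustering -> hybrid dynamic tree cut -> eigengenes -> eigengene merging
#' -> module membership -> hub flags, with the constants in \code{config}.
#'
#' @param expr residualized gene x sample expression matrix
#' @param config \code{\link{network_config}}
#' @param annotation optional gene annotation data.frame to embed in the
#'   bundle
#' @return object of class "network_bundle": adjacency, tom, labels, mes,
#'   membership, gene_table (per-gene assignment with flags), annotation,
#'   config
#' @export
run_network <- function(expr, config = network_config(), annotation = NULL) {
  cm <- correlation_matrix(expr)
  adj <- adjacency(cm, config$mode, config$beta)
  tm <- tom(adj)
  dendro <- cluster_genes(tm)
  labels <- cut_tree_dynamic(dendro, tm, config$min_module_size,
                             config$deep_split)
  if (length(module_levels(labels))) {
    mes <- module_eigengene(expr, labels)
    merged <- merge_modules(expr, labels, mes, config$merge_cor_threshold)
    labels <- merged$labels
    mes <- merged$mes
    membership <- module_membership(expr, mes, labels)
    gene_table <- call_hubs(membership, config$hub_quantile,
                            config$assign_cutoff)
  } else {
    mes <- NULL
    membership <- NULL
    gene_table <- NULL
  }
  structure(list(adjacency = adj, tom = tm, dendrogram = dendro,
                 labels = labels, mes = mes, membership = membership,
                 gene_table = gene_table, annotation = annotation,
                 config = config),
            class = "network_bundle")
}

#' @export
print.network_bundle <- function(x, ...) {
  mods <- module_levels(x$labels)
  cat(sprintf("network_bundle: %d genes, %s mode (beta=%s), %d modules, %d grey\n",
              length(x$labels), x$config$mode, x$config$beta, length(mods),
              sum(x$labels == "grey")))
  if (length(mods)) {
    sizes <- table(x$labels)[mods]
    cat("  modules:", paste(sprintf("%s(%d)", mods, sizes), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Persist a network bundle as TSVs plus a JSON manifest
#'
#' Writes assignment.tsv (gene_id, module, MM, one_minus_quantile, hub,
#' unreliable), eigengenes.tsv, adjacency.tsv, annotation.tsv (if present),
#' config.json and manifest.json (file inventory with md5 digests, verified
#' on load).
#'
#' @param bundle network_bundle
#' @param dir output directory
#' @return dir invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- bundle$gene_table
  assignment <- data.frame(gene_id = names(bundle$labels),
                           module = unname(bundle$labels),
                           stringsAsFactors = FALSE)
  if (!is.null(gt)) {
    i <- match(assignment$gene_id, gt$gene_id)
    assignment$MM <- gt$MM[i]
    assignment$one_minus_quantile <- gt$one_minus_quantile[i]
    assignment$hub <- gt$hub[i]
    assignment$unreliable <- gt$unreliable[i]
  }
  write_tsv_file(assignment, file.path(dir, "assignment.tsv"))
  if (!is.null(bundle$mes))
    write_tsv_file(bundle$mes, file.path(dir, "eigengenes.tsv"),
                   row_label = "sample_id")
  if (!is.null(bundle$membership))
    write_tsv_file(bundle$membership$mm, file.path(dir, "mm.tsv"),
                   row_label = "gene_id")
  write_tsv_file(bundle$adjacency, file.path(dir, "adjacency.tsv"),
                 row_label = "gene_id")
  if (!is.null(bundle$annotation))
    write_tsv_file(bundle$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(format = "conetwork-bundle-1",
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load a persisted network bundle
#'
#' Digest verification: every file listed in manifest.json must be present
#' with a matching md5.
#'
#' @param dir bundle directory written by \code{\link{write_bundle}}
#' @return network_bundle (without the TOM/dendrogram, which are not
#'   persisted)
#' @export
read_bundle <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) .stopf("no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(man_path)
  for (f in names(manifest$files)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) .stopf("bundle file missing: %s", f)
    if (unname(tools::md5sum(path)) != manifest$files[[f]])
      .stopf("digest mismatch for bundle file %s", f)
  }
  assignment <- read_tsv_file(file.path(dir, "assignment.tsv"))
  labels <- stats::setNames(assignment$module, assignment$gene_id)
  adj <- as.matrix(read_tsv_file(file.path(dir, "adjacency.tsv"),
                                 row_names = 1))
  colnames(adj) <- rownames(adj)
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"))
  config <- network_config(mode = cfg_raw$mode, beta = cfg_raw$beta,
                           min_module_size = cfg_raw$min_module_size,
                           deep_split = cfg_raw$deep_split,
                           merge_cor_threshold = cfg_raw$merge_cor_threshold,
                           hub_quantile = cfg_raw$hub_quantile,
                           assign_cutoff = cfg_raw$assign_cutoff,
                           predict_cutoff = cfg_raw$predict_cutoff,
                           seed = cfg_raw$seed)
  mes <- NULL
  if (file.exists(file.path(dir, "eigengenes.tsv")))
    mes <- as.matrix(read_tsv_file(file.path(dir, "eigengenes.tsv"),
                                   row_names = 1))
  membership <- NULL
  if (file.exists(file.path(dir, "mm.tsv"))) {
    mm <- as.matrix(read_tsv_file(file.path(dir, "mm.tsv"), row_names = 1))
    tab <- assignment[assignment$module != "grey",
                      c("gene_id", "module", "MM", "one_minus_quantile")]
    tab$quantile <- 1 - tab$one_minus_quantile
    membership <- structure(list(mm = mm, table = tab), class = "membership")
  }
  annotation <- NULL
  if (file.exists(file.path(dir, "annotation.tsv")))
    annotation <- read_tsv_file(file.path(dir, "annotation.tsv"))
  gene_table <- if (all(c("hub", "unreliable") %in% names(assignment))) {
    assignment[assignment$module != "grey", ]
  }
  structure(list(adjacency = adj, tom = NULL, dendrogram = NULL,
                 labels = labels, mes = mes, membership = membership,
                 gene_table = gene_table, annotation = annotation,
                 config = config),
            class = "network_bundle")
}
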