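# Query tools over a completed network run: closest genes within a module,
# gene-set module enrichment, genomic-region lookup and per-gene module
# membership profiles.

.bundle_gene_check <- function(bundle, gene_id) {
  if (!gene_id %in% names(bundle$labels))
    .stopf("unknown gene: %s", gene_id)
}

.bundle_positions <- function(bundle, genes) {
  ann <- bundle$annotation
  if (is.null(ann)) {
    return(data.frame(chromosome = NA_character_, position = NA_real_,
                      row.names = NULL)[rep(1, length(genes)), ])
  }
  i <- match(genes, ann$gene_id)
  data.frame(chromosome = ann$chromosome[i],
             position = (ann$start[i] + ann$end[i]) / 2)
}

#' Tool 1: closest genes to an input gene within its module
#'
#' Ranks all co-module genes by adjacency to the input gene (descending,
#' self excluded) and reports their MM, 1 - q(|MM|) and chromosomal
#' position.
#'
#' @param bundle network_bundle
#' @param gene_id query gene
#' @return data.frame(gene_id, adjacency, MM, one_minus_quantile,
#'   chromosome, position), adjacency non-increasing
#' @export
tool1_closest_genes <- function(bundle, gene_id) {
  .bundle_gene_check(bundle, gene_id)
  mod <- bundle$labels[[gene_id]]
  if (mod == "grey")
    .stopf("gene %s is unassigned (grey); no module to search", gene_id)
  others <- setdiff(names(bundle$labels)[bundle$labels == mod], gene_id)
  adj <- bundle$adjacency[gene_id, others]
  ord <- order(-adj, match(others, rownames(bundle$adjacency)))
  others <- others[ord]
  gt <- bundle$gene_table
  i <- match(others, gt$gene_id)
  out <- data.frame(gene_id = others, adjacency = unname(adj[ord]),
                    MM = gt$MM[i], one_minus_quantile =
                      gt$one_minus_quantile[i],
                    stringsAsFactors = FALSE)
  cbind(out, .bundle_positions(bundle, others))
}

#' Tool 2: module enrichment of a gene set
#'
#' One-sided (enrichment) Fisher's exact test of the gene set against each
#' non-grey module over the bundle's gene universe, with a Bonferroni column
#' across modules. Genes outside the universe are dropped with a warning.
#'
#' @param bundle network_bundle
#' @param gene_set character vector of gene ids
#' @return data.frame(module, overlap, module_size, set_size, universe_size,
#'   p, p_bonferroni) ordered by p
#' @export
tool2_geneset_enrichment <- function(bundle, gene_set) {
  universe <- names(bundle$labels)
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    .warnf("dropping %d gene(s) outside the network universe",
           length(outside))
  gene_set <- intersect(gene_set, universe)
  if (!length(gene_set)) .stopf("gene set has no overlap with the network")
  mods <- module_levels(bundle$labels)
  n <- length(universe)
  rows <- lapply(mods, function(mod) {
    mod_genes <- universe[bundle$labels == mod]
    k <- length(intersect(gene_set, mod_genes))
    tab <- matrix(c(k, length(mod_genes) - k, length(gene_set) - k,
                    n - length(mod_genes) - length(gene_set) + k), 2)
    data.frame(module = mod, overlap = k, module_size = length(mod_genes),
               set_size = length(gene_set), universe_size = n,
               p = stats::fisher.test(tab, alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), ]
}

#' Tool 3: network genes in a genomic region
#'
#' Returns every annotated gene whose 1-based inclusive interval overlaps
#' the query interval by at least one base, with module and MM (grey genes
#' included and labeled).
#'
#' @param bundle network_bundle (annotation required)
#' @param chromosome e.g. "chr3"
#' @param start,end 1-based inclusive query interval
#' @return data.frame(gene_id, module, MM, chromosome, start, end, position)
#' @export
tool3_region <- function(bundle, chromosome, start, end) {
  if (is.null(bundle$annotation)) .stopf("bundle has no gene annotation")
  if (start > end) .stopf("start must be <= end")
  ann <- bundle$annotation
  if (!chromosome %in% ann$chromosome) {
    .warnf("chromosome %s not present in the annotation", chromosome)
    return(data.frame(gene_id = character(0), module = character(0),
                      MM = numeric(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      position = numeric(0)))
  }
  hit <- ann$chromosome == chromosome & ann$start <= end & ann$end >= start
  ann <- ann[hit, , drop = FALSE]
  ann <- ann[ann$gene_id %in% names(bundle$labels), , drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  gt <- bundle$gene_table
  mm <- gt$MM[match(ann$gene_id, gt$gene_id)]
  data.frame(gene_id = ann$gene_id,
             module = unname(bundle$labels[ann$gene_id]),
             MM = mm, chromosome = ann$chromosome, start = ann$start,
             end = ann$end, position = (ann$start + ann$end) / 2,
             stringsAsFactors = FALSE)
}

#' Tool 4: module membership profile of a gene
#'
#' Reports the gene's MM in every module with |MM| > \code{mm_cutoff}
#' (default 0.10), at most \code{max_modules} rows (default 10), sorted by
#' |MM| descending; the gene's own module is flagged. Values are taken from
#' the membership table, not recomputed.
#'
#' @param bundle network_bundle
#' @param gene_id query gene
#' @param mm_cutoff minimum |MM| (default 0.10)
#' @param max_modules row cap (default 10)
#' @return data.frame(module, MM, own_module); empty when no module passes
#' @export
tool4_gene_profile <- function(bundle, gene_id, mm_cutoff = 0.10,
                               max_modules = 10L) {
  .bundle_gene_check(bundle, gene_id)
  mm <- bundle$membership$mm[gene_id, ]
  keep <- abs(mm) > mm_cutoff
  out <- data.frame(module = names(mm)[keep], MM = unname(mm[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$MM)), , drop = FALSE]
  out <- utils::head(out, max_modules)
  out$own_module <- out$module == bundle$labels[[gene_id]]
  rownames(out) <- NULL
  out
}
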