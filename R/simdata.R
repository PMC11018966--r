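# Synthetic data generator: latent-factor co-expression modules with planted
# ground truth, traits driven by module factors, additive age/sex effects,
# gene annotation with tiled coordinates, and per-module marker lists.
#
# Generative model per non-background gene i in module m:
#   x_ij = s_i * w_i * f_{m,j} + sqrt(1 - w_i^2) * eps_ij
#          + age_effect * age_j + sex_effect * sex_j
# with f and eps standard normal, |w_i| drawn from weight_range and
# s_i in {+1, -1}. Background genes are pure noise plus covariate effects.
# Trait k driven by module m: t_kj = loading * f_{m,j} + sqrt(1-loading^2) * eta.

#' Simulation configuration
#'
#' The defaults describe a scaled-down leukocyte RNA-seq cohort: a few
#' hundred samples, five planted modules of 50 genes over a background of
#' unstructured genes, factor loadings 0.6-0.9, an 11% lncRNA share
#' (mirroring 1798 of 15807 transcripts in large whole-blood panels), one
#' trait per module with loading 0.6, and no covariate effects unless
#' requested.
#'
#' @param n_samples number of samples
#' @param n_modules number of planted modules
#' @param genes_per_module integer vector (recycled to n_modules) of module
#'   sizes; keep at or above the detection minimum (30) so planted modules
#'   are recoverable
#' @param n_background_genes unstructured noise genes
#' @param weight_range length-2 numeric in (0,1]: range of |factor loading|
#' @param neg_fraction fraction of genes per module with sign -1
#'   (anti-correlated genes)
#' @param lncrna_fraction fraction of all genes labeled lncRNA
#' @param n_traits number of trait columns
#' @param trait_module integer vector (length n_traits) giving the driving
#'   module of each trait, NA for none; default cycles through modules
#' @param trait_loading correlation-scale loading of a trait on its factor
#' @param factor_correlation n_modules x n_modules symmetric PSD matrix with
#'   unit diagonal; default identity
#' @param age_effect,sex_effect additive covariate coefficients on expression
#' @param seed integer seed; identical configs reproduce bitwise-identical
#'   datasets
#' @return object of class "sim_config"
#' @export
sim_config <- function(n_samples = 300L, n_modules = 5L,
                       genes_per_module = 50L, n_background_genes = 500L,
                       weight_range = c(0.6, 0.9), neg_fraction = 0,
                       lncrna_fraction = 0.11, n_traits = 5L,
                       trait_module = NULL, trait_loading = 0.6,
                       factor_correlation = NULL, age_effect = 0,
                       sex_effect = 0, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_modules = as.integer(n_modules),
              genes_per_module = as.integer(rep_len(genes_per_module,
                                                    n_modules)),
              n_background_genes = as.integer(n_background_genes),
              weight_range = as.numeric(weight_range),
              neg_fraction = neg_fraction,
              lncrna_fraction = lncrna_fraction,
              n_traits = as.integer(n_traits),
              trait_module = trait_module, trait_loading = trait_loading,
              factor_correlation = factor_correlation,
              age_effect = age_effect, sex_effect = sex_effect,
              seed = as.integer(seed))
  if (is.null(cfg$factor_correlation))
    cfg$factor_correlation <- diag(cfg$n_modules)
  if (is.null(cfg$trait_module) && cfg$n_traits > 0)
    cfg$trait_module <- rep_len(seq_len(max(cfg$n_modules, 1L)), cfg$n_traits)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#' @param cfg sim_config
#' @return cfg invisibly-checked (errors name the offending field)
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 1) .stopf("n_samples must be positive")
  if (cfg$n_modules < 0) .stopf("n_modules must be >= 0")
  if (any(cfg$genes_per_module < 1)) .stopf("genes_per_module must be positive")
  if (cfg$n_background_genes < 0) .stopf("n_background_genes must be >= 0")
  wr <- cfg$weight_range
  if (length(wr) != 2 || any(wr <= 0) || any(wr > 1) || wr[1] > wr[2])
    .stopf("weight_range must be an increasing pair within (0, 1]")
  for (nm in c("neg_fraction", "lncrna_fraction", "trait_loading")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      .stopf("%s must lie in [0,1], got %s", nm, v)
  }
  fc <- cfg$factor_correlation
  if (!is.matrix(fc) || nrow(fc) != cfg$n_modules || ncol(fc) != cfg$n_modules)
    .stopf("factor_correlation must be %d x %d", cfg$n_modules, cfg$n_modules)
  if (max(abs(fc - t(fc))) > 1e-8)
    .stopf("factor_correlation must be symmetric")
  if (any(abs(diag(fc) - 1) > 1e-8))
    .stopf("factor_correlation must have unit diagonal")
  ev <- eigen(fc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    .stopf("factor_correlation is not positive semi-definite (min eigenvalue %.3g)",
           min(ev))
  if (cfg$n_traits > 0) {
    tm <- cfg$trait_module
    if (length(tm) != cfg$n_traits)
      .stopf("trait_module must have length n_traits")
    if (any(!is.na(tm) & (tm < 1 | tm > cfg$n_modules)))
      .stopf("trait_module entries must be in 1..n_modules or NA")
  }
  cfg
}

#' Generate a synthetic dataset with planted module structure
#'
#' @param cfg a \code{\link{sim_config}}
#' @return list with components:
#'   \item{expr}{gene x sample expression matrix}
#'   \item{traits}{sample x trait matrix}
#'   \item{covariates}{data.frame(sample_id, age, sex)}
#'   \item{annotation}{data.frame(gene_id, symbol, biotype, chromosome,
#'     start, end); coordinates 1-based inclusive, genes tiled 10 kb apart,
#'     1 kb long, along chr1..chr22 in module order}
#'   \item{markers}{named list: one marker list per planted module holding
#'     the first min(10, floor(size/2)) genes of that module}
#'   \item{truth}{planted ground truth: factor_matrix, gene_module (0 =
#'     background), gene_weight, gene_sign, trait_module, covariates}
#' @export
generate_dataset <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  m <- cfg$n_modules
  n_mod_genes <- sum(cfg$genes_per_module)
  n_genes <- n_mod_genes + cfg$n_background_genes
  if (n_genes < 1) .stopf("no genes to generate")

  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  # latent factors: samples x modules, jointly multivariate normal
  f <- matrix(0, n, max(m, 1L))
  if (m > 0) {
    z <- matrix(stats::rnorm(n * m), n, m)
    f <- z %*% chol(cfg$factor_correlation)
    colnames(f) <- paste0("F", seq_len(m))
  }
  rownames(f) <- sample_ids

  age <- stats::runif(n, 18, 102)
  sex <- stats::rbinom(n, 1L, 0.5)

  gene_module <- c(rep(seq_len(m), times = cfg$genes_per_module),
                   rep(0L, cfg$n_background_genes))
  gene_weight <- numeric(n_genes)
  gene_sign <- rep(1L, n_genes)
  wr <- cfg$weight_range
  if (n_mod_genes > 0) {
    gene_weight[1:n_mod_genes] <- stats::runif(n_mod_genes, wr[1], wr[2])
    for (mm in seq_len(m)) {
      idx <- which(gene_module == mm)
      n_neg <- round(cfg$neg_fraction * length(idx))
      if (n_neg > 0) gene_sign[sample(idx, n_neg)] <- -1L
    }
  }

  expr <- matrix(stats::rnorm(n_genes * n), n_genes, n,
                 dimnames = list(gene_ids, sample_ids))
  if (n_mod_genes > 0) {
    w <- gene_weight[1:n_mod_genes]
    s <- gene_sign[1:n_mod_genes]
    signal <- (s * w) * t(f)[gene_module[1:n_mod_genes], , drop = FALSE]
    expr[1:n_mod_genes, ] <- signal +
      sqrt(1 - w^2) * expr[1:n_mod_genes, , drop = FALSE]
  }
  cov_shift <- cfg$age_effect * age + cfg$sex_effect * sex
  expr <- expr + rep(cov_shift, each = n_genes)

  # traits
  traits <- NULL
  if (cfg$n_traits > 0) {
    traits <- matrix(stats::rnorm(n * cfg$n_traits), n, cfg$n_traits,
                     dimnames = list(sample_ids,
                                     sprintf("cell_type_%02d",
                                             seq_len(cfg$n_traits))))
    tl <- cfg$trait_loading
    for (k in seq_len(cfg$n_traits)) {
      mm <- cfg$trait_module[k]
      if (!is.na(mm))
        traits[, k] <- tl * f[, mm] + sqrt(1 - tl^2) * traits[, k]
    }
  }

  # biotypes: exact lncRNA count, remainder mostly protein coding
  biotype <- rep("protein_coding", n_genes)
  n_lnc <- round(cfg$lncrna_fraction * n_genes)
  if (n_lnc > 0) biotype[sample.int(n_genes, n_lnc)] <- "lncRNA"
  rest <- which(biotype == "protein_coding")
  n_pseudo <- floor(0.05 * length(rest))
  n_other <- floor(0.03 * length(rest))
  if (n_pseudo + n_other > 0) {
    extra <- sample(rest, n_pseudo + n_other)
    biotype[extra[seq_len(n_pseudo)]] <- "pseudogene"
    if (n_other > 0) biotype[extra[n_pseudo + seq_len(n_other)]] <- "other_ncRNA"
  }

  # coordinates: tile genes along chr1..chr22 in gene (module) order
  per_chrom <- ceiling(n_genes / 22)
  chrom_idx <- (seq_len(n_genes) - 1L) %/% per_chrom + 1L
  within <- (seq_len(n_genes) - 1L) %% per_chrom
  start <- within * 10000L + 1L
  annotation <- data.frame(
    gene_id = gene_ids,
    symbol = sprintf("SYM%05d", seq_len(n_genes)),
    biotype = biotype,
    chromosome = paste0("chr", chrom_idx),
    start = start,
    end = start + 999L,
    stringsAsFactors = FALSE)

  markers <- list()
  for (mm in seq_len(m)) {
    idx <- which(gene_module == mm)
    take <- min(10L, max(1L, floor(length(idx) / 2)))
    markers[[sprintf("markers_M%02d", mm)]] <- gene_ids[idx[seq_len(take)]]
  }

  covariates <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                           stringsAsFactors = FALSE)
  truth <- list(factor_matrix = f,
                gene_module = stats::setNames(gene_module, gene_ids),
                gene_weight = stats::setNames(gene_weight, gene_ids),
                gene_sign = stats::setNames(gene_sign, gene_ids),
                trait_module = cfg$trait_module,
                covariates = covariates)
  list(expr = expr, traits = traits, covariates = covariates,
       annotation = annotation, markers = markers, truth = truth)
}

#' Write a generated dataset to a directory of TSV files
#'
#' Layout: expression.tsv (genes x samples, first column gene_id),
#' traits.tsv (samples x traits), covariates.tsv, annotation.tsv,
#' markers.tsv (list_name, gene_id) and truth.json.
#'
#' @param dataset output of \code{\link{generate_dataset}}
#' @param dir output directory (created if missing)
#' @return dir invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(dataset$expr, file.path(dir, "expression.tsv"),
                 row_label = "gene_id")
  if (!is.null(dataset$traits))
    write_tsv_file(dataset$traits, file.path(dir, "traits.tsv"),
                   row_label = "sample_id")
  write_tsv_file(dataset$covariates, file.path(dir, "covariates.tsv"))
  write_tsv_file(dataset$annotation, file.path(dir, "annotation.tsv"))
  mk <- data.frame(
    list_name = rep(names(dataset$markers), lengths(dataset$markers)),
    gene_id = unlist(dataset$markers, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_file(mk, file.path(dir, "markers.tsv"))
  truth <- dataset$truth
  truth$factor_matrix <- NULL   # large; recoverable from seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
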