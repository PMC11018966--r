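# Network construction: Pearson correlation, soft-threshold adjacency
# (signed / unsigned), scale-free topology diagnostics, topological overlap.

#' Network configuration
#'
#' Bundles the tunable constants of a network run. Defaults are the values
#' used throughout: soft-threshold power 10 for signed and 3 for unsigned
#' networks, minimum module size 30, deepSplit 2, eigengene merge threshold
#' 0.8, hub quantile 0.90, assignment cutoff 0.10 and function-prediction
#' cutoff 0.20.
#'
#' @param mode "signed" or "unsigned"
#' @param beta soft threshold power; defaults to 10 (signed) or 3 (unsigned)
#' @param min_module_size smallest allowed module (genes)
#' @param deep_split integer 0-4; larger values cut the dendrogram deeper,
#'   producing more and smaller modules
#' @param merge_cor_threshold modules whose eigengenes correlate above this
#'   are merged
#' @param hub_quantile within-module |MM| quantile above which a gene is a hub
#' @param assign_cutoff genes with |MM| below this are flagged as not clearly
#'   assigned
#' @param predict_cutoff minimum |MM| for guilt-by-association function
#'   prediction
#' @param seed integer seed controlling any randomness downstream
#' @return object of class "network_config" (a named list)
#' @export
network_config <- function(mode = c("signed", "unsigned"), beta = NULL,
                           min_module_size = 30L, deep_split = 2L,
                           merge_cor_threshold = 0.8, hub_quantile = 0.90,
                           assign_cutoff = 0.10, predict_cutoff = 0.20,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(beta)) beta <- if (mode == "signed") 10 else 3
  if (!is.numeric(beta) || beta <= 0) .stopf("beta must be > 0, got %s", beta)
  if (min_module_size < 2) .stopf("min_module_size must be >= 2")
  if (!deep_split %in% 0:4) .stopf("deep_split must be an integer in 0..4")
  for (nm in c("merge_cor_threshold", "hub_quantile", "assign_cutoff",
               "predict_cutoff")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      .stopf("%s must lie in (0,1), got %s", nm, v)
  }
  structure(list(mode = mode, beta = beta,
                 min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 merge_cor_threshold = merge_cor_threshold,
                 hub_quantile = hub_quantile, assign_cutoff = assign_cutoff,
                 predict_cutoff = predict_cutoff, seed = as.integer(seed)),
            class = "network_config")
}

#' Pairwise Pearson correlation between genes
#'
#' @param expr numeric matrix, genes in rows, samples in columns; rownames
#'   are gene ids
#' @return symmetric correlation matrix with unit diagonal and gene ids as
#'   dimnames
#' @export
correlation_matrix <- function(expr) {
  .check_matrix(expr, "expression matrix")
  if (ncol(expr) < 3) .stopf("need at least 3 samples, got %d", ncol(expr))
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(expr)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    .stopf("zero-variance gene(s): %s (filter before correlating)",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  cm <- stats::cor(t(expr))
  cm <- .symmetrize(cm, -1, 1)
  diag(cm) <- 1
  cm
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned: a_ij = |r_ij|^beta, so strong negative correlations count as
#' strong connections. Signed: a_ij = ((1 + r_ij)/2)^beta, so negative
#' correlations are suppressed toward zero.
#'
#' @param cor_mat symmetric correlation matrix (unit diagonal)
#' @param mode "signed" or "unsigned"
#' @param beta soft threshold power (> 0)
#' @return adjacency matrix in [0,1] with unit diagonal; attributes "mode"
#'   and "beta" record the transform
#' @export
adjacency <- function(cor_mat, mode = c("signed", "unsigned"), beta = NULL) {
  mode <- match.arg(mode)
  if (is.null(beta)) beta <- if (mode == "signed") 10 else 3
  if (beta <= 0) .stopf("beta must be > 0")
  .check_matrix(cor_mat, "correlation matrix")
  a <- if (mode == "signed") ((1 + cor_mat) / 2)^beta else abs(cor_mat)^beta
  a <- .symmetrize(a, 0, 1)
  diag(a) <- 1
  attr(a, "mode") <- mode
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology model fit
#'
#' Computes whole-network connectivity k_i (adjacency row sums excluding the
#' diagonal), bins k into equal-width bins, and returns the R^2 of the
#' least-squares regression of log10(frequency) on log10(mean connectivity)
#' over non-empty bins. High values indicate an approximately scale-free
#' degree distribution. Diagnostic only: the soft-threshold power is a fixed
#' configuration value, not selected automatically.
#'
#' @param adj adjacency matrix
#' @param n_bins number of connectivity bins (>= 4)
#' @return R^2 of the log-log fit, in [0,1]
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  .check_matrix(adj, "adjacency matrix")
  if (n_bins < 4) .stopf("n_bins must be >= 4")
  k <- rowSums(adj) - diag(adj)
  if (length(unique(k)) < 2)
    .stopf("all connectivities are equal; scale-free fit undefined")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 2) .stopf("fewer than 2 usable connectivity bins")
  x <- log10(mean_k[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - rss / tss))
}

#' Topological overlap matrix
#'
#' Replaces each adjacency by a normalised count of neighbours shared by the
#' two genes: TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj over u distinct from i and j, and k the
#' connectivity excluding the diagonal. The diagonal is 1. 1 - TOM is the
#' clustering dissimilarity used downstream.
#'
#' @param adj adjacency matrix in [0,1], unit diagonal
#' @return TOM matrix in [0,1] with the same dimnames
#' @export
tom <- function(adj) {
  .check_matrix(adj, "adjacency matrix")
  if (any(adj < 0 | adj > 1)) .stopf("adjacency values must lie in [0,1]")
  a0 <- adj
  diag(a0) <- 0
  l <- a0 %*% a0             # (l)_ij = sum_u a_iu a_uj; a_ii = 0 removes u=i,j
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0   # >= 1 since min(k_i,k_j) >= a_ij
  tm <- (l + a0) / denom
  tm <- .symmetrize(tm, 0, 1)
  diag(tm) <- 1
  dimnames(tm) <- dimnames(adj)
  tm
}
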