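# Module detection: average-linkage clustering on 1 - TOM, a hybrid dynamic
# tree cut (percentile stage-1 cut + PAM-like reassignment with a radius
# constraint), module eigengenes, module membership, eigengene merging and
# hub / assignment flags.

#' Hierarchical clustering of genes on 1 - TOM
#'
#' @param tom_mat topological overlap matrix
#' @return an \code{\link[stats]{hclust}} dendrogram (average linkage)
#' @export
cluster_genes <- function(tom_mat) {
  .check_matrix(tom_mat, "TOM matrix")
  if (nrow(tom_mat) < 2) .stopf("need at least 2 genes to cluster")
  d <- stats::as.dist(1 - tom_mat)
  if (any(!is.finite(d))) .stopf("non-finite dissimilarities")
  stats::hclust(d, method = "average")
}

#' Hybrid dynamic tree cut
#'
#' Stage 1 cuts the dendrogram at h*, the q-th percentile (q = 99 -
#' 2.5 * deep_split) of merge heights, where the percentile is taken over
#' heights not exceeding 0.99 x the maximum height; branches with at least
#' \code{min_module_size} members become modules. Stage 2 (PAM-like) lets
#' each unassigned gene join the module minimising its average dissimilarity
#' to module members, provided that average is (a) below the gene's average
#' dissimilarity to genes outside that module and (b) at most h*; otherwise
#' the gene stays grey. Modules are labeled by size rank with the classical
#' colour vocabulary; ties break toward the lower stage-1 branch index.
#'
#' @param dendro hclust object from \code{\link{cluster_genes}}
#' @param tom_mat the TOM used for clustering (supplies dissimilarities for
#'   stage 2)
#' @param min_module_size minimum module size (default 30)
#' @param deep_split integer 0-4 (default 2); deeper splits cut lower,
#'   giving more and smaller modules
#' @return named character vector: gene id -> module colour ("grey" =
#'   unassigned)
#' @export
cut_tree_dynamic <- function(dendro, tom_mat, min_module_size = 30L,
                             deep_split = 2L) {
  if (!inherits(dendro, "hclust")) .stopf("dendro must be an hclust object")
  if (min_module_size < 2) .stopf("min_module_size must be >= 2")
  if (!deep_split %in% 0:4) .stopf("deep_split must be in 0..4")
  genes <- dendro$labels
  if (is.null(genes)) genes <- as.character(seq_len(nrow(tom_mat)))
  n <- length(genes)
  grey <- stats::setNames(rep("grey", n), genes)
  if (min_module_size > n) {
    .warnf("min_module_size (%d) exceeds gene count (%d); all genes grey",
           min_module_size, n)
    return(grey)
  }

  # average linkage is monotone; remove float-level height inversions from
  # exactly tied merges so cutree accepts the tree
  dendro$height <- cummax(dendro$height)
  h <- dendro$height
  ceiling_h <- 0.99 * max(h)
  h_use <- h[h <= ceiling_h]
  if (!length(h_use)) h_use <- h
  q <- (99 - 2.5 * deep_split) / 100
  h_star <- stats::quantile(h_use, q, names = FALSE)

  # nudge the cut by a float tolerance so exactly tied merge heights fall
  # on one side of it
  cl <- stats::cutree(dendro, h = h_star + 1e-10 * max(h) + 1e-12)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  if (!length(big)) return(grey)
  # size rank ordering, ties toward lower branch index (cutree ids follow
  # gene order, so this is stable)
  big <- big[order(-sizes[as.character(big)], big)]
  module_of <- stats::setNames(rep(0L, n), genes)
  for (i in seq_along(big)) module_of[cl == big[i]] <- i

  # stage 2: PAM-like reassignment of unassigned genes, based on the
  # stage-1 memberships only (no chaining)
  d <- 1 - tom_mat
  stage1 <- module_of
  members <- lapply(seq_along(big), function(i) which(stage1 == i))
  unassigned <- which(stage1 == 0L)
  for (g in unassigned) {
    avg_to <- vapply(members, function(idx) mean(d[g, idx]), numeric(1))
    b <- which.min(avg_to)          # which.min takes the first (lowest) index
    out_idx <- setdiff(seq_len(n), c(members[[b]], g))
    avg_out <- if (length(out_idx)) mean(d[g, out_idx]) else Inf
    if (avg_to[b] < avg_out && avg_to[b] <= h_star) module_of[g] <- b
  }

  # relabel by final size rank so colours reflect merged sizes
  final_sizes <- tabulate(module_of, nbins = length(big))
  ord <- order(-final_sizes, seq_along(big))
  rank_of <- integer(length(big)); rank_of[ord] <- seq_along(big)
  labels <- module_color_labels(length(big))
  out <- grey
  assigned <- module_of > 0L
  out[assigned] <- labels[rank_of[module_of[assigned]]]
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' standardized expression of its genes: genes are scaled to mean 0,
#' variance 1 across samples, the leading right singular vector of the
#' gene x sample submatrix is taken and rescaled to unit variance. The sign
#' is chosen so the eigengene correlates non-negatively with the module's
#' mean standardized profile. A single-gene module's eigengene is that
#' gene's standardized profile.
#'
#' @param expr gene x sample expression matrix
#' @param labels named module assignment from \code{\link{cut_tree_dynamic}}
#' @return sample x module matrix, one standardized column per non-grey
#'   module, columns ordered by decreasing module size
#' @export
module_eigengene <- function(expr, labels) {
  .check_matrix(expr, "expression matrix")
  labels <- labels[rownames(expr)]
  mods <- module_levels(labels)
  if (!length(mods)) .stopf("no non-grey modules")
  n <- ncol(expr)
  mes <- matrix(0, n, length(mods),
                dimnames = list(colnames(expr), mods))
  for (j in seq_along(mods)) {
    idx <- which(labels == mods[j])
    xs <- t(scale(t(expr[idx, , drop = FALSE])))
    if (length(idx) == 1L) {
      me <- drop(xs)
    } else {
      sv <- svd(xs, nu = 0, nv = 1)
      me <- sv$v[, 1]
      # align with the mean standardized profile; when that is degenerate
      # (e.g. exactly balanced signs) fall back to the first gene's profile
      ref <- colMeans(xs)
      if (stats::sd(ref) == 0) ref <- xs[1, ]
      al <- stats::cor(me, ref)
      if (!is.na(al) && al < 0) me <- -me
      me <- me / stats::sd(me)
    }
    mes[, j] <- me
  }
  mes
}

#' Non-grey module labels ordered by decreasing size
#' @param labels module assignment vector
#' @return character vector of module labels
#' @export
module_levels <- function(labels) {
  tab <- table(labels[labels != "grey"])
  if (!length(tab)) return(character(0))
  nm <- names(tab)
  # order by size desc, then by colour-vocabulary rank for determinism
  rank <- match(nm, module_color_labels(max(length(nm), length(.module_colors))))
  rank[is.na(rank)] <- length(.module_colors) + seq_len(sum(is.na(rank)))
  nm[order(-as.integer(tab), rank)]
}

#' Module membership (MM / kME)
#'
#' MM is the Pearson correlation between a gene's profile and each module
#' eigengene; its sign records co- versus counter-expression. For each
#' assigned (non-grey) gene the within-module quantile rank of |MM| is
#' attached: q = rank / module size with ties averaged, so the strongest
#' member has q = 1.
#'
#' @param expr gene x sample expression matrix
#' @param mes eigengene matrix from \code{\link{module_eigengene}}
#' @param labels module assignment
#' @return list of class "membership": \code{mm} (gene x module MM matrix)
#'   and \code{table} (data.frame gene_id, module, MM, quantile,
#'   one_minus_quantile for non-grey genes)
#' @export
module_membership <- function(expr, mes, labels) {
  .check_matrix(expr, "expression matrix")
  shared <- intersect(colnames(expr), rownames(mes))
  if (length(shared) < 3) .stopf("need >= 3 shared samples between expr and MEs")
  mm <- stats::cor(t(expr[, shared, drop = FALSE]),
                   mes[shared, , drop = FALSE])
  labels <- labels[rownames(expr)]
  assigned <- names(labels)[labels != "grey" & labels %in% colnames(mm)]
  tab <- data.frame(gene_id = assigned,
                    module = unname(labels[assigned]),
                    MM = mm[cbind(assigned, labels[assigned])],
                    stringsAsFactors = FALSE)
  tab$quantile <- NA_real_
  for (mod in unique(tab$module)) {
    i <- tab$module == mod
    tab$quantile[i] <- rank(abs(tab$MM[i]), ties.method = "average") / sum(i)
  }
  tab$one_minus_quantile <- 1 - tab$quantile
  structure(list(mm = mm, table = tab), class = "membership")
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively finds the pair of modules whose eigengenes have the highest
#' Pearson correlation; if it exceeds the threshold the smaller module is
#' relabeled into the larger (ties toward the colour-vocabulary order),
#' eigengenes are recomputed, and the search repeats. Grey never merges.
#'
#' @param expr gene x sample expression matrix
#' @param labels module assignment
#' @param mes current eigengene matrix (recomputed internally after merges)
#' @param merge_cor_threshold merge when ME correlation exceeds this
#'   (default 0.8)
#' @return list(labels, mes) after merging; labels are re-ranked by size
#' @export
merge_modules <- function(expr, labels, mes,
                          merge_cor_threshold = 0.8) {
  if (!length(module_levels(labels))) .stopf("no non-grey modules to merge")
  repeat {
    mods <- colnames(mes)
    if (length(mods) < 2) break
    cc <- stats::cor(mes)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    if (cc[best[1], best[2]] <= merge_cor_threshold) break
    a <- mods[best[1]]; b <- mods[best[2]]
    na <- sum(labels == a); nb <- sum(labels == b)
    # absorb the smaller module into the larger; tie -> keep the earlier colour
    keep <- if (na > nb) a else if (nb > na) b else
      mods[min(best)]
    drop <- setdiff(c(a, b), keep)
    labels[labels == drop] <- keep
    mes <- module_eigengene(expr, labels)
  }
  mes <- module_eigengene(expr, labels)
  list(labels = labels, mes = mes)
}

#' Hub and assignment-reliability flags
#'
#' A gene is a hub when its |MM| lies in the top (1 - hub_quantile) of its
#' module, i.e. 1 - q(|MM|) < 1 - hub_quantile. A gene is flagged
#' unreliable when |MM| to its own module is below assign_cutoff.
#'
#' @param membership output of \code{\link{module_membership}}
#' @param hub_quantile default 0.90
#' @param assign_cutoff default 0.10
#' @return the membership table with logical columns hub and unreliable
#' @export
call_hubs <- function(membership, hub_quantile = 0.90, assign_cutoff = 0.10) {
  tab <- membership$table
  tab$hub <- tab$one_minus_quantile < (1 - hub_quantile)
  tab$unreliable <- abs(tab$MM) < assign_cutoff
  tab
}
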