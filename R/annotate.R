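# Module annotation: marker-list hypergeometric enrichment (Bonferroni),
# eigengene-trait correlation with Student asymptotic p-values, cross-network
# module overlap (Fisher's exact), guilt-by-association function prediction
# for lncRNAs, closest-partner summaries and stratified re-runs.

#' Marker-list enrichment of modules
#'
#' Upper-tail hypergeometric test of the overlap between each non-grey
#' module and each marker list, over a fixed gene universe:
#' p = P(X >= overlap) with population universe_size, successes list_size
#' and draws module_size. Bonferroni correction is applied over all
#' module x list tests.
#'
#' @param labels module assignment (named character vector)
#' @param lists named list of character vectors of gene ids
#' @param universe character vector of gene ids; must contain every module
#'   gene. Lists are intersected with the universe before testing.
#' @return data.frame(module, list_name, overlap, module_size, list_size,
#'   universe_size, p_raw, p_bonferroni)
#' @export
list_enrichment <- function(labels, lists, universe = names(labels)) {
  if (!length(universe)) .stopf("empty gene universe")
  mods <- module_levels(labels)
  if (!all(names(labels)[labels != "grey"] %in% universe))
    .stopf("universe must contain every module gene")
  lists <- lapply(lists, intersect, universe)
  n_univ <- length(universe)
  rows <- expand.grid(module = mods, list_name = names(lists),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    mod_genes <- names(labels)[labels == rows$module[i]]
    lst <- lists[[rows$list_name[i]]]
    k <- length(intersect(mod_genes, lst))
    data.frame(module = rows$module[i], list_name = rows$list_name[i],
               overlap = k, module_size = length(mod_genes),
               list_size = length(lst), universe_size = n_univ,
               p_raw = stats::phyper(k - 1, length(lst),
                                     n_univ - length(lst),
                                     length(mod_genes), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out[order(out$p_raw), ]
}

#' Eigengene-trait correlation
#'
#' Pearson correlation between each module eigengene and each trait over
#' pairwise-complete samples, with the Student asymptotic p-value
#' p = 2 P(T_{n-2} >= |r| sqrt(n-2) / sqrt(1-r^2)). Pairs with fewer than
#' \code{min_n} complete samples, or a constant trait on the overlap, are
#' dropped with a warning. Significance is flagged under Bonferroni across
#' all module x trait pairs.
#'
#' @param mes sample x module eigengene matrix
#' @param traits sample x trait numeric matrix (NAs allowed)
#' @param min_n minimum complete samples per pair (default 10)
#' @param alpha familywise significance level for the flag (default 0.05)
#' @return data.frame(module, trait, n_used, r, p, p_bonferroni, significant)
#' @export
trait_correlation <- function(mes, traits, min_n = 10L, alpha = 0.05) {
  shared <- intersect(rownames(mes), rownames(traits))
  if (length(shared) < min_n) .stopf("fewer than %d shared samples", min_n)
  mes <- mes[shared, , drop = FALSE]
  traits <- traits[shared, , drop = FALSE]
  grid <- expand.grid(module = colnames(mes), trait = colnames(traits),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- mes[, grid$module[i]]
    y <- traits[, grid$trait[i]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_n) {
      .warnf("dropping %s x %s: only %d complete samples",
             grid$module[i], grid$trait[i], n)
      return(NULL)
    }
    if (stats::sd(y[ok]) == 0) {
      .warnf("dropping %s x %s: constant trait", grid$module[i],
             grid$trait[i])
      return(NULL)
    }
    r <- stats::cor(x[ok], y[ok])
    p <- cor_pvalue_student(r, n)
    data.frame(module = grid$module[i], trait = grid$trait[i], n_used = n,
               r = r, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) .stopf("no testable module x trait pairs")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonferroni <= alpha
  out[order(out$p), ]
}

#' Student asymptotic p-value for a Pearson correlation
#'
#' Two-sided p-value of r under the null of no correlation, using
#' t = r sqrt(n-2) / sqrt(1-r^2) with n-2 degrees of freedom. |r| = 1
#' returns 0.
#'
#' @param r correlation in [-1, 1]
#' @param n number of samples (> 2)
#' @return p-value in [0, 1]
#' @export
cor_pvalue_student <- function(r, n) {
  if (n <= 2) .stopf("need n > 2 for the Student p-value")
  if (abs(r) > 1 + 1e-12) .stopf("|r| must be <= 1")
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(0)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Cross-tabulation of two module assignments
#'
#' For every pair of modules (one per labeling, grey included) over a shared
#' gene universe, the overlap count and the two-sided Fisher's exact p-value
#' of the 2x2 membership table are computed; a -log10(p) matrix is attached
#' for heatmap rendering.
#'
#' @param labels_a,labels_b named module assignments over the same genes
#' @return list of class "crosstab": counts, p, neglog10p (matrices with
#'   labels_a modules in rows, labels_b in columns)
#' @export
crosstab_overlap <- function(labels_a, labels_b) {
  genes <- intersect(names(labels_a), names(labels_b))
  if (!length(genes)) .stopf("disjoint gene universes")
  if (length(genes) < length(labels_a) || length(genes) < length(labels_b))
    .warnf("restricting crosstab to %d shared genes", length(genes))
  a <- labels_a[genes]; b <- labels_b[genes]
  mods_a <- c(module_levels(a), if (any(a == "grey")) "grey")
  mods_b <- c(module_levels(b), if (any(b == "grey")) "grey")
  n <- length(genes)
  counts <- p <- matrix(NA_real_, length(mods_a), length(mods_b),
                        dimnames = list(mods_a, mods_b))
  for (i in seq_along(mods_a)) for (j in seq_along(mods_b)) {
    in_a <- a == mods_a[i]; in_b <- b == mods_b[j]
    k <- sum(in_a & in_b)
    counts[i, j] <- k
    tab <- matrix(c(k, sum(in_a) - k, sum(in_b) - k,
                    n - sum(in_a) - sum(in_b) + k), 2)
    p[i, j] <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  structure(list(counts = counts, p = p, neglog10p = -log10(p)),
            class = "crosstab")
}

#' Guilt-by-association function prediction
#'
#' Assigns a provisional function to each gene (typically an lncRNA) from
#' the label of its co-expression module: a prediction row is emitted for
#' every gene with |MM| above \code{predict_cutoff} whose module carries a
#' function label. A biotype summary in the total / predicted / hub layout
#' is attached (hubs: 1 - q(|MM|) < 1 - hub_quantile among predicted genes).
#'
#' @param membership output of \code{\link{module_membership}}
#' @param annotation gene annotation data.frame with gene_id and biotype
#' @param module_functions named character vector: module -> function label
#'   (user supplied, e.g. from enrichment results)
#' @param predict_cutoff minimum |MM| (default 0.20)
#' @param hub_quantile hub rule quantile (default 0.90)
#' @return list: predictions (data.frame gene_id, biotype, module,
#'   module_function_label, MM, one_minus_quantile, hub) and summary
#'   (biotype x {total, predicted, hubs} counts)
#' @export
guilt_by_association <- function(membership, annotation, module_functions,
                                 predict_cutoff = 0.20, hub_quantile = 0.90) {
  tab <- call_hubs(membership, hub_quantile = hub_quantile)
  tab <- tab[tab$module %in% names(module_functions) &
               abs(tab$MM) > predict_cutoff, , drop = FALSE]
  bio <- stats::setNames(annotation$biotype, annotation$gene_id)
  pred <- data.frame(gene_id = tab$gene_id,
                     biotype = unname(bio[tab$gene_id]),
                     module = tab$module,
                     module_function_label =
                       unname(module_functions[tab$module]),
                     MM = tab$MM,
                     one_minus_quantile = tab$one_minus_quantile,
                     hub = tab$hub, stringsAsFactors = FALSE)
  all_bio <- sort(unique(annotation$biotype))
  summary <- data.frame(
    biotype = all_bio,
    total = as.integer(table(factor(annotation$biotype, all_bio))),
    predicted = as.integer(table(factor(pred$biotype, all_bio))),
    hubs = as.integer(table(factor(pred$biotype[pred$hub], all_bio))),
    stringsAsFactors = FALSE)
  list(predictions = pred[order(-abs(pred$MM)), ], summary = summary)
}

#' Closest co-expression partner per gene
#'
#' For each gene in a non-singleton, non-grey module, finds the co-module
#' gene with the highest adjacency (self excluded; ties toward the lower
#' gene index). A filtered summary restricted to important genes
#' (1 - q(|MM|) < 0.20) with top adjacency above \code{adjacency_floor}
#' (default: the empirical 3rd quartile of all top adjacencies) is attached,
#' as biotype x biotype contingency tables.
#'
#' @param adj adjacency matrix
#' @param labels module assignment
#' @param membership output of \code{\link{module_membership}}
#' @param annotation gene annotation (gene_id, biotype)
#' @param adjacency_floor numeric or NULL for the data-driven default
#' @return list: partners (gene_id, module, partner, adjacency, flagged for
#'   singleton modules), adjacency_floor, summary_all, summary_important
#'   (partner biotype x gene biotype count tables)
#' @export
closest_partner_summary <- function(adj, labels, membership, annotation,
                                    adjacency_floor = NULL) {
  genes <- rownames(adj)
  labels <- labels[genes]
  partners <- data.frame(gene_id = genes, module = unname(labels),
                         partner = NA_character_, adjacency = NA_real_,
                         singleton = FALSE, stringsAsFactors = FALSE)
  for (mod in module_levels(labels)) {
    idx <- which(labels == mod)
    if (length(idx) < 2) {
      partners$singleton[idx] <- TRUE
      next
    }
    sub <- adj[idx, idx, drop = FALSE]
    diag(sub) <- -Inf
    best <- apply(sub, 1, which.max)
    partners$partner[idx] <- genes[idx][best]
    partners$adjacency[idx] <- sub[cbind(seq_along(idx), best)]
  }
  partners$singleton[labels == "grey"] <- NA
  has <- !is.na(partners$adjacency)
  if (is.null(adjacency_floor))
    adjacency_floor <- stats::quantile(partners$adjacency[has], 0.75,
                                       names = FALSE)
  bio <- stats::setNames(annotation$biotype, annotation$gene_id)
  lv <- sort(unique(annotation$biotype))
  xtab <- function(rows) {
    table(partner_biotype = factor(bio[rows$partner], lv),
          gene_biotype = factor(bio[rows$gene_id], lv))
  }
  tab <- membership$table
  important <- tab$gene_id[tab$one_minus_quantile < 0.20]
  sel <- has & partners$gene_id %in% important &
    partners$adjacency > adjacency_floor
  list(partners = partners, adjacency_floor = adjacency_floor,
       summary_all = xtab(partners[has, ]),
       summary_important = xtab(partners[sel, ]))
}

#' Stratified network re-runs
#'
#' Re-runs residualization, network construction, module detection and
#' merging on each sample stratum (e.g. males / females) and, when a pooled
#' assignment is supplied, cross-tabulates each stratum's modules against
#' the pooled modules restricted to important genes (1 - q(|MM|) < 0.20 in
#' the stratum network).
#'
#' @param expr gene x sample matrix (pre-residualization)
#' @param cov covariate table (sample_id, age, sex)
#' @param strata named list of character vectors of sample ids
#' @param config \code{\link{network_config}}
#' @param pooled optional pooled run (list with labels and membership) for
#'   overlap tabulation
#' @param min_stratum smallest allowed stratum (default 30)
#' @return named list per stratum: the network run (see
#'   \code{\link{run_network}}) plus crosstab_vs_pooled when pooled is given
#' @export
run_stratified <- function(expr, cov, strata, config = network_config(),
                           pooled = NULL, min_stratum = 30L) {
  out <- list()
  for (nm in names(strata)) {
    ids <- intersect(strata[[nm]], colnames(expr))
    if (length(ids) < min_stratum)
      .stopf("stratum '%s' has %d samples (< %d)", nm, length(ids),
             min_stratum)
    sub_cov <- cov[cov$sample_id %in% ids, , drop = FALSE]
    # within a single-sex stratum the sex column is constant; drop it
    res <- if (length(unique(sub_cov$sex)) < 2) {
      sub_cov$sex <- NULL
      sub_cov$sex <- 0
      r <- expr[, ids, drop = FALSE]
      x <- cbind(1, sub_cov$age[match(ids, sub_cov$sample_id)])
      t(qr.resid(qr(x), t(r)))
    } else {
      residualize(expr[, ids, drop = FALSE], sub_cov)
    }
    run <- run_network(res, config)
    if (!is.null(pooled)) {
      tab <- run$membership$table
      important <- tab$gene_id[tab$one_minus_quantile < 0.20]
      run$crosstab_vs_pooled <- crosstab_overlap(
        run$labels[important], pooled$labels[important])
    }
    out[[nm]] <- run
  }
  out
}
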