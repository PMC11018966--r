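make_labels <- function(sizes, grey = 0) {
  mods <- c("turquoise", "blue", "brown", "yellow")[seq_along(sizes)]
  lab <- c(rep(mods, sizes), rep("grey", grey))
  setNames(lab, sprintf("g%03d", seq_along(lab)))
}

test_that("hypergeometric enrichment matches exact enumeration", {
  # universe 20, list 5, module 5, overlap 5 -> p = 1 / C(20,5)
  labels <- make_labels(c(5, 15))
  universe <- names(labels)
  lists <- list(hit = names(labels)[1:5])
  res <- list_enrichment(labels, lists, universe)
  row <- res[res$module == "turquoise", ]
  expect_equal(row$overlap, 5)
  expect_equal(row$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
  # overlap 0 -> p = 1
  lists0 <- list(miss = names(labels)[6:10])
  res0 <- list_enrichment(labels, lists0, universe)
  expect_equal(res0$p_raw[res0$module == "turquoise"], 1)
})

test_that("hypergeometric tail agrees with the pmf-summation oracle", {
  set.seed(101)
  for (rep in 1:150) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    p_impl <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_impl, hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("Bonferroni column satisfies its invariants", {
  labels <- make_labels(c(6, 6), grey = 8)
  set.seed(102)
  lists <- list(a = sample(names(labels), 5), b = sample(names(labels), 7),
                c = sample(names(labels), 3))
  res <- list_enrichment(labels, lists)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * nrow(res)))
  expect_true(all(res$p_bonferroni >= res$p_raw))
  expect_true(all(res$overlap <= pmin(res$module_size, res$list_size)))
})

test_that("trait correlation p-values match the quadrature oracle", {
  for (case in list(c(0.5, 20), c(0.12, 60), c(-0.8, 15), c(0.3, 500))) {
    p <- cor_pvalue_student(case[1], case[2])
    expect_equal(p, t_p_quadrature(case[1], case[2]), tolerance = 1e-8)
  }
  expect_equal(cor_pvalue_student(0, 20), 1)
  expect_equal(cor_pvalue_student(1, 20), 0)
  expect_equal(cor_pvalue_student(-1, 20), 0)
})

test_that("trait correlation p is decreasing in |r| and in n", {
  r_grid <- seq(0.05, 0.95, by = 0.1)
  p_r <- sapply(r_grid, cor_pvalue_student, n = 30)
  expect_true(all(diff(p_r) < 0))
  n_grid <- c(10, 20, 50, 100, 400)
  p_n <- sapply(n_grid, function(n) cor_pvalue_student(0.3, n))
  expect_true(all(diff(p_n) < 0))
})

test_that("trait table recovers a planted loading as the top association", {
  d <- generate_dataset(sim_config(n_samples = 500, n_modules = 3,
                                   genes_per_module = 40,
                                   n_background_genes = 40, n_traits = 3,
                                   trait_module = c(2L, NA, NA),
                                   trait_loading = 0.6, seed = 103))
  gm <- d$truth$gene_module
  labels <- setNames(ifelse(gm > 0, c("turquoise", "blue", "brown")[pmax(gm, 1)],
                            "grey"), names(gm))
  mes <- module_eigengene(d$expr, labels)
  tc <- trait_correlation(mes, d$traits)
  top <- tc[1, ]
  expect_equal(top$trait, "cell_type_01")
  expect_equal(top$module, "blue")     # planted module 2
  expect_lt(abs(abs(top$r) - 0.6), 0.08)
  expect_true(top$significant)
})

test_that("trait correlation handles missing values and constant traits", {
  set.seed(104)
  mes <- matrix(rnorm(60), 30, 2,
                dimnames = list(paste0("s", 1:30), c("turquoise", "blue")))
  traits <- matrix(rnorm(60), 30, 2,
                   dimnames = list(paste0("s", 1:30), c("t1", "t2")))
  traits[1:15, 2] <- NA
  tc <- suppressWarnings(trait_correlation(mes, traits, min_n = 10))
  expect_equal(unique(tc$n_used[tc$trait == "t2"]), 15)
  traits[, 2] <- 3
  w <- capture_warnings(trait_correlation(mes, traits))
  expect_match(w, "constant trait", all = TRUE)
  expect_length(w, 2)   # one per module
})

test_that("self-crosstab diagonals match Fisher enumeration and dominate rows", {
  labels <- make_labels(c(30, 70))
  ct <- crosstab_overlap(labels, labels)
  expect_equal(ct$p["turquoise", "turquoise"],
               fisher_oracle(matrix(c(30, 0, 0, 70), 2)), tolerance = 1e-10)
  expect_equal(ct$p["blue", "blue"],
               fisher_oracle(matrix(c(70, 0, 0, 30), 2)), tolerance = 1e-10)
  for (i in rownames(ct$p)) {
    expect_true(all(ct$p[i, i] <= ct$p[i, colnames(ct$p) != i]))
  }
  expect_equal(ct$counts["turquoise", "turquoise"], 30)
  expect_equal(ct$counts["blue", "blue"], 70)
  expect_equal(ct$counts["turquoise", "blue"], 0)
})

test_that("crosstab Fisher p matches enumeration on random labelings", {
  set.seed(105)
  for (rep in 1:5) {
    n <- 30
    la <- setNames(sample(c(rep("turquoise", 18), rep("grey", 12))),
                   sprintf("g%03d", 1:n))
    lb <- setNames(sample(c(rep("blue", 11), rep("grey", 19))),
                   sprintf("g%03d", 1:n))
    ct <- crosstab_overlap(la, lb)
    k <- ct$counts["turquoise", "blue"]
    tab <- matrix(c(k, 18 - k, 11 - k, n - 18 - 11 + k), 2)
    expect_equal(ct$p["turquoise", "blue"], fisher_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("guilt-by-association applies the MM > 0.20 rule exactly", {
  tab <- data.frame(
    gene_id = paste0("g", 1:5),
    module = c("turquoise", "turquoise", "turquoise", "blue", "blue"),
    MM = c(0.25, 0.15, -0.30, 0.9, 0.21),
    quantile = c(0.5, 0.25, 0.95, 1.0, 0.5),
    one_minus_quantile = c(0.5, 0.75, 0.05, 0.0, 0.5),
    stringsAsFactors = FALSE)
  membership <- structure(list(mm = NULL, table = tab),
                          class = "membership")
  ann <- data.frame(gene_id = paste0("g", 1:5),
                    biotype = c("lncRNA", "lncRNA", "protein_coding",
                                "lncRNA", "protein_coding"),
                    stringsAsFactors = FALSE)
  fns <- c(turquoise = "neutrophil")   # blue carries no label
  gba <- guilt_by_association(membership, ann, fns, predict_cutoff = 0.20)
  expect_setequal(gba$predictions$gene_id, c("g1", "g3"))  # 0.15 fails cutoff
  expect_equal(unique(gba$predictions$module_function_label), "neutrophil")
  expect_true(gba$predictions$hub[gba$predictions$gene_id == "g3"])
  s <- gba$summary
  expect_equal(s$predicted[s$biotype == "lncRNA"], 1)
  expect_equal(s$total[s$biotype == "lncRNA"], 3)
})

test_that("planted lncRNAs in labeled modules receive predictions", {
  fix <- small_bundle(seed = 106)
  b <- fix$bundle
  mods <- module_levels(b$labels)
  fns <- setNames(paste0("fn_", mods), mods)
  gba <- guilt_by_association(b$membership, fix$data$annotation, fns)
  planted_lnc <- fix$data$annotation$gene_id[
    fix$data$annotation$biotype == "lncRNA" &
      fix$data$truth$gene_module > 0]
  predicted <- intersect(planted_lnc, gba$predictions$gene_id)
  expect_gte(length(predicted), 0.9 * length(planted_lnc))
})

test_that("closest partners maximise adjacency within the module", {
  fix <- small_bundle(seed = 107, n_samples = 80, n_modules = 2,
                      genes_per_module = 31, n_background = 20)
  b <- fix$bundle
  cp <- closest_partner_summary(b$adjacency, b$labels, b$membership,
                                fix$data$annotation)
  have <- cp$partners[!is.na(cp$partners$adjacency), ]
  for (i in sample(nrow(have), 10)) {
    g <- have$gene_id[i]
    mod_genes <- setdiff(names(b$labels)[b$labels == have$module[i]], g)
    expect_equal(have$adjacency[i], max(b$adjacency[g, mod_genes]))
  }
  # floor defaults to the 3rd quartile of top adjacencies
  expect_equal(cp$adjacency_floor,
               unname(quantile(have$adjacency, 0.75)))
  # two-gene module: mutual closest partners
  labels2 <- setNames(c("turquoise", "turquoise"), rownames(b$adjacency)[1:2])
  cp2 <- closest_partner_summary(b$adjacency[1:2, 1:2], labels2,
                                 b$membership, fix$data$annotation)
  expect_equal(cp2$partners$partner, rev(cp2$partners$gene_id))
})

test_that("stratified halves of a planted dataset significantly overlap", {
  d <- generate_dataset(sim_config(n_samples = 300, n_modules = 2,
                                   genes_per_module = 40,
                                   n_background_genes = 40,
                                   age_effect = 0.02, seed = 108))
  ids <- colnames(d$expr)
  strata <- list(h1 = ids[1:150], h2 = ids[151:300])
  cfg <- network_config("signed")
  runs <- run_stratified(d$expr, d$covariates, strata, cfg)
  ct <- crosstab_overlap(runs$h1$labels, runs$h2$labels)
  # every planted module matches across halves with a significant overlap
  n_pairs <- length(ct$p)
  for (m in 1:2) {
    genes <- names(d$truth$gene_module)[d$truth$gene_module == m]
    m1 <- names(which.max(table(runs$h1$labels[genes])))
    m2 <- names(which.max(table(runs$h2$labels[genes])))
    expect_lt(ct$p[m1, m2] * n_pairs, 0.05)
  }
  expect_error(run_stratified(d$expr, d$covariates,
                              list(tiny = ids[1:10]), cfg),
               "stratum")
})
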