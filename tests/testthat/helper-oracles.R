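# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and, where possible, the library routines) they
# check.

# O(n^3) direct-summation TOM
tom_oracle <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# two-pass covariance Pearson correlation
cor_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# upper-tail hypergeometric P(X >= k), term-by-term pmf summation via
# log-binomials (never calls phyper/dhyper)
hyper_tail_oracle <- function(k, list_size, universe_size, draws) {
  hi <- min(list_size, draws)
  if (k > hi) return(0)
  i <- max(k, max(0, draws - (universe_size - list_size))):hi
  sum(exp(lchoose(list_size, i) +
          lchoose(universe_size - list_size, draws - i) -
          lchoose(universe_size, draws)))
}

# Fisher's exact p for a 2x2 table by enumeration over all tables with the
# observed margins
fisher_oracle <- function(tab, alternative = "two.sided") {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, a_range) + lchoose(n - c1, r1 - a_range) -
    lchoose(n, r1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(a_obs, a_range)]
  switch(alternative,
         two.sided = sum(p[p <= obs * (1 + 1e-7)]),
         greater = sum(p[a_range >= a_obs]),
         less = sum(p[a_range <= a_obs]))
}

# two-sided Student-t correlation p-value by quadrature of the t density
# (density written out from the gamma-function formula; never calls pt/dt)
t_p_quadrature <- function(r, n) {
  df <- n - 2
  t_obs <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, t_obs, Inf, rel.tol = 1e-12)$value
}

# naive O(n^3) average-linkage agglomeration; returns the cophenetic
# distance matrix (height at which each pair first shares a cluster)
average_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  dd <- d
  diag(dd) <- Inf
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1]) best <- c(avg, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# a small completed network run shared by query/annotation tests
small_bundle <- function(seed = 101, n_samples = 150, n_modules = 3,
                         genes_per_module = 40, n_background = 60) {
  cfg <- sim_config(n_samples = n_samples, n_modules = n_modules,
                    genes_per_module = genes_per_module,
                    n_background_genes = n_background,
                    weight_range = c(0.65, 0.9), seed = seed)
  d <- generate_dataset(cfg)
  bundle <- run_network(d$expr, network_config("signed"),
                        annotation = d$annotation)
  list(bundle = bundle, data = d)
}
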