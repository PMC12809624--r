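# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use naive formulations, not the package's code paths.

# Brute-force betaMNTD: explicit double loop over taxa of each pair.
oracle_beta_mntd <- function(table, dists) {
  f <- sweep(table, 1, rowSums(table), "/")
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    taxa_j <- colnames(table)[table[j, ] > 0]
    taxa_k <- colnames(table)[table[k, ] > 0]
    s <- 0
    for (a in taxa_j) s <- s + f[j, a] * min(dists[a, taxa_k])
    for (b in taxa_k) s <- s + f[k, b] * min(dists[b, taxa_j])
    out[j, k] <- s / 2
  }
  out
}

# Closed-form expected rarefied richness (hypergeometric).
oracle_rarefied_richness <- function(counts, depth) {
  tot <- sum(counts)
  sum(1 - exp(lchoose(tot - counts, depth) - lchoose(tot, depth)))
}

# Independent Holm step-down adjustment.
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Random small community instance on a random tree.
random_instance <- function(n_taxa, n_samples, seed) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n_taxa)
    tree$tip.label <- paste0("t", seq_len(n_taxa))
    tab <- matrix(rpois(n_samples * n_taxa, 3), n_samples, n_taxa,
                  dimnames = list(paste0("s", seq_len(n_samples)), tree$tip.label))
    empty <- rowSums(tab) == 0
    tab[empty, 1] <- 1L
    list(tree = tree, table = tab)
  })
}

# Pooled RCbray values for tables generated by the null process itself:
# one fixed occurrence/abundance pool, `n_reps` seeded null tables, all
# upper-triangle RC values pooled.
rc_self_calibration <- function(master_seed, n_reps = 5, n_null = 199) {
  base <- withr::with_seed(master_seed, {
    m <- matrix(rpois(12 * 50, rexp(12 * 50, 1 / 10)), 12, 50,
                dimnames = list(paste0("s", 1:12), paste0("t", 1:50)))
    m[rowSums(m) == 0, 1] <- 1L
    m
  })
  occ <- colMeans(base > 0)
  mab <- colMeans(base / rowSums(base))
  unlist(lapply(seq_len(n_reps), function(r) {
    nulltab <- withr::with_seed(master_seed + r, {
      t(vapply(seq_len(nrow(base)), function(j) {
        raup_crick_null(sum(base[j, ] > 0), sum(base[j, ]), occ, mab)
      }, integer(ncol(base))))
    })
    dimnames(nulltab) <- dimnames(base)
    rc <- raup_crick_bray(nulltab, n_null = n_null, seed = master_seed + 100 + r)
    rc[upper.tri(rc)]
  }))
}

# Triangle / path / star / two-clique graph fixtures as assoc_networks.
fixture_network <- function(kind) {
  edge <- function(from, to, sign = "+", weight = 0.5)
    data.frame(from = from, to = to, sign = sign, weight = weight,
               cooccurrence_score = 1)
  switch(kind,
    triangle = assoc_network(c("A", "B", "C"),
      rbind(edge("A", "B"), edge("B", "C"), edge("A", "C"))),
    path = assoc_network(c("A", "B", "C"),
      rbind(edge("A", "B"), edge("B", "C"))),
    star = assoc_network(c("hub", "l1", "l2", "l3", "l4"),
      rbind(edge("hub", "l1"), edge("hub", "l2"), edge("hub", "l3"),
            edge("hub", "l4"))),
    two_clique = {
      nodes <- data.frame(id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                          domain_marker = rep(c("16S", "18S"), each = 3),
                          size_fraction = rep(c("small", "large"), each = 3))
      assoc_network(nodes, rbind(
        edge("a1", "a2"), edge("a2", "a3"), edge("a1", "a3"),
        edge("b1", "b2"), edge("b2", "b3"), edge("b1", "b3")))
    })
}
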