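test_that("rarefaction conserves depth and matches the hypergeometric richness", {
  inst <- random_instance(20, 4, seed = 51)
  tab <- inst$table * 5L
  depth <- min(rowSums(tab)) - 3L
  rr <- rarefy(tab, depth, seed = 1)
  expect_true(all(rowSums(rr) == depth))
  expect_identical(attr(rr, "provenance"), "rarefied")

  # depth equal to a sample's total leaves it unchanged
  one <- tab[1, , drop = FALSE]
  expect_identical(unname(rarefy(one, sum(one), seed = 2)[1, ]),
                   as.integer(unname(one[1, ])))

  # mean richness over seeded draws matches the closed form
  counts <- c(40L, 25L, 10L, 5L, 3L, 1L, 1L)
  m <- matrix(counts, 1, dimnames = list("s1", paste0("t", 1:7)))
  d <- 20L
  rich <- vapply(1:1000, function(r) sum(rarefy(m, d, seed = 3000 + r) > 0), 0)
  expect_equal(mean(rich), oracle_rarefied_richness(counts, d), tolerance = 0.01)

  # expectation-preserving relative abundances
  fr <- vapply(1:1000, function(r) rarefy(m, d, seed = 3000 + r)[1, 1] / d, 0)
  expect_equal(mean(fr), counts[1] / sum(counts), tolerance = 0.02)

  expect_error(rarefy(m, sum(counts) + 1, seed = 1), "shallower")
  expect_warning(rarefy(rbind(m, s2 = 2L * counts), sum(counts) + 1, seed = 1,
                        drop_shallow = TRUE), "dropping")
})

test_that("alpha diversity matches closed forms", {
  tab <- rbind(even = c(5, 5, 5, 5), mono = c(9, 0, 0, 0))
  colnames(tab) <- paste0("t", 1:4)
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  a <- alpha_diversity(tab, tr)
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$pielou[1], 1)
  expect_equal(a$shannon[2], 0)
  expect_true(is.na(a$pielou[2]))
  # all tips present: Faith PD = total branch length
  expect_equal(a$faith_pd[1], sum(tr$edge.length))
  expect_error(alpha_diversity(rbind(tab, empty = c(0, 0, 0, 0))), "empty")
})

test_that("rank abundance is normalised, ordered and tie-stable", {
  tab <- matrix(c(6, 3, 1), 1, dimnames = list("s1", c("b", "a", "c")))
  ra <- rank_abundance(tab)
  expect_equal(ra$rel_abund, c(0.6, 0.3, 0.1))
  expect_equal(ra$rank, 1:3)
  expect_equal(sum(ra$rel_abund), 1)
  # tie broken by column order
  tie <- matrix(c(2, 2, 1), 1, dimnames = list("s1", c("z", "a", "m")))
  expect_equal(rank_abundance(tie)$asv_id, c("z", "a", "m"))
})

test_that("Bray-Curtis matches hand computation and is a semimetric", {
  tab <- rbind(j = c(0.5, 0.5, 0), k = c(0, 0.5, 0.5), l = c(0.5, 0.5, 0))
  colnames(tab) <- paste0("t", 1:3)
  bc <- as.matrix(bray_curtis(tab))
  expect_equal(bc["j", "k"], 0.5)
  expect_equal(bc["j", "l"], 0)
  disj <- rbind(a = c(1, 0), b = c(0, 1)); colnames(disj) <- c("x", "y")
  expect_equal(as.matrix(bray_curtis(disj))["a", "b"], 1)

  inst <- random_instance(15, 6, seed = 52)
  m <- as.matrix(bray_curtis(inst$table))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(bray_curtis(rbind(inst$table, z = rep(0, 15))), "zero total")
})

test_that("PERMANOVA partitions variance sequentially and sums to one", {
  inst <- random_instance(20, 12, seed = 53)
  meta <- data.frame(sample_id = rownames(inst$table),
                     g = rep(c("A", "B"), 6),
                     z = withr::with_seed(54, rnorm(12)))
  pv <- permanova(bray_curtis(inst$table), meta, c("g", "z"), n_perm = 99, seed = 5)
  expect_equal(sum(pv$r2[1:3]), 1)
  expect_equal(pv$r2[4], 1)
  expect_true(all(pv$p[1:2] > 0 & pv$p[1:2] <= 1))
  expect_error(permanova(bray_curtis(inst$table), within(meta, g <- "A"), "g"),
               "single level")
})

test_that("PERMANOVA agrees with adonis2 on a shared permutation matrix", {
  inst <- random_instance(25, 10, seed = 55)
  meta <- data.frame(sample_id = rownames(inst$table),
                     g = rep(c("A", "B"), 5),
                     z = withr::with_seed(56, rnorm(10)))
  bc <- bray_curtis(inst$table)
  perm <- withr::with_seed(57, t(replicate(99, sample.int(10))))
  mine <- permanova(bc, meta, c("g", "z"), n_perm = 99, seed = 57)
  ref <- vegan::adonis2(bc ~ g + z, data = meta, permutations = perm, by = "terms")
  expect_equal(mine$r2[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(mine$f[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(mine$p[1:2], ref$`Pr(>F)`[1:2], tolerance = 1e-12)
})

test_that("time decay enumerates within-group pairs with positive lags", {
  n <- 6
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     date = seq(as.Date("2020-01-15"), by = "month", length.out = n),
                     site = "x", size_fraction = "small")
  dm <- matrix(runif(n * n), n, n); dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- meta$sample_id
  td <- time_decay(dm, meta)
  expect_equal(nrow(td), n * (n - 1) / 2)
  expect_true(all(td$dt_months > 0))

  # drifting community: dissimilarity grows with lag
  cfg <- scenario_config(n_taxa = 80, n_months = 30, pop_size = 400,
                         immigration = 0, selection_width = Inf, seed = 58)
  tr <- simulate_tree(80, seed = 59)
  tv <- evolve_traits(tr, 1, seed = 60)
  sim <- simulate_communities(tr, tv, rep(0, 30), cfg, seed = 61)
  td2 <- time_decay(bray_curtis(sim$table), sim$meta)
  expect_gt(cor(td2$dt_months, td2$dissimilarity, method = "spearman"), 0)
})
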