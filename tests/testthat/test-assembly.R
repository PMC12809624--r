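test_that("betaMNTD matches hand evaluation and the brute-force oracle", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tab <- rbind(j = c(A = 1, B = 0, C = 0), k = c(A = 0, B = 1, C = 1))
  expect_equal(beta_mntd(tab, d)["j", "k"], 3.0)

  # identical communities: nearest relative is self
  same <- rbind(s1 = c(A = 2, B = 1, C = 0), s2 = c(A = 2, B = 1, C = 0))
  expect_equal(beta_mntd(same, d)["s1", "s2"], 0)

  for (seed in 1:20) {
    inst <- random_instance(sample(3:8, 1), sample(2:6, 1), seed = 600 + seed)
    dd <- cophenetic_distances(inst$tree)
    expect_equal(beta_mntd(inst$table, dd), oracle_beta_mntd(inst$table, dd),
                 tolerance = 1e-10)
  }
})

test_that("betaMNTD agrees with picante's comdistnt", {
  inst <- random_instance(12, 6, seed = 62)
  mine <- beta_mntd(inst$table, cophenetic_distances(inst$tree))
  ref <- as.matrix(picante::comdistnt(inst$table,
                                      cophenetic_distances(inst$tree),
                                      abundance.weighted = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betaNTI flags shuffle-invariant and identical-community degeneracy", {
  # star phylogeny: all tip pairs equidistant, every shuffle is a no-op
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  inst <- random_instance(4, 4, seed = 63)
  colnames(inst$table) <- star$tip.label
  bn <- bnti(inst$table, star, n_null = 49, seed = 1)
  expect_true(all(bn$degenerate))
  expect_true(all(bn$bnti == 0))

  # identical communities: observed and all nulls are zero
  tr <- simulate_tree(6, seed = 64)
  same <- matrix(rep(c(3L, 1L, 0L, 2L, 0L, 1L), each = 3), 3, 6,
                 dimnames = list(paste0("s", 1:3), tr$tip.label))
  bn2 <- bnti(same, tr, n_null = 49, seed = 2)
  expect_true(all(bn2$degenerate))
})

test_that("betaNTI is invariant to uniform branch-length rescaling", {
  inst <- random_instance(15, 5, seed = 65)
  bn1 <- bnti(inst$table, inst$tree, n_null = 99, seed = 7)
  scaled <- inst$tree
  scaled$edge.length <- scaled$edge.length * 37
  bn2 <- bnti(inst$table, scaled, n_null = 99, seed = 7)
  expect_equal(bn1$bnti, bn2$bnti, tolerance = 1e-9)
})

test_that("betaNTI is calibrated when phylogenetic signal is destroyed", {
  tr <- simulate_tree(50, seed = 66)
  tab <- withr::with_seed(67, {
    m <- matrix(rpois(12 * 50, 20), 12, 50,
                dimnames = list(paste0("s", 1:12), sample(tr$tip.label)))
    m
  })
  bn <- bnti(tab, tr, n_null = 199, seed = 68)
  vals <- bn$bnti[upper.tri(bn$bnti)]
  expect_lt(mean(abs(vals) > 2), 0.15)
})

test_that("Raup-Crick attains its bounds on constructed extremes", {
  # observed dissimilarity above every null: near-disjoint dominant taxa
  t1 <- rbind(s1 = c(1000L, 1L, 1L), s2 = c(1L, 1L, 1000L))
  colnames(t1) <- paste0("x", 1:3)
  rc1 <- raup_crick_bray(t1, n_null = 199, seed = 1)
  expect_equal(rc1["s1", "s2"], 1)

  # identical pair inside a wider pool: every null dissimilarity positive
  ident <- rbind(s1 = c(rep(50L, 6), rep(0L, 6)), s2 = c(rep(50L, 6), rep(0L, 6)))
  ctx <- withr::with_seed(69, matrix(rpois(48, 25) + 1L, 4, 12))
  rownames(ctx) <- paste0("c", 1:4)
  t2 <- rbind(ident, ctx)
  colnames(t2) <- paste0("x", 1:12)
  rc2 <- raup_crick_bray(t2, n_null = 199, seed = 2)
  expect_equal(rc2["s1", "s2"], -1)

  # antisymmetry of the extremes via the counting formula itself
  expect_equal(2 * ((199 + 0.5 * 0) / 199) - 1, 1)
  expect_equal(2 * ((0 + 0.5 * 0) / 199) - 1, -1)

  expect_error(raup_crick_bray(t1 / 2, n_null = 49, seed = 1), "integer")
})

test_that("Raup-Crick stays in [-1, 1] and centres on null-generated data", {
  v <- rc_self_calibration(70, n_reps = 3)
  expect_true(all(v >= -1 & v <= 1))
  expect_lt(abs(mean(v)), 0.15)
  expect_gte(mean(abs(v) <= 0.95), 0.85)
})

test_that("process classification follows the two-step thresholds", {
  b <- matrix(c(0, 2.5, 0, 0, 2.5, 0, 0, 0, 0, 0, 0, -3, 0, 0, -3, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  rc <- matrix(0, 4, 4, dimnames = dimnames(b))
  rc["s1", "s3"] <- rc["s3", "s1"] <- 0.97
  rc["s1", "s4"] <- rc["s4", "s1"] <- -0.97
  cl <- classify_processes(b, rc)
  get <- function(j, k) as.character(cl$process[cl$sample_j == j & cl$sample_k == k])
  expect_equal(get("s1", "s2"), "heterogeneous selection")
  expect_equal(get("s3", "s4"), "homogeneous selection")
  expect_equal(get("s1", "s3"), "historical contingency")
  expect_equal(get("s1", "s4"), "non-selective low turnover")
  expect_equal(get("s2", "s3"), "ecological drift")

  fr <- process_fractions(cl)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$process == "heterogeneous selection"], 1 / 6)

  # counting example: 4 heterogeneous + 6 drift
  lab <- data.frame(process = factor(
    rep(c("heterogeneous selection", "ecological drift"), c(4, 6)),
    levels = levels(cl$process)))
  fr2 <- process_fractions(lab)
  expect_equal(fr2$fraction[fr2$process == "heterogeneous selection"], 0.4)
  expect_equal(fr2$fraction[fr2$process == "ecological drift"], 0.6)
})

test_that("degenerate pairs classify through the taxonomic branch", {
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  tab <- rbind(s1 = c(5L, 5L, 0L), s2 = c(0L, 5L, 5L), s3 = c(5L, 0L, 5L))
  colnames(tab) <- star$tip.label
  bn <- bnti(tab, star, n_null = 49, seed = 3)
  rc <- matrix(0.97, 3, 3, dimnames = list(rownames(tab), rownames(tab)))
  diag(rc) <- 0
  cl <- classify_processes(bn, rc)
  expect_true(all(cl$degenerate))
  expect_true(all(cl$process == "historical contingency"))
})
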