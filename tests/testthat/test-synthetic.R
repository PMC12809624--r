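test_that("simulated trees are reproducible ultrametric binaries", {
  tr <- simulate_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(depths[1], depths[2])

  tr10 <- simulate_tree(10, seed = 2)
  expect_equal(ape::Ntip(tr10), 10)
  expect_equal(tr10$Nnode, 9)
  expect_identical(ape::write.tree(simulate_tree(10, seed = 2)),
                   ape::write.tree(tr10))
  expect_error(simulate_tree(1, seed = 1), ">= 2")
})

test_that("Brownian traits have the closed-form cherry variance and phylogenetic signal", {
  # degenerate rate: all tips at the root value
  tr <- simulate_tree(6, seed = 3)
  expect_equal(unname(evolve_traits(tr, 0, root_value = 1.5, seed = 1)),
               rep(1.5, 6))

  # cherry with branches of length t: Var(mu_A - mu_B) = 2 sigma^2 t
  cherry <- ape::read.tree(text = "(A:0.7,B:0.7);")
  sigma <- 1.3
  diffs <- vapply(1:1000, function(r) {
    tv <- evolve_traits(cherry, sigma, seed = 10000 + r)
    tv["A"] - tv["B"]
  }, 0)
  expect_equal(var(diffs), 2 * sigma^2 * 0.7, tolerance = 0.1)

  # squared trait differences grow with cophenetic distance
  tr100 <- simulate_tree(100, seed = 4)
  tv <- evolve_traits(tr100, 1, seed = 5)
  d <- cophenetic_distances(tr100)
  ut <- upper.tri(d)
  expect_gt(cor(d[ut], outer(tv, tv, "-")[ut]^2, method = "spearman"), 0)
})

test_that("environmental series follow the closed form and the seed", {
  expect_equal(make_environment(0, 7, 12, 5, 0), rep(7, 5))
  e <- make_environment(1, 0, 12, 13, 0)
  expect_equal(e[4], 1)  # t = 3 -> sin(pi/2)
  expect_identical(make_environment(2, 1, 12, 20, 0.5, seed = 9),
                   make_environment(2, 1, 12, 20, 0.5, seed = 9))
})

test_that("community simulation conserves totals and tracks the environment", {
  cfg <- scenario_config(n_taxa = 60, n_months = 41, pop_size = 500, seed = 6)
  tr <- simulate_tree(60, seed = 7)
  tv <- evolve_traits(tr, 1, seed = 8)
  env <- make_environment(3, 0, 12, 41, 0.25, seed = 9)
  sim <- simulate_communities(tr, tv, env, cfg, seed = 10)
  expect_true(all(rowSums(sim$table) == 500))

  # neutral, no immigration: richness can only erode
  cfg_n <- scenario_config(n_taxa = 60, n_months = 41, pop_size = 500,
                           immigration = 0, selection_width = Inf, seed = 6)
  simn <- simulate_communities(tr, tv, env, cfg_n, seed = 11)
  rich <- rowSums(simn$table > 0)
  expect_true(all(diff(rich) <= 0))

  # strong selection: community-weighted mean optimum follows the forcing
  f <- sim$table / rowSums(sim$table)
  cwm <- as.numeric(f %*% tv[colnames(f)])
  expect_gt(cor(cwm, env), 0.5)
})

test_that("selection strength is monotone in the niche width", {
  tr <- simulate_tree(60, seed = 12)
  tv <- evolve_traits(tr, 1, seed = 13)
  track <- function(width, seed) {
    cfg <- scenario_config(n_taxa = 60, n_months = 41, pop_size = 500,
                           selection_width = width, seed = seed)
    env <- make_environment(3, 0, 12, 41, 0.25, seed = seed + 1)
    sim <- simulate_communities(tr, tv, env, cfg, seed = seed + 2)
    f <- sim$table / rowSums(sim$table)
    cor(as.numeric(f %*% tv[colnames(f)]), env)
  }
  strong <- vapply(1:5, function(r) track(0.5, 100 + 10 * r), 0)
  weak <- vapply(1:5, function(r) track(5, 100 + 10 * r), 0)
  expect_gt(mean(strong), mean(weak))
})

test_that("the neutral regime is invariant to permuting the trait map", {
  # with selection inert, traits must not influence the law of the output:
  # identical seeds with permuted traits give identical tables
  tr <- simulate_tree(30, seed = 14)
  tv <- evolve_traits(tr, 1, seed = 15)
  cfg <- scenario_config(n_taxa = 30, n_months = 12, pop_size = 300,
                         selection_width = Inf, seed = 16)
  env <- make_environment(0, 0, 12, 12, 0)
  a <- simulate_communities(tr, tv, env, cfg, seed = 17)
  tv_perm <- setNames(sample(tv), names(tv))
  b <- simulate_communities(tr, tv_perm, env, cfg, seed = 17)
  expect_identical(a$table, b$table)
})

test_that("scenario bundles both sites deterministically", {
  cfg <- scenario_config(n_taxa = 40, n_months = 10, pop_size = 200, seed = 18)
  scen <- make_scenario(cfg)
  expect_equal(nrow(scen$meta), 20)
  expect_setequal(unique(scen$meta$site), c("temperate", "tropical"))
  expect_gt(var(scen$env$temperate), var(scen$env$tropical))
  expect_identical(scen$tables, make_scenario(cfg)$tables)
  expect_equal(unname(scen$truth["tropical"]), "neutral drift")
  expect_equal(unname(scen$truth["temperate"]), "seasonal selection")
})

test_that("planted static networks honour density, sign and seed", {
  net <- make_static_network(c("A", "B", "C", "D"), edge_density = 1,
                             positive_fraction = 1, seed = 19)
  expect_equal(nrow(net$edges), 6)
  expect_true(all(net$edges$sign == "+"))
  net2 <- make_static_network(paste0("n", 1:20), edge_density = 0.3,
                              positive_fraction = 0.5, seed = 20)
  net3 <- make_static_network(paste0("n", 1:20), edge_density = 0.3,
                              positive_fraction = 0.5, seed = 20)
  expect_identical(net2$edges, net3$edges)
})
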