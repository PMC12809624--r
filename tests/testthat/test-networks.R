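test_that("CLR transform centres each sample and matches the closed form", {
  tab <- rbind(s1 = c(4L, 4L, 4L), s2 = c(10L, 1L, 5L))
  colnames(tab) <- paste0("t", 1:3)
  y <- clr_transform(tab)
  expect_equal(unname(y["s1", ]), c(0, 0, 0))
  expect_lt(max(abs(rowSums(y))), 1e-9)
  expect_identical(attr(y, "provenance"), "clr")

  two <- matrix(c(10L, 1L), 1, dimnames = list("s", c("a", "b")))
  expect_equal(unname(clr_transform(two)[1, ]),
               c(log(11 / 2) / 2, -log(11 / 2) / 2))
})

test_that("co-occurrence filtering removes weak edges then isolated nodes", {
  net <- fixture_network("path")  # A-B, B-C
  det <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10), c("A", "B", "C")))
  det[1:6, "C"] <- 0  # B-C co-detected in 40% of samples
  out <- cooccurrence_filter(net, det, min_score = 0.5)
  expect_equal(nrow(out$edges), 1)
  expect_setequal(out$nodes$id, c("A", "B"))  # C isolated, dropped
  expect_equal(out$edges$cooccurrence_score, 1)
  expect_error(cooccurrence_filter(net, det[, 1:2]), "missing from detection")
})

test_that("monthly subnetworks follow the detection rule", {
  net <- fixture_network("triangle")
  dates <- as.Date(c("2020-01-15", "2020-02-15", "2020-03-15"))
  tab <- matrix(1L, 3, 3, dimnames = list(paste0("s", 1:3), c("A", "B", "C")))
  tab[2, "C"] <- 0L
  tab[3, c("B", "C")] <- 0L
  meta <- data.frame(sample_id = rownames(tab), date = dates)
  subs <- monthly_subnetworks(net, tab, meta)
  expect_equal(length(subs), 3)
  # all detected: identical to the static network
  expect_setequal(subs[["2020-01"]]$nodes$id, net$nodes$id)
  expect_equal(nrow(subs[["2020-01"]]$edges), nrow(net$edges))
  # C undetected: all its edges vanish
  expect_false("C" %in% subs[["2020-02"]]$nodes$id)
  expect_equal(nrow(subs[["2020-02"]]$edges), 1)
  # subset property every month
  for (s in subs) {
    expect_true(all(s$nodes$id %in% net$nodes$id))
    expect_lte(nrow(s$edges), nrow(net$edges))
  }
  # monotonicity: February's detected set contains March's
  expect_true(all(subs[["2020-03"]]$edges$from %in% subs[["2020-02"]]$edges$from))
})

test_that("topology metrics match closed forms on canonical graphs", {
  tri <- network_metrics(fixture_network("triangle"))
  expect_equal(tri$edge_density, 1)
  expect_equal(tri$transitivity, 1)
  expect_equal(tri$avg_path_length, 1)
  expect_equal(tri$mean_degree, 2)

  pth <- network_metrics(fixture_network("path"))
  expect_equal(pth$edge_density, 2 / 3)
  expect_equal(pth$transitivity, 0)
  expect_equal(pth$avg_path_length, 4 / 3)

  star <- network_metrics(fixture_network("star"))
  expect_equal(star$assortativity_degree, -1)

  tc <- network_metrics(fixture_network("two_clique"))
  expect_equal(tc$assortativity_domain, 1)
  expect_equal(tc$assortativity_fraction, 1)
  expect_equal(tc$transitivity, 1)
  expect_equal(tc$mean_positive_strength, 0.5)

  # undefined metrics carry reasons
  lone <- assoc_network(c("A", "B"), data.frame(
    from = "A", to = "B", sign = "+", weight = 1, cooccurrence_score = 1))
  m <- network_metrics(lone)
  expect_true(is.na(m$assortativity_domain))
  expect_true("assortativity_domain" %in% names(attr(m, "reasons")))
})

test_that("metric-environment correlations apply Holm across the family", {
  months <- sprintf("2020-%02d", 1:8)
  metrics <- data.frame(month = months, up = 1:8, down = 8:1)
  env <- data.frame(month = months, temp = (1:8) * 2 + 1)
  out <- metric_env_correlations(metrics, env)
  expect_equal(out$rho[out$metric == "up"], 1)
  expect_equal(out$rho[out$metric == "down"], -1)
  expect_true(all(out$p_holm >= out$p, na.rm = TRUE))

  # Holm equals the independent step-down oracle on random p-vectors
  for (r in 1:20) {
    p <- withr::with_seed(9200 + r, runif(sample(3:20, 1)))
    expect_equal(stats::p.adjust(p, "holm"), oracle_holm(p), tolerance = 1e-12)
  }
  # worked example
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "holm"), c(0.03, 0.04, 0.04))

  # too few complete pairs -> NA with reason
  metrics$up[1:6] <- NA
  out2 <- metric_env_correlations(metrics, env)
  expect_true(is.na(out2$rho[out2$metric == "up"]))
  expect_match(out2$note[out2$metric == "up"], "min_pairs")
})

test_that("the baseline CLR-correlation network recovers planted structure", {
  tab <- withr::with_seed(93, {
    base <- matrix(rpois(60 * 20, 30), 60, 20,
                   dimnames = list(paste0("s", 1:60), paste0("t", 1:20)))
    shared <- rpois(60, 150)
    base[, 1] <- base[, 1] + shared; base[, 2] <- base[, 2] + shared
    base
  })
  net <- infer_cooccurrence(clr_transform(tab), cutoff = 0.6)
  key <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to))
  expect_true("t1 t2" %in% key)
})
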