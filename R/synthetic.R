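# Two-observatory synthetic community generator. A Yule phylogeny carries a
# Brownian-motion environmental optimum per tip; each month the community is
# resampled multinomially with weights combining last month's frequencies,
# immigration from a fixed regional pool, and a Gaussian environmental
# filter. A "temperate" site gets strong sinusoidal forcing with finite
# selection width; a "tropical" site is run neutrally (selection inert).

#' Scenario configuration for the synthetic two-observatory generator
#'
#' Defaults are the study conditions used throughout the test-suite
#' recovery analyses: 150 taxa followed monthly for 41 months at two sites,
#' 2000 individuals per sample, immigration 0.05 from a uniform regional
#' pool, Gaussian selection of width 0.5 trait units at the seasonally
#' forced site (amplitude 3, period 12 months) and neutral dynamics at the
#' aseasonal site, traits evolved by Brownian motion with rate 1.
#'
#' @param n_taxa number of ASVs (tree tips).
#' @param n_months samples per site (monthly cadence).
#' @param pop_size individuals per sample (multinomial total).
#' @param immigration fraction of each month's sampling weight drawn from
#'   the regional pool, in `[0, 1]`.
#' @param selection_width Gaussian niche width in trait units; smaller is
#'   stronger selection; `Inf` disables selection.
#' @param env_amplitude named numeric, sinusoid amplitude per site (trait
#'   units).
#' @param env_mean named numeric, environmental mean per site.
#' @param env_period forcing period in months.
#' @param env_noise_sd Gaussian noise on the environmental series.
#' @param trait_diffusion Brownian-motion rate (trait units per unit branch
#'   length).
#' @param pool regional pool: `"uniform"` or `"logseries"`.
#' @param n_fractions 1 or 2 size-fractions per site (fraction tables are
#'   independent draws from the same latent monthly weights).
#' @param tropical_neutral run the low-amplitude site with selection
#'   disabled so its truth label is ecological drift.
#' @param emulate_depth_variation draw sample totals uniformly from
#'   `[0.8, 1.2] * pop_size` so rarefaction has work to do.
#' @param seed integer; mandatory, seeds every stochastic step.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_taxa = 150, n_months = 41, pop_size = 2000,
                            immigration = 0.05, selection_width = 0.5,
                            env_amplitude = c(temperate = 3, tropical = 0),
                            env_mean = c(temperate = 0, tropical = 0),
                            env_period = 12, env_noise_sd = 0.25,
                            trait_diffusion = 1, pool = c("uniform", "logseries"),
                            n_fractions = 1, tropical_neutral = TRUE,
                            emulate_depth_variation = FALSE, seed) {
  pool <- match.arg(pool)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_taxa >= 2, n_months >= 1, pop_size >= 1,
            immigration >= 0, immigration <= 1, selection_width > 0,
            env_period > 0, trait_diffusion >= 0, n_fractions %in% 1:2)
  structure(list(
    n_taxa = n_taxa, n_months = n_months, pop_size = pop_size,
    immigration = immigration, selection_width = selection_width,
    env_amplitude = env_amplitude, env_mean = env_mean,
    env_period = env_period, env_noise_sd = env_noise_sd,
    trait_diffusion = trait_diffusion, pool = pool,
    n_fractions = n_fractions, tropical_neutral = tropical_neutral,
    emulate_depth_variation = emulate_depth_variation,
    seed = as.integer(seed)), class = "scenario_config")
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_tips number of tips (>= 2); labels `t1..tn`.
#' @param seed integer seed.
#' @return an ultrametric [ape::phylo] Yule tree.
#' @export
simulate_tree <- function(n_tips, seed) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$tip.label <- paste0("t", seq_len(n_tips))
    tree
  })
}

#' Evolve a trait by Brownian motion along a phylogeny
#'
#' Tip value = `root_value` plus independent Gaussian increments along each
#' branch with variance `sigma^2 * branch length`, so the trait is
#' phylogenetically conserved: close relatives share similar environmental
#' optima, which is the structure the phylogenetic turnover null models
#' presuppose.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param sigma Brownian rate (trait units per sqrt branch length), >= 0.
#' @param root_value ancestral trait value.
#' @param seed integer seed.
#' @return named numeric vector of tip optima.
#' @export
evolve_traits <- function(tree, sigma, root_value = 0, seed) {
  stopifnot(sigma >= 0)
  tree <- validate_tree(tree)
  if (sigma == 0) {
    out <- rep(root_value, ape::Ntip(tree))
    names(out) <- tree$tip.label
    return(out)
  }
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                  root.value = root_value))
}

#' Sinusoidal environmental series with Gaussian noise
#'
#' `E(t) = mean + amplitude * sin(2 pi t / period) + N(0, noise_sd)` at
#' `t = 0 .. n_months - 1`.
#'
#' @param amplitude sinusoid amplitude (trait units).
#' @param mean series mean.
#' @param period months per cycle (> 0).
#' @param n_months series length.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return numeric vector of length `n_months`.
#' @export
make_environment <- function(amplitude, mean, period = 12, n_months, noise_sd = 0,
                             seed = NULL) {
  stopifnot(period > 0, n_months >= 1)
  t <- seq_len(n_months) - 1
  base <- mean + amplitude * sin(2 * pi * t / period)
  if (noise_sd > 0) base <- base + with_seed(seed, stats::rnorm(n_months, 0, noise_sd))
  base
}

# Regional pool frequencies.
pool_frequencies <- function(n_taxa, pool) {
  if (pool == "uniform") return(rep(1 / n_taxa, n_taxa))
  # log-series-like: geometric ranks, normalised
  p <- 0.98 ^ seq_len(n_taxa)
  p / sum(p)
}

#' Simulate a community time series under drift, immigration and selection
#'
#' Month 0 is a uniform multinomial draw. For `t >= 1` the sampling weight
#' of taxon `i` is
#' `(x_i(t-1)/N * (1 - m) + m * pi_i) * exp(-(E(t) - mu_i)^2 / (2 sigma_sel^2))`
#' and counts are drawn as `Multinomial(N, w / sum(w))`. With
#' `selection_width = Inf` the exponential filter is identically 1 and the
#' model reduces to neutral drift with immigration.
#'
#' @param tree phylogeny whose tips index the taxa.
#' @param traits named tip optima (see [evolve_traits()]).
#' @param env environmental series, one value per month.
#' @param config a [scenario_config()]; its `seed` is used unless `seed` is
#'   given.
#' @param site label written into the metadata.
#' @param size_fraction label written into the metadata.
#' @param start_date first sampling date (monthly cadence thereafter).
#' @param seed optional integer seed overriding `config$seed`.
#' @return list with `table` (months x taxa counts) and `meta`
#'   (sample_id, date, site, size_fraction, domain_marker, temperature).
#' @export
simulate_communities <- function(tree, traits, env, config, site = "site",
                                 size_fraction = "small",
                                 start_date = as.Date("2013-04-15"),
                                 seed = NULL) {
  taxa <- tree$tip.label
  stopifnot(setequal(names(traits), taxa))
  traits <- traits[taxa]
  n_months <- length(env)
  n_taxa <- length(taxa)
  N <- config$pop_size
  m <- config$immigration
  pi_i <- pool_frequencies(n_taxa, config$pool)
  filt <- function(E) {
    if (!is.finite(config$selection_width)) return(rep(1, n_taxa))
    exp(-(E - traits)^2 / (2 * config$selection_width^2))
  }
  with_seed(seed %||% config$seed, {
    counts <- matrix(0L, n_months, n_taxa, dimnames = list(NULL, taxa))
    totals <- if (isTRUE(config$emulate_depth_variation)) {
      round(stats::runif(n_months, 0.8 * N, 1.2 * N))
    } else rep(N, n_months)
    x <- as.integer(stats::rmultinom(1, totals[1], rep(1 / n_taxa, n_taxa)))
    counts[1, ] <- x
    if (n_months > 1) for (t in 2:n_months) {
      w <- (x / sum(x) * (1 - m) + m * pi_i) * filt(env[t])
      if (all(w == 0)) {
        stop("all sampling weights are zero; selection_width is too small ",
             "for the spread between traits and environment")
      }
      x <- as.integer(stats::rmultinom(1, totals[t], w / sum(w)))
      counts[t, ] <- x
    }
    dates <- seq(start_date, by = "month", length.out = n_months)
    ids <- sprintf("%s_%s_%s", site, size_fraction, format(dates, "%Y%m"))
    rownames(counts) <- ids
    meta <- data.frame(sample_id = ids, date = dates, site = site,
                       size_fraction = size_fraction, domain_marker = "16S",
                       temperature = env, stringsAsFactors = FALSE)
    list(table = counts, meta = meta)
  })
}

#' Generate the full two-observatory scenario
#'
#' One shared Yule tree and trait map; a "temperate" site driven by a
#' high-amplitude seasonal environment under Gaussian selection, and a
#' "tropical" site with near-constant environment run neutrally (see
#' `tropical_neutral`). With `n_fractions = 2`, each site's two
#' size-fraction tables are independent multinomial draws from the same
#' latent monthly weights.
#'
#' @param config a [scenario_config()].
#' @return list with `tables` (named site[_fraction] count matrices),
#'   `meta` (combined sample table, includes `daylength`), `tree`,
#'   `traits`, `env` (per-site series) and `truth` (generating regime per
#'   site).
#' @export
make_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  tree <- simulate_tree(config$n_taxa, seed = sub_seed(seed, 1))
  traits <- evolve_traits(tree, config$trait_diffusion, root_value = 0,
                          seed = sub_seed(seed, 2))
  sites <- names(config$env_amplitude)
  fractions <- c("small", "large")[seq_len(config$n_fractions)]
  tables <- list(); metas <- list(); envs <- list()
  for (si in seq_along(sites)) {
    s <- sites[si]
    envs[[s]] <- make_environment(config$env_amplitude[[s]], config$env_mean[[s]],
                                  config$env_period, config$n_months,
                                  config$env_noise_sd, seed = sub_seed(seed, 10 + si))
    cfg_s <- config
    neutral <- isTRUE(config$tropical_neutral) && s == "tropical"
    if (neutral) cfg_s$selection_width <- Inf
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      # same latent regime; fraction draws differ only through the RNG stream
      sim <- simulate_communities(tree, traits, envs[[s]], cfg_s, site = s,
                                  size_fraction = f,
                                  seed = sub_seed(seed, 100 * si + fi))
      key <- if (length(fractions) > 1) paste(s, f, sep = "_") else s
      # daylength: deterministic seasonal covariate, damped at the tropical site
      dl_amp <- if (s == "tropical") 0.3 else 2.4
      sim$meta$daylength <- 12 + dl_amp *
        sin(2 * pi * (seq_len(config$n_months) - 1) / config$env_period)
      tables[[key]] <- sim$table
      metas[[key]] <- sim$meta
    }
  }
  neutral_site <- (sites == "tropical" & isTRUE(config$tropical_neutral)) |
    !is.finite(config$selection_width)
  truth <- stats::setNames(ifelse(neutral_site, "neutral drift", "seasonal selection"),
                           sites)
  list(tables = tables, meta = do.call(rbind, c(metas, list(make.row.names = FALSE))),
       tree = tree, traits = traits, env = envs, truth = truth, config = config)
}

#' Random signed Erdos-Renyi association network
#'
#' Structural fixture for the temporal-subnetwork machinery; it does not
#' model interaction dynamics.
#'
#' @param nodes character vector of ids or node data.frame (see
#'   [assoc_network()]).
#' @param edge_density probability of each possible edge, in `(0, 1]`.
#' @param positive_fraction probability that an edge is positive.
#' @param seed integer seed.
#' @return an `assoc_network` with weights in `[0.1, 1]` (sign applied) and
#'   cooccurrence scores in `[0.5, 1]`.
#' @export
make_static_network <- function(nodes, edge_density, positive_fraction = 0.9, seed) {
  stopifnot(edge_density > 0, edge_density <= 1,
            positive_fraction >= 0, positive_fraction <= 1)
  if (is.character(nodes)) nodes <- data.frame(id = nodes)
  ids <- nodes$id
  pairs <- utils::combn(ids, 2)
  with_seed(seed, {
    keep <- stats::runif(ncol(pairs)) <= edge_density
    from <- pairs[1, keep]; to <- pairs[2, keep]
    sgn <- ifelse(stats::runif(sum(keep)) <= positive_fraction, "+", "-")
    w <- stats::runif(sum(keep), 0.1, 1) * ifelse(sgn == "+", 1, -1)
    sc <- stats::runif(sum(keep), 0.5, 1)
    assoc_network(nodes, data.frame(from = from, to = to, sign = sgn,
                                    weight = w, cooccurrence_score = sc))
  })
}

#' Plant seasonal and aperiodic ASVs in a synthetic count table
#'
#' Seasonal ASVs follow a 12-month sinusoidal expected abundance
#' (`mu * (1 + amp * sin)`, random phase); aperiodic ASVs share the
#' lognormal month-to-month noise but have a flat expectation. Counts are
#' Poisson around the noisy expectation. With the defaults the sinusoid's
#' standard deviation is about twice the multiplicative noise's, i.e. a
#' signal-to-noise ratio of about 2.
#'
#' @param n_seasonal,n_noise numbers of planted seasonal and aperiodic ASVs.
#' @param n_months series length.
#' @param period planted period, months.
#' @param amp relative sinusoid amplitude.
#' @param noise_sd lognormal sd of the multiplicative noise.
#' @param base_mu mean expected count per ASV and month.
#' @param seed integer seed.
#' @return list with `table` (months x ASVs integer counts, seasonal ASVs
#'   named `seas*`, others `noise*`), `meta` (sample_id, date), and
#'   `truth` (logical seasonal flag per ASV).
#' @export
simulate_seasonal_asvs <- function(n_seasonal = 30, n_noise = 70, n_months = 41,
                                   period = 12, amp = 0.75, noise_sd = 0.25,
                                   base_mu = 200, seed) {
  with_seed(seed, {
    t <- seq_len(n_months) - 1
    ids <- c(sprintf("seas%03d", seq_len(n_seasonal)),
             sprintf("noise%03d", seq_len(n_noise)))
    counts <- matrix(0L, n_months, n_seasonal + n_noise,
                     dimnames = list(NULL, ids))
    phases <- stats::runif(n_seasonal, 0, period)
    for (i in seq_len(n_seasonal + n_noise)) {
      mu <- base_mu * stats::runif(1, 0.5, 2)
      expect <- if (i <= n_seasonal) {
        mu * (1 + amp * sin(2 * pi * (t - phases[i]) / period))
      } else rep(mu, n_months)
      lambda <- expect * exp(stats::rnorm(n_months, 0, noise_sd))
      counts[, i] <- stats::rpois(n_months, lambda)
    }
    dates <- seq(as.Date("2013-04-15"), by = "month", length.out = n_months)
    rownames(counts) <- format(dates, "s%Y%m")
    list(table = counts,
         meta = data.frame(sample_id = rownames(counts), date = dates),
         truth = stats::setNames(grepl("^seas", ids), ids))
  })
}
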