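# Null-model quantification of community assembly processes: phylogenetic
# turnover (betaMNTD -> betaNTI) decides selection; taxonomic turnover
# (Raup-Crick on Bray-Curtis) splits the remainder into historical
# contingency, non-selective low turnover and ecological drift.

PROCESS_LEVELS <- c("heterogeneous selection", "homogeneous selection",
                    "historical contingency", "non-selective low turnover",
                    "ecological drift")

#' Patristic (cophenetic) distances between tree tips
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @return symmetric matrix of path-length distances between all tip pairs.
#' @export
cophenetic_distances <- function(tree) {
  tree <- validate_tree(tree)
  ape::cophenetic.phylo(tree)
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For communities j and k,
#' `betaMNTD(j,k) = 1/2 [ sum_i f_ij min_i' d(i,i') + sum_i' f_i'k min_i d(i,i') ]`
#' where the minima run over the taxa present in the other community (a
#' taxon present in both has nearest-taxon distance zero) and `f` are
#' within-sample relative abundances.
#'
#' @param table samples x taxa abundances; every taxon must appear in
#'   `dists`.
#' @param dists taxa x taxa phylogenetic distance matrix (see
#'   [cophenetic_distances()]).
#' @param abundance_weighted weight by relative abundance (default) or
#'   equally across present taxa.
#' @return symmetric samples x samples betaMNTD matrix.
#' @export
beta_mntd <- function(table, dists, abundance_weighted = TRUE) {
  miss <- setdiff(colnames(table), rownames(dists))
  if (length(miss)) stop("taxa missing from distance matrix: ",
                         paste(miss, collapse = ", "))
  if (any(rowSums(table) <= 0)) {
    stop("empty sample(s): ", paste(rownames(table)[rowSums(table) <= 0], collapse = ", "))
  }
  d <- dists[colnames(table), colnames(table), drop = FALSE]
  f <- if (abundance_weighted) rel_abund(table) else rel_abund(1 * (table > 0))
  .beta_mntd_engine(f, d)
}

# f: samples x taxa relative weights; d: taxa x taxa distances.
# M[i, k] = min over taxa present in sample k of d(i, .); then
# betaMNTD = (F M + (F M)') / 2.
.beta_mntd_engine <- function(f, d) {
  pres <- f > 0
  n_s <- nrow(f)
  m <- matrix(0, ncol(f), n_s, dimnames = list(colnames(f), rownames(f)))
  for (k in seq_len(n_s)) {
    m[, k] <- row_mins(d[, pres[k, ], drop = FALSE])
  }
  b <- f %*% m
  out <- (b + t(b)) / 2
  dimnames(out) <- list(rownames(f), rownames(f))
  out
}

#' Beta nearest taxon index from phylogeny randomisations
#'
#' Null betaMNTD distributions are generated by shuffling taxon labels
#' across the whole distance matrix (one permutation per randomisation,
#' shared by every sample pair: the regional-pool null of the Stegen
#' framework). `betaNTI = (betaMNTD_obs - mean_null) / sd_null`. Pairs with
#' null standard deviation 0 (e.g. star phylogenies or identical
#' communities) are recorded as 0 with a degeneracy flag so classification
#' falls through to the taxonomic branch.
#'
#' @param table samples x taxa counts (rarefied recommended).
#' @param tree rooted phylogeny covering the table's taxa, or a
#'   precomputed distance matrix.
#' @param n_null number of randomisations (>= 2; 999 reproduces the
#'   standard protocol).
#' @param seed integer seed.
#' @param abundance_weighted passed to [beta_mntd()].
#' @param null_model `"regional"` (one shared permutation per
#'   randomisation) or `"per_pair"` (an independent permutation per sample
#'   pair, for sensitivity analysis; much slower).
#' @return list of class `bnti_result`: `bnti`, `bmntd_obs`, `null_mean`,
#'   `null_sd`, `degenerate` (logical), all samples x samples matrices.
#' @export
bnti <- function(table, tree, n_null = 999, seed = NULL,
                 abundance_weighted = TRUE,
                 null_model = c("regional", "per_pair")) {
  null_model <- match.arg(null_model)
  if (n_null < 2) stop("n_null must be >= 2")
  d <- if (inherits(tree, "phylo")) cophenetic_distances(tree) else as.matrix(tree)
  miss <- setdiff(colnames(table), rownames(d))
  if (length(miss)) stop("taxa missing from tree: ", paste(miss, collapse = ", "))
  d <- d[colnames(table), colnames(table), drop = FALSE]
  f <- if (abundance_weighted) rel_abund(table) else rel_abund(1 * (table > 0))
  obs <- .beta_mntd_engine(f, d)
  n_t <- ncol(f)
  with_seed(seed, {
    if (null_model == "regional") {
      s1 <- matrix(0, nrow(obs), ncol(obs)); s2 <- s1
      for (r in seq_len(n_null)) {
        p <- sample.int(n_t)
        dp <- d[p, p, drop = FALSE]
        dimnames(dp) <- dimnames(d)
        nb <- .beta_mntd_engine(f, dp)
        s1 <- s1 + nb; s2 <- s2 + nb^2
      }
      null_mean <- s1 / n_null
      null_sd <- sqrt(pmax(s2 / n_null - null_mean^2, 0) * n_null / (n_null - 1))
    } else {
      n_s <- nrow(f)
      null_mean <- matrix(0, n_s, n_s, dimnames = dimnames(obs))
      null_sd <- null_mean
      for (j in seq_len(n_s - 1)) for (k in (j + 1):n_s) {
        vals <- vapply(seq_len(n_null), function(r) {
          p <- sample.int(n_t)
          dp <- d[p, p, drop = FALSE]; dimnames(dp) <- dimnames(d)
          .beta_mntd_engine(f[c(j, k), , drop = FALSE], dp)[1, 2]
        }, 0)
        null_mean[j, k] <- null_mean[k, j] <- mean(vals)
        null_sd[j, k] <- null_sd[k, j] <- stats::sd(vals)
      }
    }
    # relative threshold: running-sum variance carries ~1e-8 cancellation
    # noise on shuffle-invariant inputs
    degenerate <- null_sd <= 1e-7 * pmax(null_mean, 1e-12)
    bn <- (obs - null_mean) / null_sd
    bn[degenerate] <- 0
    diag(bn) <- 0; diag(degenerate) <- TRUE
    structure(list(bnti = bn, bmntd_obs = obs, null_mean = null_mean,
                   null_sd = null_sd, degenerate = degenerate,
                   n_null = n_null), class = "bnti_result")
  })
}

#' One null community preserving richness and total count
#'
#' Building block of the Raup-Crick null: draw the observed number of taxa
#' without replacement with probability proportional to dataset occurrence
#' frequency, then distribute the remaining individuals multinomially with
#' probability proportional to dataset mean relative abundance restricted
#' to the drawn taxa.
#'
#' @param richness number of taxa to draw.
#' @param total total individuals (>= richness).
#' @param occ_freq per-taxon occurrence frequencies across the dataset.
#' @param mean_abund per-taxon mean relative abundances across the dataset.
#' @return integer vector of counts over all taxa.
#' @export
raup_crick_null <- function(richness, total, occ_freq, mean_abund) {
  n_t <- length(occ_freq)
  stopifnot(richness >= 1, total >= richness, length(mean_abund) == n_t)
  picks <- sample.int(n_t, richness, prob = occ_freq)
  x <- integer(n_t)
  x[picks] <- 1L
  if (total > richness) {
    extra <- stats::rmultinom(1, total - richness, mean_abund[picks])
    x[picks] <- x[picks] + as.integer(extra)
  }
  x
}

#' Raup-Crick metric on Bray-Curtis dissimilarities
#'
#' Each randomisation reassembles every sample under the null of
#' [raup_crick_null()] (one null community per sample per randomisation)
#' and records the null Bray-Curtis matrix; per pair,
#' `RCbray = 2 * ((#\{BC_null < BC_obs\} + 1/2 #\{BC_null = BC_obs\}) / n_null) - 1`,
#' bounded in `[-1, 1]` with 0 meaning no deviation from stochastic
#' assembly.
#'
#' @param table samples x taxa integer counts (rarefied recommended).
#' @param n_null number of randomisations (999 reproduces the standard
#'   protocol).
#' @param seed integer seed.
#' @return symmetric samples x samples RCbray matrix.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = NULL) {
  validate_count_table(table, "raw")
  if (n_null < 2) stop("n_null must be >= 2")
  f <- rel_abund(table)
  occ <- colMeans(table > 0)
  mab <- colMeans(f)
  rich <- rowSums(table > 0)
  tot <- rowSums(table)
  n_s <- nrow(table)
  bc_obs <- as.matrix(bray_curtis(table))
  lt <- matrix(0, n_s, n_s); eq <- lt
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      nt <- t(vapply(seq_len(n_s), function(j) {
        raup_crick_null(rich[j], tot[j], occ, mab)
      }, integer(ncol(table))))
      bc_null <- as.matrix(vegan::vegdist(sweep(nt, 1, rowSums(nt), "/"),
                                          method = "bray"))
      diffm <- bc_null - bc_obs
      lt <- lt + (diffm < -1e-12)
      eq <- eq + (abs(diffm) <= 1e-12)
    }
  })
  rc <- 2 * ((lt + 0.5 * eq) / n_null) - 1
  diag(rc) <- 0
  dimnames(rc) <- dimnames(bc_obs)
  rc
}

#' Classify sample pairs into the five temporal assembly processes
#'
#' Thresholds: betaNTI > 2 heterogeneous selection; betaNTI < -2
#' homogeneous selection; otherwise RCbray > 0.95 historical contingency,
#' RCbray < -0.95 non-selective low turnover, and |RCbray| <= 0.95
#' ecological drift. Degenerate-null pairs carry betaNTI = 0 and are
#' classified through the taxonomic branch, flagged in the output.
#'
#' @param bnti a `bnti_result` or a betaNTI matrix.
#' @param rcbray RCbray matrix on the same samples.
#' @param bnti_threshold,rc_threshold classification thresholds (2 and
#'   0.95).
#' @return data.frame, one row per unordered pair: sample_j, sample_k,
#'   bnti, rcbray, process (factor over the five processes), degenerate.
#' @export
classify_processes <- function(bnti, rcbray, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  degen <- NULL
  if (inherits(bnti, "bnti_result")) {
    degen <- bnti$degenerate
    bnti <- bnti$bnti
  }
  bnti <- as.matrix(bnti); rcbray <- as.matrix(rcbray)
  if (!identical(dimnames(bnti), dimnames(rcbray))) {
    if (!setequal(rownames(bnti), rownames(rcbray))) {
      stop("betaNTI and RCbray cover different sample pairs")
    }
    rcbray <- rcbray[rownames(bnti), colnames(bnti)]
  }
  pr <- utils::combn(nrow(bnti), 2)
  b <- bnti[cbind(pr[1, ], pr[2, ])]
  rc <- rcbray[cbind(pr[1, ], pr[2, ])]
  lab <- ifelse(b > bnti_threshold, PROCESS_LEVELS[1],
         ifelse(b < -bnti_threshold, PROCESS_LEVELS[2],
         ifelse(rc > rc_threshold, PROCESS_LEVELS[3],
         ifelse(rc < -rc_threshold, PROCESS_LEVELS[4], PROCESS_LEVELS[5]))))
  data.frame(sample_j = rownames(bnti)[pr[1, ]],
             sample_k = rownames(bnti)[pr[2, ]],
             bnti = b, rcbray = rc,
             process = factor(lab, levels = PROCESS_LEVELS),
             degenerate = if (is.null(degen)) FALSE else degen[cbind(pr[1, ], pr[2, ])],
             stringsAsFactors = FALSE)
}

#' Relative importance of assembly processes per dataset
#'
#' @param labels output of [classify_processes()], optionally with extra
#'   grouping columns.
#' @param grouping optional factor/character vector (one per pair) or name
#'   of a column in `labels`; `NULL` treats all pairs as one group.
#' @return data.frame: group, process, fraction, n_pairs; fractions sum to
#'   1 within each group.
#' @export
process_fractions <- function(labels, grouping = NULL) {
  if (is.character(grouping) && length(grouping) == 1 && grouping %in% names(labels)) {
    grouping <- labels[[grouping]]
  }
  if (is.null(grouping)) grouping <- rep("all", nrow(labels))
  if (length(grouping) != nrow(labels)) stop("grouping length != number of pairs")
  out <- list()
  for (gl in unique(grouping)) {
    sub <- labels$process[grouping == gl]
    if (!length(sub)) stop("empty group: ", gl)
    tab <- table(factor(sub, levels = PROCESS_LEVELS))
    out[[gl]] <- data.frame(group = gl, process = names(tab),
                            fraction = as.numeric(tab) / length(sub),
                            n_pairs = length(sub), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Full assembly-process quantification for one dataset
#'
#' Convenience wrapper: betaNTI and RCbray at matched settings, pairwise
#' classification and process fractions.
#'
#' @inheritParams bnti
#' @param table samples x taxa integer counts.
#' @return list: `pairs` (classification data.frame), `fractions`, `bnti`
#'   (the `bnti_result`), `rcbray`.
#' @export
assembly_processes <- function(table, tree, n_null = 999, seed = NULL) {
  bn <- bnti(table, tree, n_null = n_null, seed = seed)
  rc <- raup_crick_bray(table, n_null = n_null,
                        seed = if (is.null(seed)) NULL else sub_seed(seed, 2))
  pairs <- classify_processes(bn, rc)
  list(pairs = pairs, fractions = process_fractions(pairs), bnti = bn, rcbray = rc)
}
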