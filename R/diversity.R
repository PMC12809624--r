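# Alpha/beta diversity, rarefaction, PERMANOVA variance partitioning and
# time-decay extraction.

#' Rarefy a count table to even depth
#'
#' One subsample without replacement per sample (vegan's `rrarefy`), the
#' convention for community standardisation before the ecological null
#' models.
#'
#' @param table samples x ASVs integer counts.
#' @param depth target reads per sample; defaults to the minimum sample
#'   total.
#' @param seed integer seed.
#' @param drop_shallow drop (with a warning) samples whose total is below
#'   `depth` instead of erroring.
#' @return rarefied count matrix, provenance `"rarefied"`.
#' @export
rarefy <- function(table, depth = min(rowSums(table)), seed, drop_shallow = FALSE) {
  validate_count_table(table, attr(table, "provenance") %||% "raw")
  tot <- rowSums(table)
  if (any(tot < depth)) {
    if (!drop_shallow) {
      stop("sample(s) shallower than depth ", depth, ": ",
           paste(rownames(table)[tot < depth], collapse = ", "),
           " (set drop_shallow = TRUE to remove them)")
    }
    warning("dropping ", sum(tot < depth), " sample(s) shallower than ", depth)
    table <- table[tot >= depth, , drop = FALSE]
  }
  # vegan heuristically warns when the smallest count exceeds 1; harmless here
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(table, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    }))
  out <- matrix(as.integer(out), nrow(out), ncol(out), dimnames = dimnames(out))
  attr(out, "provenance") <- "rarefied"
  out
}

#' Per-sample alpha diversity
#'
#' Richness, Shannon entropy (natural log), Pielou evenness
#' `J = H / ln(richness)` (missing when richness < 2), and, when a rooted
#' tree is supplied, Faith phylogenetic diversity including the path to the
#' root.
#'
#' @param table samples x ASVs counts or relative abundances.
#' @param tree optional rooted [ape::phylo]; tips must cover the table's
#'   ASVs (extra tips are ignored).
#' @return data.frame: sample_id, richness, shannon, pielou, faith_pd.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  if (any(rowSums(table) <= 0)) {
    stop("empty sample(s): ", paste(rownames(table)[rowSums(table) <= 0], collapse = ", "))
  }
  rich <- rowSums(table > 0)
  shan <- vegan::diversity(table, index = "shannon")
  piel <- ifelse(rich > 1, shan / log(rich), NA_real_)
  out <- data.frame(sample_id = rownames(table), richness = as.integer(rich),
                    shannon = as.numeric(shan), pielou = as.numeric(piel),
                    faith_pd = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    al <- align_inputs(table, tree)
    pd <- picante::pd(al$table[, al$tree$tip.label, drop = FALSE], al$tree,
                      include.root = TRUE)
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  out
}

#' Ranked relative abundances per sample
#'
#' Descending relative abundances with ties broken by ASV column order;
#' `rank_norm = rank / richness` rescales ranks into `(0, 1]` so samples of
#' different richness overlay.
#'
#' @param table samples x ASVs counts.
#' @return data.frame: sample_id, asv_id, rank, rank_norm, rel_abund.
#' @export
rank_abundance <- function(table) {
  f <- rel_abund(table)
  out <- lapply(rownames(f), function(s) {
    x <- f[s, ]
    x <- x[x > 0]
    ord <- order(-x, match(names(x), colnames(table)))
    data.frame(sample_id = s, asv_id = names(x)[ord], rank = seq_along(ord),
               rank_norm = seq_along(ord) / length(ord),
               rel_abund = as.numeric(x[ord]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on within-sample relative abundances:
#' `BC(j,k) = sum |f_ij - f_ik| / sum (f_ij + f_ik)`.
#'
#' @param table samples x ASVs counts (or abundances); rows are normalised
#'   internally.
#' @return a [stats::dist] with attribute `metric = "bray"`.
#' @export
bray_curtis <- function(table) {
  d <- vegan::vegdist(rel_abund(table), method = "bray")
  attr(d, "metric") <- "bray"
  d
}

# ---- PERMANOVA --------------------------------------------------------------

# Trace-based distance partition (McArdle & Anderson). Implemented directly
# rather than delegated so that permutation F ties on degenerate inputs
# (zero residual sum of squares) compare exactly: residual SS below
# 1e-10 * total SS maps F to +Inf for observed and permuted statistics
# alike. Cross-checked against vegan::adonis2 in the test-suite.
gower_center <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  r <- rowMeans(a); g <- mean(a)
  a - outer(r, rep(1, n)) - outer(rep(1, n), r) + g
}

term_hats <- function(meta, terms) {
  hats <- list(); prev_rank <- 1L
  x_cum <- matrix(1, nrow(meta), 1)
  for (tm in terms) {
    v <- meta[[tm]]
    if (is.character(v) || is.factor(v)) {
      v <- droplevels(factor(v))
      if (nlevels(v) < 2) stop("term '", tm, "' has a single level")
    }
    x_cum <- cbind(x_cum, stats::model.matrix(~v)[, -1, drop = FALSE])
    q <- qr(x_cum)
    h <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    hats[[tm]] <- list(hat = h, df = q$rank - prev_rank)
    prev_rank <- q$rank
  }
  hats
}

#' Distance-based PERMANOVA with sequential variance partitioning
#'
#' Partitions the distance-based sum of squares sequentially over the given
#' term order (Type-I-like, the `adonis2` convention) and tests each term's
#' pseudo-F by free permutation of sample labels:
#' `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`, or the exact fraction
#' over all `n!` orderings when `exhaustive = TRUE`. Single-variable runs
#' are order-free.
#'
#' @param dist a [stats::dist] or symmetric matrix with labels.
#' @param meta sample metadata containing `terms`; matched to the distance
#'   labels via `sample_id` (or rownames).
#' @param terms character vector of metadata columns, in partition order.
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all `n!` label orderings (n <= 9).
#' @return data.frame: term, df, sum_sq, r2, f, p (plus Residual and Total
#'   rows); attributes `n_perm` and `term_order`.
#' @export
permanova <- function(dist, meta, terms, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  dm <- as.matrix(dist)
  ids <- rownames(dm) %||% labels(dist)
  key <- if ("sample_id" %in% names(meta)) meta$sample_id else rownames(meta)
  idx <- match(ids, key)
  if (anyNA(idx)) stop("distance ids missing from metadata: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  meta <- meta[idx, , drop = FALSE]
  n <- nrow(dm)
  if (n < length(terms) + 2) stop("fewer samples than terms + 2")
  g <- gower_center(dm)
  ss_tot <- sum(diag(g))
  hats <- term_hats(meta, terms)
  h_full <- hats[[length(hats)]]$hat
  df_terms <- vapply(hats, `[[`, 0, "df")
  df_res <- n - 1L - sum(df_terms)
  if (df_res < 1) stop("no residual degrees of freedom")

  stat_f <- function(gm) {
    # per-term SS from increments of cumulative hat traces
    cum <- vapply(hats, function(h) sum(h$hat * gm), 0) # tr(H G)
    ss <- diff(c(0, cum))
    ss_res <- ss_tot - cum[length(cum)]
    f <- (ss / df_terms) / (ss_res / df_res)
    f[ss_res < 1e-10 * max(ss_tot, 1e-300)] <- Inf
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_f(g)

  perms <- if (exhaustive) {
    all_permutations(n)
  } else {
    with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }
  count <- numeric(length(terms))
  thr <- obs$f - 1e-8 * abs(obs$f) - 1e-12
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    fp <- stat_f(g[p, p])$f
    count <- count + ifelse(is.infinite(obs$f), is.infinite(fp) & fp > 0,
                            fp >= thr)
  }
  pval <- if (exhaustive) count / nrow(perms) else (count + 1) / (nrow(perms) + 1)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$ss_res, ss_tot),
    r2 = c(obs$ss, obs$ss_res, ss_tot) / ss_tot,
    f = c(obs$f, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- nrow(perms)
  attr(out, "term_order") <- terms
  out
}

#' Within-group time decay of community dissimilarity
#'
#' All sample pairs within each group (default site x size-fraction) with
#' their time lag in decimal months and dissimilarity, the raw material of
#' time-decay plots.
#'
#' @param dist a [stats::dist] or labelled symmetric matrix.
#' @param meta metadata with `sample_id`, `date`, and the grouping columns.
#' @param group_vars metadata columns defining groups; `NULL` for one
#'   global group.
#' @return data.frame: sample_j, sample_k, group columns, dt_months,
#'   dissimilarity.
#' @export
time_decay <- function(dist, meta, group_vars = c("site", "size_fraction")) {
  dm <- as.matrix(dist)
  ids <- rownames(dm)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) stop("distance ids missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  if (is.null(meta$date)) stop("metadata needs a date column")
  group_vars <- intersect(group_vars, names(meta))
  grp <- if (length(group_vars)) interaction(meta[group_vars], drop = TRUE) else factor(rep(1, nrow(meta)))
  tm <- months_since(meta$date)
  out <- list()
  for (gl in levels(grp)) {
    w <- which(grp == gl)
    if (length(w) < 2) next
    pr <- utils::combn(w, 2)
    df <- data.frame(sample_j = ids[pr[1, ]], sample_k = ids[pr[2, ]],
                     dt_months = abs(tm[pr[1, ]] - tm[pr[2, ]]),
                     dissimilarity = dm[cbind(pr[1, ], pr[2, ])],
                     stringsAsFactors = FALSE)
    for (v in group_vars) df[[v]] <- meta[[v]][w[1]]
    out[[gl]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
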