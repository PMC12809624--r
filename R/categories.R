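# ASV categorisation across two observatories: common, exclusive,
# indicator (IndVal) and background.

#' Shared and site-exclusive ASVs between two tables
#'
#' ASVs with zero counts everywhere are excluded with a warning.
#'
#' @param table_a,table_b samples x ASVs counts for the two sites (same ASV
#'   id space not required; the union is used).
#' @return list: `shared`, `a_only`, `b_only` (character vectors) and
#'   `counts` (named sizes).
#' @export
shared_unique <- function(table_a, table_b) {
  pres_a <- colnames(table_a)[colSums(table_a) > 0]
  pres_b <- colnames(table_b)[colSums(table_b) > 0]
  all_ids <- union(colnames(table_a), colnames(table_b))
  absent <- setdiff(all_ids, union(pres_a, pres_b))
  if (length(absent)) {
    warning(length(absent), " ASV(s) with zero counts everywhere excluded")
  }
  out <- list(shared = intersect(pres_a, pres_b),
              a_only = setdiff(pres_a, pres_b),
              b_only = setdiff(pres_b, pres_a))
  out$counts <- c(shared = length(out$shared), a_only = length(out$a_only),
                  b_only = length(out$b_only))
  out
}

#' Site occupancy of each ASV
#' @param table samples x ASVs counts.
#' @return named fraction of samples with count > 0.
#' @export
site_occupancy <- function(table) colMeans(table > 0)

#' Common ASVs: shared with > 50% occurrence at both sites
#'
#' Strictly greater than `min_occ` at both sites.
#'
#' @param shared character vector of shared ASV ids.
#' @param occ_a,occ_b named occupancy vectors (see [site_occupancy()]).
#' @param min_occ occupancy threshold (default 0.5).
#' @return character vector of common ASV ids.
#' @export
common_asvs <- function(shared, occ_a, occ_b, min_occ = 0.5) {
  shared[occ_a[shared] > min_occ & occ_b[shared] > min_occ]
}

#' Group-equalised indicator value (IndVal.g) with permutation test
#'
#' For ASV i and group g, specificity
#' `A_ig = mean abundance in g / sum over groups of mean abundances` and
#' fidelity `B_ig = fraction of g's samples where i is present`; the
#' statistic is `max_g sqrt(A_ig B_ig)`, tested by permuting group labels:
#' `p = (#\{stat_perm >= stat_obs\} + 1) / (n_perm + 1)`.
#'
#' @param table samples x ASVs abundances.
#' @param groups factor/character of group membership per sample (>= 2
#'   groups, each with >= 2 samples).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return data.frame: asv_id, group (argmax group), stat, p.
#' @export
indval <- function(table, groups, n_perm = 999, seed = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  gm <- rowsum(table, groups) / as.vector(table(groups))
  if (any(colSums(gm) == 0)) {
    # ASVs absent everywhere make A undefined
    stop("ASV(s) with zero abundance in every group: ",
         paste(colnames(table)[colSums(gm) == 0], collapse = ", "))
  }
  if (any(rowSums(gm) == 0)) {
    stop("group(s) with all-zero abundances: ",
         paste(rownames(gm)[rowSums(gm) == 0], collapse = ", "))
  }
  stat_fun <- function(g) {
    mg <- rowsum(table, g) / as.vector(table(g))
    a <- sweep(mg, 2, colSums(mg), "/")
    b <- rowsum(1 * (table > 0), g) / as.vector(table(g))
    sqrt(a * b)
  }
  iv <- stat_fun(groups)
  stat <- apply(iv, 2, max)
  best <- rownames(iv)[apply(iv, 2, which.max)]
  exceed <- rep(0, ncol(table))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      sp <- apply(stat_fun(sample(groups)), 2, max)
      exceed <- exceed + (sp >= stat - 1e-12)
    }
  })
  data.frame(asv_id = colnames(table), group = best, stat = as.numeric(stat),
             p = (exceed + 1) / (n_perm + 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assign headline categories to ASVs across two sites
#'
#' Headline priority: common > indicator > exclusive > background, with all
#' overlap flags preserved (an exclusive ASV that also passes the indicator
#' test is headline "indicator" with `exclusive = TRUE`).
#'
#' @param table_a,table_b samples x ASVs counts per site (ASVs unioned; a
#'   missing column counts as absent).
#' @param site_names length-2 labels used in category names.
#' @param n_perm,seed IndVal permutation settings.
#' @param min_occ common-ASV occupancy threshold (0.5).
#' @param indval_min,indval_p indicator thresholds (0.7 and 0.01).
#' @return data.frame, one row per detected ASV: asv_id, occurrence per
#'   site, shared/exclusive/common/indicator flags, indval_stat, indval_p,
#'   indval_group and headline `category`.
#' @export
assign_categories <- function(table_a, table_b, site_names = c("A", "B"),
                              n_perm = 999, seed = NULL, min_occ = 0.5,
                              indval_min = 0.7, indval_p = 0.01) {
  ids <- union(colnames(table_a), colnames(table_b))
  pad <- function(tab) {
    m <- matrix(0L, nrow(tab), length(ids), dimnames = list(rownames(tab), ids))
    m[, colnames(tab)] <- as.matrix(tab)
    m
  }
  ta <- pad(table_a); tb <- pad(table_b)
  su <- shared_unique(ta, tb)
  detected <- c(su$shared, su$a_only, su$b_only)
  occ_a <- site_occupancy(ta); occ_b <- site_occupancy(tb)
  common <- common_asvs(su$shared, occ_a, occ_b, min_occ)
  merged <- rbind(ta, tb)[, detected, drop = FALSE]
  groups <- rep(site_names, c(nrow(ta), nrow(tb)))
  iv <- indval(merged, groups, n_perm = n_perm, seed = seed)
  iv <- iv[match(detected, iv$asv_id), ]
  is_ind <- iv$stat > indval_min & iv$p < indval_p
  out <- data.frame(
    asv_id = detected,
    occurrence_a = as.numeric(occ_a[detected]),
    occurrence_b = as.numeric(occ_b[detected]),
    shared = detected %in% su$shared,
    exclusive = ifelse(detected %in% su$a_only, site_names[1],
                ifelse(detected %in% su$b_only, site_names[2], NA_character_)),
    common = detected %in% common,
    indicator = is_ind,
    indval_group = iv$group, indval_stat = iv$stat, indval_p = iv$p,
    stringsAsFactors = FALSE)
  if (any(out$common & !is.na(out$exclusive))) {
    stop("contradictory assignment: common and exclusive")
  }
  out$category <- ifelse(out$common, "common",
                  ifelse(out$indicator, paste0("indicator-", out$indval_group),
                  ifelse(!is.na(out$exclusive), paste0("exclusive-", out$exclusive),
                         "background")))
  out
}
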