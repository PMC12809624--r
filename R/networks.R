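# CLR preprocessing, co-occurrence edge filtering, monthly temporal
# subnetworks, topology metrics and metric-environment correlations.

#' Centred log-ratio transformation
#'
#' Per sample: `y_i = ln(x_i + pc) - mean_j ln(x_j + pc)`.
#'
#' @param table samples x ASVs integer counts.
#' @param pseudocount added before taking logs (default 1).
#' @return real-valued matrix with provenance `"clr"`; rows sum to 0.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  validate_count_table(table, attr(table, "provenance") %||% "raw",
                       allow_empty_samples = TRUE)
  lg <- log(table + pseudocount)
  out <- lg - rowMeans(lg)
  attr(out, "provenance") <- "clr"
  out
}

#' Filter network edges by co-occurrence score and drop isolated nodes
#'
#' The co-occurrence score of an edge is the fraction of samples in which
#' both endpoints are detected (> 0). Edges scoring below `min_score` are
#' removed, then nodes left without any edge are dropped. The score is a
#' joint-detection frequency, the interpretation used by the temporal
#' subnetwork workflow; network inference itself is an input here.
#'
#' @param net an `assoc_network`.
#' @param detection samples x nodes matrix of abundances (or logicals);
#'   must cover every node.
#' @param min_score minimum score to keep an edge (default 0.5).
#' @return filtered `assoc_network` with recomputed `cooccurrence_score`.
#' @export
cooccurrence_filter <- function(net, detection, min_score = 0.5) {
  miss <- setdiff(net$nodes$id, colnames(detection))
  if (length(miss)) stop("node(s) missing from detection matrix: ",
                         paste(miss, collapse = ", "))
  det <- detection[, , drop = FALSE] > 0
  e <- net$edges
  e$cooccurrence_score <- vapply(seq_len(nrow(e)), function(i) {
    mean(det[, e$from[i]] & det[, e$to[i]])
  }, 0)
  e <- e[e$cooccurrence_score >= min_score, , drop = FALSE]
  keep_nodes <- net$nodes$id %in% c(e$from, e$to)
  assoc_network(net$nodes[keep_nodes, , drop = FALSE], e)
}

#' Monthly temporal subnetworks of a static association network
#'
#' A node is present in a month's subnetwork when its abundance in that
#' month's sample(s) is above zero; an edge is present when it exists in
#' the static network and both endpoints are present. Months without
#' samples are skipped with a warning.
#'
#' @param net static `assoc_network` whose node ids are columns of `table`.
#' @param table samples x nodes abundances.
#' @param meta metadata with `sample_id` and `date`; samples are grouped by
#'   calendar month (`YYYY-MM`).
#' @return named list of `assoc_network` objects, one per sampled month.
#' @export
monthly_subnetworks <- function(net, table, meta) {
  miss <- setdiff(net$nodes$id, colnames(table))
  if (length(miss)) stop("node(s) missing from abundance table: ",
                         paste(miss, collapse = ", "))
  idx <- match(rownames(table), meta$sample_id)
  if (anyNA(idx)) stop("table samples missing from metadata")
  month <- format(as.Date(meta$date[idx]), "%Y-%m")
  out <- list()
  for (mo in sort(unique(month))) {
    rows <- which(month == mo)
    if (!length(rows)) { warning("month without samples skipped: ", mo); next }
    present <- net$nodes$id[colSums(table[rows, net$nodes$id, drop = FALSE] > 0) > 0]
    e <- net$edges[net$edges$from %in% present & net$edges$to %in% present, , drop = FALSE]
    out[[mo]] <- assoc_network(net$nodes[net$nodes$id %in% present, , drop = FALSE], e)
  }
  out
}

#' Global topology metrics of an association network
#'
#' Edge density `m / (n(n-1)/2)`, mean degree, global transitivity (closed
#' over all triplets), average shortest-path length over connected pairs
#' (edge signs and weights ignored for connectivity), degree assortativity,
#' categorical (Newman) assortativity on domain and size-fraction, and the
#' mean of positive edge weights. Metrics undefined on the given graph
#' (e.g. assortativity with a single category) are `NA` with the reason
#' recorded in the `reasons` attribute.
#'
#' @param net an `assoc_network` (or igraph with matching attributes).
#' @return one-row data.frame of metrics with a `reasons` attribute.
#' @export
network_metrics <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  reasons <- character()
  na_reason <- function(metric, why) reasons[[metric]] <<- why
  dens <- if (n > 1) m / (n * (n - 1) / 2) else { na_reason("edge_density", "fewer than 2 nodes"); NA }
  mean_deg <- if (n > 0) 2 * m / n else NA
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) { trans <- NA; na_reason("transitivity", "no connected triplets") }
  apl <- if (m > 0) igraph::mean_distance(g, weights = NA) else { na_reason("avg_path_length", "edgeless graph"); NA }
  if (is.nan(apl %||% NA)) { apl <- NA; na_reason("avg_path_length", "no connected pairs") }
  deg_ass <- if (m > 1) suppressWarnings(igraph::assortativity_degree(g)) else NA
  if (is.na(deg_ass) || is.nan(deg_ass)) {
    deg_ass <- NA; na_reason("assortativity_degree", "degree variance zero or too few edges")
  }
  cat_ass <- function(attrname, metric) {
    if (!attrname %in% igraph::vertex_attr_names(g)) { na_reason(metric, "attribute absent"); return(NA) }
    v <- igraph::vertex_attr(g, attrname)
    if (anyNA(v) || length(unique(v)) < 2) { na_reason(metric, "fewer than 2 categories"); return(NA) }
    out <- suppressWarnings(igraph::assortativity_nominal(g, factor(v)))
    if (is.nan(out)) { na_reason(metric, "degenerate mixing matrix"); return(NA) }
    out
  }
  dom_ass <- cat_ass("domain_marker", "assortativity_domain")
  frac_ass <- cat_ass("size_fraction", "assortativity_fraction")
  w <- igraph::edge_attr(g, "weight")
  sgn <- igraph::edge_attr(g, "sign")
  pos <- if (!is.null(sgn)) w[sgn == "+"] else w[w > 0]
  mps <- if (length(pos)) mean(pos) else { na_reason("mean_positive_strength", "no positive edges"); NA }
  out <- data.frame(n_nodes = n, n_edges = m, edge_density = dens,
                    mean_degree = mean_deg, transitivity = trans,
                    avg_path_length = apl, assortativity_degree = deg_ass,
                    assortativity_domain = dom_ass,
                    assortativity_fraction = frac_ass,
                    mean_positive_strength = mps)
  attr(out, "reasons") <- reasons
  out
}

#' Metric series for a list of monthly subnetworks
#'
#' @param subnets named list from [monthly_subnetworks()].
#' @return data.frame with a `month` column followed by the
#'   [network_metrics()] columns.
#' @export
subnetwork_metrics <- function(subnets) {
  rows <- lapply(names(subnets), function(mo) {
    cbind(month = mo, network_metrics(subnets[[mo]]))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correlate network metric series with environmental series
#'
#' Spearman rank correlation per (metric, variable) over pairwise-complete
#' months, with Holm's step-down adjustment across the whole family of
#' tested pairs. Pairs with fewer than `min_pairs` complete observations
#' are reported `NA` with a reason.
#'
#' @param metrics data.frame from [subnetwork_metrics()] (needs `month`).
#' @param env data.frame with `month` (`YYYY-MM`) and numeric variables.
#' @param metric_cols,env_cols columns to test; default all numeric.
#' @param min_pairs minimum complete pairs (default 4).
#' @return data.frame: metric, variable, n, rho, p, p_holm, note.
#' @export
metric_env_correlations <- function(metrics, env, metric_cols = NULL,
                                    env_cols = NULL, min_pairs = 4) {
  joined <- merge(metrics, env, by = "month")
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)], "month")
  }
  if (is.null(env_cols)) {
    env_cols <- setdiff(names(env)[vapply(env, is.numeric, TRUE)], "month")
  }
  out <- expand.grid(metric = metric_cols, variable = env_cols,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$rho <- NA_real_; out$p <- NA_real_
  out$note <- ""
  for (i in seq_len(nrow(out))) {
    x <- joined[[out$metric[i]]]; y <- joined[[out$variable[i]]]
    ok <- is.finite(x) & is.finite(y)
    out$n[i] <- sum(ok)
    if (sum(ok) < min_pairs) { out$note[i] <- "fewer than min_pairs complete observations"; next }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    out$rho[i] <- unname(ct$estimate); out$p[i] <- ct$p.value
  }
  out$p_holm <- NA_real_
  tested <- !is.na(out$p)
  out$p_holm[tested] <- stats::p.adjust(out$p[tested], method = "holm")
  out
}

#' Baseline co-occurrence network from CLR profiles
#'
#' Thresholded Pearson correlation of CLR-transformed abundance profiles:
#' plumbing for end-to-end synthetic runs, not a substitute for a dedicated
#' network-inference method (static networks are normally inputs).
#'
#' @param clr_table samples x ASVs CLR matrix (see [clr_transform()]).
#' @param cutoff absolute correlation threshold for an edge.
#' @param nodes optional node data.frame (defaults to the table's columns).
#' @return an `assoc_network`; weight is the correlation, sign its sign,
#'   cooccurrence_score the joint detection frequency (requires `detection`
#'   to be refined later via [cooccurrence_filter()], here set to 1).
#' @export
infer_cooccurrence <- function(clr_table, cutoff = 0.7, nodes = NULL) {
  cc <- stats::cor(clr_table)
  cc[!is.finite(cc)] <- 0
  ids <- colnames(clr_table)
  sel <- which(abs(cc) >= cutoff & upper.tri(cc), arr.ind = TRUE)
  edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                      sign = ifelse(cc[sel] >= 0, "+", "-"),
                      weight = cc[sel], cooccurrence_score = rep(1, nrow(sel)),
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- data.frame(id = ids)
  assoc_network(nodes, edges)
}
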