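# ---- count tables -----------------------------------------------------------

#' Validate a community count table
#'
#' The canonical in-memory orientation is samples as rows and ASVs as
#' columns. Raw and rarefied tables must hold non-negative integers;
#' centred-log-ratio tables (`provenance = "clr"`) are real-valued.
#'
#' @param counts numeric matrix with sample ids as rownames and ASV ids as
#'   colnames.
#' @param provenance one of `"raw"`, `"rarefied"`, `"clr"`.
#' @param allow_empty_samples keep samples whose total is zero.
#' @return the matrix, invisibly, with a `provenance` attribute.
#' @export
validate_count_table <- function(counts, provenance = c("raw", "rarefied", "clr"),
                                 allow_empty_samples = FALSE) {
  provenance <- match.arg(provenance)
  if (!is.matrix(counts) || !is.numeric(counts)) stop("counts must be a numeric matrix")
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty table")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table needs sample rownames and ASV colnames")
  }
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s)) stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  dup_a <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_a)) stop("duplicated ASV id(s): ", paste(dup_a, collapse = ", "))
  if (anyNA(counts)) stop("count table contains missing values")
  if (provenance != "clr") {
    bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-negative integer counts required; offending cell(s): %s",
        paste(sprintf("[%s, %s] = %g", rownames(counts)[bad[, 1]],
                      colnames(counts)[bad[, 2]],
                      counts[bad[, , drop = FALSE]]), collapse = "; ")))
    }
    if (!allow_empty_samples && any(rowSums(counts) == 0)) {
      stop("sample(s) with zero total: ",
           paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
    }
  }
  attr(counts, "provenance") <- provenance
  invisible(counts)
}

#' Read a tab-separated count table
#'
#' The first column holds ids for one axis, the header row for the other.
#' Orientation is auto-detected against `meta$sample_id` when metadata is
#' supplied; otherwise rows are assumed to be samples unless overridden.
#'
#' @param path TSV file.
#' @param orientation `"auto"`, `"samples"` (rows are samples) or `"asvs"`
#'   (rows are ASVs; table is transposed on read).
#' @param meta optional sample table used by `"auto"` detection.
#' @param provenance recorded on the result; `"raw"` enforces integer counts.
#' @return a validated count matrix (samples x ASVs) with a `provenance`
#'   attribute.
#' @export
read_count_table <- function(path, orientation = c("auto", "samples", "asvs"),
                             meta = NULL, provenance = "raw") {
  orientation <- match.arg(orientation)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  dup_h <- unique(header[duplicated(header)])
  if (length(dup_h)) stop("duplicated column id(s): ", paste(dup_h, collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty table: ", path)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell(s) in %s, e.g. row %d column '%s'",
                 path, bad[1, 1] + 1L, colnames(raw)[-1][bad[1, 2]]))
  }
  rownames(m) <- ids
  if (orientation == "auto") {
    orientation <- "samples"
    if (!is.null(meta)) {
      row_hit <- mean(ids %in% meta$sample_id)
      col_hit <- mean(colnames(m) %in% meta$sample_id)
      if (col_hit > row_hit) orientation <- "asvs"
    }
  }
  if (orientation == "asvs") m <- t(m)
  validate_count_table(m, provenance = provenance)
  attr(m, "provenance") <- provenance
  m
}

#' Write a count table as TSV
#'
#' Samples as rows, first column `sample_id`. Round-trips through
#' [read_count_table()].
#'
#' @param counts samples x ASVs matrix.
#' @param path output file.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' One row per sample; `date` parsed as ISO-8601; remaining columns kept
#' as-is (site, size_fraction, domain_marker, environmental variables).
#'
#' @param path TSV with at least a `sample_id` column.
#' @return data.frame with parsed `date` if present.
#' @export
read_sample_table <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata needs a sample_id column")
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) stop("duplicated sample id(s) in metadata: ", paste(dup, collapse = ", "))
  if ("date" %in% names(meta)) {
    d <- as.Date(meta$date)
    if (anyNA(d)) stop("unparseable date(s): ",
                       paste(meta$date[is.na(d)], collapse = ", "))
    meta$date <- d
  }
  meta
}

#' Write a sample metadata table
#' @param meta data.frame with a `sample_id` column.
#' @param path output TSV.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- trees ------------------------------------------------------------------

#' Read a rooted newick tree
#'
#' @param path newick file.
#' @return an [ape::phylo] tree; missing branch lengths are set to 0 with a
#'   warning.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("unparseable newick: ", path)
  validate_tree(tree)
}

#' Validate a phylogeny for downstream use
#' @param tree an [ape::phylo] object.
#' @return the tree (branch lengths NA/absent replaced by 0 with a warning).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (ape::Ntip(tree) < 2) stop("tree has fewer than 2 tips")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicated tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning(sum(is.na(tree$edge.length)), " missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length(s)")
  tree
}

#' Align a count table, tree and metadata to their common samples and taxa
#'
#' Restricts the table to samples present in the metadata, prunes the tree
#' to ASVs present in the table, and records what was dropped. ASVs absent
#' from the tree stay in the table (taxonomic analyses keep them) but are
#' listed so phylogeny-dependent stages can exclude them.
#'
#' @param table samples x ASVs count matrix.
#' @param tree optional [ape::phylo].
#' @param meta sample metadata with `sample_id`.
#' @return list with `table`, `tree`, `meta` and a `report` list
#'   (`samples_dropped`, `tips_pruned`, `asvs_missing_from_tree`).
#' @export
align_inputs <- function(table, tree = NULL, meta = NULL) {
  report <- list(samples_dropped = character(), tips_pruned = character(),
                 asvs_missing_from_tree = character())
  if (!is.null(meta)) {
    keep <- rownames(table) %in% meta$sample_id
    if (!any(keep)) stop("no samples shared between table and metadata")
    report$samples_dropped <- rownames(table)[!keep]
    table <- table[keep, , drop = FALSE]
    meta <- meta[match(rownames(table), meta$sample_id), , drop = FALSE]
  }
  if (!is.null(tree)) {
    tree <- validate_tree(tree)
    in_tree <- colnames(table) %in% tree$tip.label
    report$asvs_missing_from_tree <- colnames(table)[!in_tree]
    if (!any(in_tree)) stop("no taxa shared between table and tree")
    extra <- setdiff(tree$tip.label, colnames(table))
    report$tips_pruned <- extra
    if (length(extra)) tree <- ape::keep.tip(tree, intersect(tree$tip.label, colnames(table)))
    if (length(report$asvs_missing_from_tree)) {
      message(length(report$asvs_missing_from_tree),
              " ASV(s) absent from the tree; excluded from phylogenetic analyses")
    }
  }
  list(table = table, tree = tree, meta = meta, report = report)
}

# ---- association networks ---------------------------------------------------

#' Construct a signed association network
#'
#' @param nodes data.frame with columns `id` and optionally `domain_marker`,
#'   `size_fraction`.
#' @param edges data.frame with columns `from`, `to`, `sign` (`"+"`/`"-"`),
#'   `weight`, `cooccurrence_score` (in `[0, 1]`).
#' @return an object of class `assoc_network`.
#' @export
assoc_network <- function(nodes, edges) {
  if (is.character(nodes)) nodes <- data.frame(id = nodes)
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicated node id(s)")
  if (!"domain_marker" %in% names(nodes)) nodes$domain_marker <- NA_character_
  if (!"size_fraction" %in% names(nodes)) nodes$size_fraction <- NA_character_
  need <- c("from", "to", "sign", "weight", "cooccurrence_score")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop("edge table missing column(s): ", paste(miss, collapse = ", "))
  edges <- edges[, need, drop = FALSE]
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    stop("self-loop(s): ", paste(unique(edges$from[edges$from == edges$to]), collapse = ", "))
  }
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(bad)) stop("edge endpoint(s) missing from node table: ", paste(bad, collapse = ", "))
  if (!all(edges$sign %in% c("+", "-"))) stop("edge sign must be '+' or '-'")
  if (any(edges$cooccurrence_score < 0 | edges$cooccurrence_score > 1, na.rm = TRUE)) {
    stop("cooccurrence_score must lie in [0, 1]")
  }
  key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to), paste(edges$to, edges$from))
  if (anyDuplicated(key)) stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(list(nodes = nodes, edges = edges[order(key), , drop = FALSE]),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "+"),
              sum(x$edges$sign == "-")))
  invisible(x)
}

#' Read an association network
#'
#' Edge-list TSV (`node1 node2 sign weight cooccurrence_score`, with an
#' optional companion node table) or GraphML, chosen by file extension.
#'
#' @param path `.tsv`/`.txt` edge list or `.graphml` file.
#' @param nodes optional node data.frame (edge-list input only); defaults to
#'   the union of edge endpoints.
#' @return an `assoc_network`.
#' @export
read_network <- function(path, nodes = NULL) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph_to_network(g))
  }
  e <- utils::read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  names(e)[1:2] <- c("from", "to")
  if (is.null(nodes)) nodes <- data.frame(id = unique(c(e$from, e$to)))
  assoc_network(nodes, e)
}

#' Write an association network
#'
#' @param net an `assoc_network`.
#' @param path `.graphml` for GraphML, anything else for edge-list TSV.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    e <- net$edges
    names(e)[1:2] <- c("node1", "node2")
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Convert an association network to igraph
#' @param net an `assoc_network`.
#' @param signed keep negative-weight edges as-is (weights are never used as
#'   distances by the metric functions).
#' @return an undirected [igraph::igraph] graph with node/edge attributes.
#' @export
as_igraph <- function(net, signed = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

# igraph -> assoc_network (GraphML round-trip)
igraph_to_network <- function(g) {
  nodes <- data.frame(id = igraph::V(g)$name)
  for (a in c("domain_marker", "size_fraction")) {
    if (a %in% igraph::vertex_attr_names(g)) nodes[[a]] <- igraph::vertex_attr(g, a)
  }
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2])
  for (a in c("sign", "weight", "cooccurrence_score")) {
    edges[[a]] <- if (a %in% igraph::edge_attr_names(g)) igraph::edge_attr(g, a) else NA
  }
  assoc_network(nodes, edges)
}
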