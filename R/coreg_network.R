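ffl_edge_rows <- function(f) {
  base <- switch(as.character(f$ffl_class),
    TF_FFL = data.frame(
      source = c(f$tf_id, f$tf_id, f$mirna_id),
      target = c(f$mirna_id, f$target_gene_id, f$target_gene_id),
      regulation_type = c("TF_regulation", "TF_regulation", "miRNA_regulation"),
      stringsAsFactors = FALSE),
    miRNA_FFL = data.frame(
      source = c(f$mirna_id, f$tf_id, f$mirna_id),
      target = c(f$tf_id, f$target_gene_id, f$target_gene_id),
      regulation_type = c("miRNA_regulation", "TF_regulation", "miRNA_regulation"),
      stringsAsFactors = FALSE),
    composite_FFL = data.frame(
      source = c(f$tf_id, f$mirna_id, f$tf_id, f$mirna_id),
      target = c(f$mirna_id, f$tf_id, f$target_gene_id, f$target_gene_id),
      regulation_type = c("TF_regulation", "miRNA_regulation",
                          "TF_regulation", "miRNA_regulation"),
      stringsAsFactors = FALSE),
    stop("unknown ffl_class: ", f$ffl_class))
  base
}

#' Build a TF-miRNA co-regulatory network from feed-forward loops
#'
#' Takes the union of all motif edges over a loop list and returns a typed
#' directed graph. Nodes carry a `node_type` attribute (`TF`, `miRNA` or
#' `gene`; a gene that ever acts as the TF vertex of a motif is typed `TF`)
#' and edges carry `regulation_type` (`TF_regulation` or
#' `miRNA_regulation`). Parallel duplicates are removed.
#'
#' @param ffls FFL data frame from [enumerate_ffls()].
#' @return an `igraph` directed graph (empty graph for an empty loop list).
#' @export
build_network <- function(ffls) {
  if (nrow(ffls) == 0)
    return(igraph::make_empty_graph(directed = TRUE))
  ed <- do.call(rbind, lapply(seq_len(nrow(ffls)),
                              function(i) ffl_edge_rows(ffls[i, ])))
  ed <- unique(ed)
  nodes <- data.frame(id = unique(c(ffls$tf_id, ffls$mirna_id,
                                    ffls$target_gene_id)),
                      stringsAsFactors = FALSE)
  nodes$node_type <- ifelse(nodes$id %in% ffls$tf_id, "TF",
                            ifelse(nodes$id %in% ffls$mirna_id, "miRNA",
                                   "gene"))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nodes)
}

#' Node degrees and the network hub
#'
#' Degree is computed on the undirected simple graph (multiple regulation
#' edges between the same pair collapse), i.e. the number of distinct
#' neighbours. The hub is the node of maximal degree; ties go to the
#' lexicographically first id.
#'
#' @param net network from [build_network()].
#' @return list: `degree` (named integer vector), `hub` (node id).
#' @export
degree_and_hub <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  und <- igraph::as_undirected(net, mode = "collapse")
  deg <- igraph::degree(igraph::simplify(und))
  hub <- sort(names(deg)[deg == max(deg)])[1]
  list(degree = deg, hub = hub)
}

#' Occurrence ranking of regulators across FFL sets
#'
#' Counts, for every TF and miRNA, the number of loops it participates in
#' per dataset, and ranks regulators within each dataset by descending
#' count (ties ordered by lexicographic id; regulators absent from a
#' dataset are unranked there).
#'
#' @param ffl_sets named list of FFL data frames, one per dataset.
#' @return data frame: `id`, `regulator_kind`, then `<dataset>_ffls` and
#'   `<dataset>_rank` per dataset, and `total_ffls`; sorted by descending
#'   total.
#' @export
occurrence_ranking <- function(ffl_sets) {
  if (length(ffl_sets) == 0) stop("need at least one FFL set")
  if (is.null(names(ffl_sets)) || any(names(ffl_sets) == ""))
    stop("ffl_sets must be named")
  regs <- unique(do.call(rbind, lapply(ffl_sets, function(f)
    data.frame(id = c(f$tf_id, f$mirna_id),
               regulator_kind = rep(c("TF", "miRNA"),
                                    times = c(nrow(f), nrow(f))),
               stringsAsFactors = FALSE))))
  if (is.null(regs) || nrow(regs) == 0) stop("no regulators in any FFL set")
  out <- regs[order(regs$id), , drop = FALSE]
  total <- numeric(nrow(out))
  for (ds in names(ffl_sets)) {
    f <- ffl_sets[[ds]]
    cnt <- vapply(out$id, function(r)
      sum(f$tf_id == r | f$mirna_id == r), numeric(1))
    rank <- rep(NA_integer_, length(cnt))
    pos <- which(cnt > 0)
    rank[pos[order(-cnt[pos], out$id[pos])]] <- seq_along(pos)
    out[[paste0(ds, "_ffls")]] <- as.integer(cnt)
    out[[paste0(ds, "_rank")]] <- rank
    total <- total + cnt
  }
  out$total_ffls <- as.integer(total)
  out <- out[order(-out$total_ffls, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ego subnetwork of a node
#'
#' Returns the node, its direct neighbours, and only the edges incident to
#' the centre node (edges among neighbours are excluded).
#'
#' @param net network from [build_network()].
#' @param node_id centre node id.
#' @return an `igraph` graph.
#' @export
ego_subnetwork <- function(net, node_id) {
  if (!node_id %in% igraph::V(net)$name) stop("unknown node: ", node_id)
  eids <- igraph::incident(net, node_id, mode = "all")
  igraph::subgraph_from_edges(net, eids, delete.vertices = TRUE)
}

#' Power-law exponent of a degree distribution
#'
#' Least-squares slope of log(count) versus log(degree) over the empirical
#' degree distribution (degree-0 nodes ignored); the exponent is the
#' negated slope. Scale-free networks typically show exponents between 2
#' and 3.
#'
#' @param degrees named degree vector (see [degree_and_hub()]).
#' @return exponent estimate (single number).
#' @export
powerlaw_exponent <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3) stop("need >= 3 distinct degree values")
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  fit <- stats::lm(log(cnt) ~ log(k))
  -unname(stats::coef(fit)[2])
}

#' Export a network in SIF format
#'
#' One line per edge: `source<TAB>regulation_type<TAB>target`
#' (Cytoscape-compatible simple interaction format).
#'
#' @param net network from [build_network()].
#' @param path output path.
#' @export
export_sif <- function(net, path) {
  ed <- igraph::as_data_frame(net, what = "edges")
  writeLines(if (nrow(ed) == 0) character(0)
             else paste(ed$from, ed$regulation_type, ed$to, sep = "\t"),
             path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Node `node_type` and edge `regulation_type` attributes are preserved, so
#' the file styles directly in Cytoscape.
#'
#' @param net network from [build_network()].
#' @param path output path.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
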