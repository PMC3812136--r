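FFL_CLASSES <- c("TF_FFL", "miRNA_FFL", "composite_FFL")

empty_ffl_table <- function() {
  data.frame(ffl_class = character(0), tf_id = character(0),
             mirna_id = character(0), target_gene_id = character(0),
             stringsAsFactors = FALSE)
}

ffl_key <- function(ffls) {
  paste(ffls$ffl_class, ffls$tf_id, ffls$mirna_id, ffls$target_gene_id,
        sep = "\r")
}

triple_key <- function(d) paste(d$tf_id, d$mirna_id, d$target_gene_id, sep = "\r")

sort_ffls <- function(ffls) {
  ord <- order(match(ffls$ffl_class, FFL_CLASSES), ffls$tf_id, ffls$mirna_id,
               ffls$target_gene_id)
  ffls <- ffls[ord, , drop = FALSE]
  rownames(ffls) <- NULL
  ffls
}

#' Enumerate TF-miRNA feed-forward loops from an identified edge set
#'
#' A feed-forward loop here is a 3-vertex motif over a TF, a miRNA and a
#' target gene in which both regulators control the target and one
#' regulator also controls the other:
#' \describe{
#'   \item{TF_FFL}{TF->miRNA, TF->gene, miRNA->gene (TF is master).}
#'   \item{miRNA_FFL}{miRNA->TF, miRNA->gene, TF->gene (miRNA is master).}
#'   \item{composite_FFL}{TF and miRNA regulate each other and both
#'     regulate the gene (all four edges).}
#' }
#' miRNA->TF regulation is read off miRNA->gene edges whose target gene sits
#' in the TF roster. Composite instances are reported only as composite,
#' never additionally as TF_FFL or miRNA_FFL, so class counts are additive.
#' All three vertices must be distinct; output ordering is deterministic
#' (class, tf, mirna, gene).
#'
#' @param edges typed edge data frame (prior catalog or identified edge
#'   set): columns `regulator_type`, `regulator_id`, `target_type`,
#'   `target_id`.
#' @param tf_roster character vector of gene ids designated as TFs.
#' @return data frame with columns `ffl_class`, `tf_id`, `mirna_id`,
#'   `target_gene_id`.
#' @export
enumerate_ffls <- function(edges, tf_roster) {
  if (nrow(edges) == 0) return(empty_ffl_table())
  tf_m <- edges[edges$regulator_type == "TF" & edges$target_type == "miRNA",
                c("regulator_id", "target_id")]
  names(tf_m) <- c("tf_id", "mirna_id")
  tf_g <- edges[edges$regulator_type == "TF" & edges$target_type == "gene",
                c("regulator_id", "target_id")]
  names(tf_g) <- c("tf_id", "target_gene_id")
  m_g <- edges[edges$regulator_type == "miRNA" & edges$target_type == "gene",
               c("regulator_id", "target_id")]
  names(m_g) <- c("mirna_id", "target_gene_id")
  m_tf <- m_g[m_g$target_gene_id %in% tf_roster, ]
  names(m_tf) <- c("mirna_id", "tf_id")

  mg_key <- paste(m_g$mirna_id, m_g$target_gene_id, sep = "\r")
  tg_key <- paste(tf_g$tf_id, tf_g$target_gene_id, sep = "\r")

  # TF-master candidates: join TF->miRNA with TF->gene, then require miRNA->gene
  tf_cand <- merge(tf_m, tf_g, by = "tf_id")
  tf_cand <- tf_cand[paste(tf_cand$mirna_id, tf_cand$target_gene_id, sep = "\r")
                     %in% mg_key, , drop = FALSE]
  # miRNA-master candidates: join miRNA->TF with miRNA->gene, require TF->gene
  mi_cand <- merge(m_tf, m_g, by = "mirna_id")
  mi_cand <- mi_cand[paste(mi_cand$tf_id, mi_cand$target_gene_id, sep = "\r")
                     %in% tg_key, , drop = FALSE]

  distinct3 <- function(d)
    d[d$tf_id != d$target_gene_id & d$mirna_id != d$target_gene_id &
        d$mirna_id != d$tf_id, , drop = FALSE]
  tf_cand <- distinct3(tf_cand)
  mi_cand <- distinct3(mi_cand)

  comp_keys <- intersect(triple_key(tf_cand), triple_key(mi_cand))
  pieces <- list()
  if (nrow(tf_cand) > 0) {
    tfo <- tf_cand[!(triple_key(tf_cand) %in% comp_keys), , drop = FALSE]
    if (nrow(tfo) > 0) pieces$tf <- cbind(ffl_class = "TF_FFL", tfo)
  }
  if (nrow(mi_cand) > 0) {
    mio <- mi_cand[!(triple_key(mi_cand) %in% comp_keys), , drop = FALSE]
    if (nrow(mio) > 0) pieces$mi <- cbind(ffl_class = "miRNA_FFL", mio)
    comp <- mi_cand[triple_key(mi_cand) %in% comp_keys, , drop = FALSE]
    if (nrow(comp) > 0) pieces$comp <- cbind(ffl_class = "composite_FFL", comp)
  }
  cols <- c("ffl_class", "tf_id", "mirna_id", "target_gene_id")
  out <- do.call(rbind, c(list(empty_ffl_table()),
                          lapply(pieces, function(d) d[, cols])))
  sort_ffls(unique(out))
}

#' Count feed-forward loops by class
#'
#' @param ffls output of [enumerate_ffls()].
#' @return named integer vector over `TF_FFL`, `miRNA_FFL`, `composite_FFL`.
#' @export
count_ffls <- function(ffls) {
  vapply(FFL_CLASSES, function(cl) sum(ffls$ffl_class == cl), integer(1))
}

#' Intersect two feed-forward loop lists
#'
#' Loops are matched on the full (class, tf, mirna, gene) identity; used to
#' find motifs shared by two datasets.
#'
#' @param a,b FFL data frames as returned by [enumerate_ffls()].
#' @return the common loops, deterministically sorted.
#' @export
common_ffls <- function(a, b) {
  out <- a[ffl_key(a) %in% ffl_key(b), , drop = FALSE]
  sort_ffls(unique(out))
}

#' Write a feed-forward loop list to TSV
#' @param ffls FFL data frame.
#' @param path output path.
#' @export
write_ffls <- function(ffls, path) {
  utils::write.table(ffls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
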