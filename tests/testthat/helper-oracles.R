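# Independent oracles used to cross-check the implementation. Each one
# recomputes the quantity by the most direct route available (explicit
# summation, exhaustive enumeration, closed forms) and shares no code with
# the functions under test.

# mutual information by explicit double summation over the joint table
mi_oracle <- function(x, y) {
  n <- length(x)
  xs <- unique(x); ys <- unique(y)
  total <- 0
  for (a in xs) for (b in ys) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

# greedy mRMR re-evaluated from scratch at every step
mrmr_oracle <- function(target, profiles, scheme, max_keep = 20L) {
  dt <- discretize(target, scheme)
  dc <- lapply(profiles, discretize, scheme = scheme)
  ids <- sort(names(profiles))
  selected <- character(0)
  k <- min(max_keep, length(ids))
  for (step in seq_len(k)) {
    remaining <- setdiff(ids, selected)
    obj <- sapply(remaining, function(id) {
      rel <- mi_oracle(dc[[id]], dt)
      if (length(selected) == 0) rel
      else rel - mean(sapply(selected, function(s) mi_oracle(dc[[id]], dc[[s]])))
    })
    best <- remaining[obj == max(obj)]
    selected <- c(selected, sort(best)[1])
  }
  selected
}

# OLS by the normal equations, with the overall F-test closed form
ols_oracle <- function(y, X) {
  ys <- (y - mean(y)) / sd(y)
  Xs <- apply(X, 2, function(v) (v - mean(v)) / sd(v))
  A <- cbind(1, Xs)
  beta <- solve(t(A) %*% A, t(A) %*% ys)
  resid <- ys - A %*% beta
  rss <- sum(resid^2)
  tss <- sum((ys - mean(ys))^2)
  p <- ncol(Xs)
  n <- length(y)
  f <- ((tss - rss) / p) / (rss / (n - p - 1))
  list(beta = as.numeric(beta[-1]), f = f,
       p = pf(f, p, n - p - 1, lower.tail = FALSE))
}

# FFL enumeration by testing every (tf, mirna, gene) triple
ffl_oracle <- function(edges, tf_roster) {
  has <- function(rt, rid, tt, tid)
    any(edges$regulator_type == rt & edges$regulator_id == rid &
          edges$target_type == tt & edges$target_id == tid)
  tfs <- unique(edges$regulator_id[edges$regulator_type == "TF"])
  tfs <- union(tfs, intersect(edges$target_id, tf_roster))
  mirnas <- unique(c(edges$regulator_id[edges$regulator_type == "miRNA"],
                     edges$target_id[edges$target_type == "miRNA"]))
  genes <- unique(edges$target_id[edges$target_type == "gene"])
  out <- list()
  for (tf in tfs) for (m in mirnas) for (g in genes) {
    if (tf == g || m == g || m == tf) next
    t_m <- has("TF", tf, "miRNA", m)
    m_t <- (tf %in% tf_roster) && has("miRNA", m, "gene", tf)
    t_g <- has("TF", tf, "gene", g)
    m_g <- has("miRNA", m, "gene", g)
    if (!(t_g && m_g)) next
    cl <- if (t_m && m_t) "composite_FFL"
          else if (t_m) "TF_FFL"
          else if (m_t) "miRNA_FFL"
          else next
    out[[length(out) + 1]] <- data.frame(ffl_class = cl, tf_id = tf,
                                         mirna_id = m, target_gene_id = g,
                                         stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(ffl_class = character(0), tf_id = character(0),
                      mirna_id = character(0), target_gene_id = character(0)))
  do.call(rbind, out)
}

# random typed digraph over TF/miRNA/gene vertex sets
random_typed_edges <- function(n_tf, n_mir, n_gene, p_edge, tf_roster_frac = 1) {
  tfs <- sprintf("t%02d", seq_len(n_tf))
  mirs <- sprintf("m%02d", seq_len(n_mir))
  genes <- sprintf("g%02d", seq_len(n_gene))
  pool <- rbind(
    expand.grid(regulator_type = "TF", regulator_id = tfs,
                target_type = "miRNA", target_id = mirs,
                stringsAsFactors = FALSE),
    expand.grid(regulator_type = "TF", regulator_id = tfs,
                target_type = "gene", target_id = c(genes, tfs),
                stringsAsFactors = FALSE),
    expand.grid(regulator_type = "miRNA", regulator_id = mirs,
                target_type = "gene", target_id = c(genes, tfs),
                stringsAsFactors = FALSE))
  pool <- pool[pool$regulator_id != pool$target_id, ]
  edges <- pool[runif(nrow(pool)) < p_edge, ]
  rownames(edges) <- NULL
  edges$source_tag <- "rand"
  list(edges = edges, tf_roster = tfs)
}

ffl_sort_key <- function(f)
  paste(f$ffl_class, f$tf_id, f$mirna_id, f$target_gene_id)

# AUC as the exhaustive pairwise concordance probability
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(pos) * length(neg))
}

# small expression TSV written to a temp file
write_expr_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
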