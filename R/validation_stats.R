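edge_pair_key <- function(edges)
  paste(edges$regulator_id, edges$target_id, sep = "\r")

#' Permute an expression dataset feature-wise
#'
#' Shuffles every feature's values independently across samples in both
#' layers, destroying regulator-target covariation while preserving each
#' feature's marginal distribution. This is the null used for the
#' permutation false-discovery-rate.
#'
#' @param dataset a `ParallelDataset`.
#' @return a `ParallelDataset` with permuted values.
#' @export
permute_dataset <- function(dataset) {
  shuffle_rows <- function(m, type) {
    v <- unclass(m)
    for (i in seq_len(nrow(v))) v[i, ] <- v[i, sample.int(ncol(v))]
    expression_matrix(v, type)
  }
  dataset$mrna <- shuffle_rows(dataset$mrna, "gene")
  dataset$mirna <- shuffle_rows(dataset$mirna, "miRNA")
  dataset
}

#' Permutation false-discovery-rate of an edge-identification procedure
#'
#' The FDR of an identification procedure is estimated by running it on
#' feature-permuted copies of the expression data: every edge found on
#' permuted data is a false positive by construction. Per repeat,
#' FDR = (mean discovery count over `n_perm` permutations) / (discovery
#' count on the real data); the mean and variance over `n_repeat` repeats
#' are reported. Any procedure mapping a dataset to an edge set can be
#' plugged in, so selection depths (or external methods) can be compared.
#'
#' @param identify function(dataset) returning an edge data frame.
#' @param dataset the real `ParallelDataset`.
#' @param n_perm permutations per repeat (default 100).
#' @param n_repeat independent repeats (default 3).
#' @param seed optional RNG seed.
#' @return list of class `FDRReport`: `fdr_mean`, `fdr_variance`,
#'   `n_permutations`, `n_repeats`, `per_repeat_fdr`, `n_real_discoveries`.
#' @export
estimate_fdr <- function(identify, dataset, n_perm = 100L, n_repeat = 3L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_real <- nrow(identify(dataset))
  if (n_real == 0) stop("undefined FDR: no discoveries on the real data")
  per_repeat <- vapply(seq_len(n_repeat), function(r) {
    counts <- vapply(seq_len(n_perm),
                     function(p) nrow(identify(permute_dataset(dataset))),
                     numeric(1))
    mean(counts) / n_real
  }, numeric(1))
  structure(list(fdr_mean = mean(per_repeat),
                 fdr_variance = if (n_repeat > 1) stats::var(per_repeat) else 0,
                 n_permutations = as.integer(n_perm),
                 n_repeats = as.integer(n_repeat),
                 per_repeat_fdr = per_repeat,
                 n_real_discoveries = n_real),
            class = "FDRReport")
}

#' Count identified edges by interaction type
#'
#' @param edges typed edge data frame.
#' @return named integer vector over `TF_gene`, `TF_miRNA`, `miRNA_gene`.
#' @export
edge_type_counts <- function(edges) {
  key <- paste(edges$regulator_type, edges$target_type, sep = "_")
  vapply(c("TF_gene", "TF_miRNA", "miRNA_gene"),
         function(k) sum(key == k), integer(1))
}

#' Random-interaction null test for feed-forward loop counts
#'
#' Tests whether the observed loop counts could arise from randomly chosen
#' prior interactions: each draw samples, uniformly without replacement and
#' per interaction type, the same number of edges as were identified, and
#' the loops in the sampled edge set are counted. Two p-values are
#' reported per loop class. `t_pvalue` is the one-sample t-test of the
#' null draws against the observed count, one-sided (alternative: null
#' mean below the observed count) — the conventional motif-enrichment
#' t-test. Note it only tests whether the *null mean* lies below the
#' observed value, so when the observed count is itself a typical null
#' draw it still rejects about half the time (whenever the count lands
#' above the null mean); `empirical_pvalue`
#' = (1 + #draws >= observed) / (n_draws + 1) is the calibrated
#' alternative and is the one to use when a valid test of "the observed
#' count is typical of random selection" is needed.
#'
#' @param observed named count vector per FFL class (see [count_ffls()]).
#' @param priors the full [prior_catalog()] to draw from.
#' @param identified_sizes named counts per edge type (see
#'   [edge_type_counts()]).
#' @param tf_roster TF gene ids.
#' @param n_draws number of null draws (default 1000).
#' @param seed optional RNG seed.
#' @return list of class `NullFFLReport`: `observed`, `null_mean`,
#'   `null_sd`, `t_pvalue`, `empirical_pvalue` (per class), `n_draws`,
#'   `null_counts` (draws x
#'   class matrix).
#' @export
null_ffl_test <- function(observed, priors, identified_sizes, tf_roster,
                          n_draws = 1000L, seed = NULL) {
  if (n_draws < 2) stop("n_draws must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  pool_counts <- edge_type_counts(priors)
  identified_sizes <- identified_sizes[names(pool_counts)]
  identified_sizes[is.na(identified_sizes)] <- 0L
  if (any(identified_sizes > pool_counts))
    stop("identified edge counts exceed the prior pool for: ",
         paste(names(pool_counts)[identified_sizes > pool_counts],
               collapse = ", "))
  type_key <- paste(priors$regulator_type, priors$target_type, sep = "_")
  idx_by_type <- split(seq_len(nrow(priors)), type_key)
  draws <- matrix(0L, n_draws, length(FFL_CLASSES),
                  dimnames = list(NULL, FFL_CLASSES))
  for (d in seq_len(n_draws)) {
    take <- unlist(lapply(names(idx_by_type), function(k) {
      m <- identified_sizes[[k]]
      if (is.null(m) || is.na(m) || m == 0) return(integer(0))
      sample(idx_by_type[[k]], m)
    }))
    draws[d, ] <- count_ffls(enumerate_ffls(priors[take, , drop = FALSE],
                                            tf_roster))
  }
  pvals <- vapply(FFL_CLASSES, function(cl) {
    x <- draws[, cl]
    if (stats::sd(x) == 0) {
      if (mean(x) < observed[[cl]]) 0 else if (mean(x) > observed[[cl]]) 1 else 0.5
    } else {
      stats::t.test(x, mu = observed[[cl]], alternative = "less")$p.value
    }
  }, numeric(1))
  structure(list(observed = observed[FFL_CLASSES],
                 null_mean = colMeans(draws),
                 null_sd = apply(draws, 2, stats::sd),
                 t_pvalue = pvals,
                 empirical_pvalue = vapply(FFL_CLASSES, function(cl)
                   (1 + sum(draws[, cl] >= observed[[cl]])) / (n_draws + 1),
                   numeric(1)),
                 n_draws = as.integer(n_draws),
                 null_counts = draws),
            class = "NullFFLReport")
}

#' Correlation shift between candidate and selected regulator-target pairs
#'
#' Computes the absolute Pearson correlation for every regulator-target
#' pair before and after selection and tests, with a one-sided two-sample
#' Mann-Whitney U-test, whether the selected pairs have higher |PCC|.
#' Magnitudes are used because miRNA regulation is repressive: a strong
#' negative correlation is as supportive as a strong positive one.
#'
#' @param pairs_before,pairs_after lists of 2-element lists/vectors
#'   `(regulator profile, target profile)`.
#' @return list: `pcc_before`, `pcc_after` (absolute correlations) and
#'   `u_pvalue` (alternative: after > before).
#' @export
pcc_shift_test <- function(pairs_before, pairs_after) {
  abs_pcc <- function(pairs) {
    if (length(pairs) == 0) stop("empty pair list")
    vapply(pairs, function(p) {
      r <- p[[1]]; t <- p[[2]]
      if (length(r) != length(t) || length(r) < 3)
        stop("pair profiles must have equal length >= 3")
      if (stats::sd(r) == 0 || stats::sd(t) == 0) {
        warning("constant profile in a pair; PCC set to 0")
        return(0)
      }
      abs(stats::cor(r, t))
    }, numeric(1))
  }
  before <- abs_pcc(pairs_before)
  after <- abs_pcc(pairs_after)
  u <- stats::wilcox.test(after, before, alternative = "greater",
                          exact = FALSE)
  list(pcc_before = before, pcc_after = after, u_pvalue = u$p.value)
}

#' Enrichment of known interactions among selected edges
#'
#' One-sided hypergeometric test of whether the selected edge set is
#' enriched for experimentally validated interactions relative to the
#' candidate universe.
#'
#' @param selected,known,universe typed edge data frames; `selected` must be
#'   a subset of `universe`.
#' @return list: `fraction_selected`, `fraction_universe`, `overlap`,
#'   `hyper_pvalue`.
#' @export
known_interaction_enrichment <- function(selected, known, universe) {
  if (nrow(selected) == 0) stop("empty selected edge set")
  sel_k <- unique(edge_pair_key(selected))
  uni_k <- unique(edge_pair_key(universe))
  if (!all(sel_k %in% uni_k)) stop("selected edges must lie in the universe")
  known_k <- intersect(unique(edge_pair_key(known)), uni_k)
  overlap <- length(intersect(sel_k, known_k))
  N <- length(uni_k); K <- length(known_k); n <- length(sel_k)
  p <- stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  list(fraction_selected = overlap / n,
       fraction_universe = K / N,
       overlap = overlap,
       hyper_pvalue = p)
}

#' Pearson chi-square test on a 2x2 count table
#'
#' Compares two proportions `a_pos/a_tot` vs `b_pos/b_tot` with the Pearson
#' chi-square test on the 2x2 table, df = 1, without continuity correction.
#'
#' @param a_pos,a_tot,b_pos,b_tot non-negative counts with
#'   `a_pos <= a_tot`, `b_pos <= b_tot`.
#' @return list: `chi2`, `pvalue`.
#' @export
chi_square_2x2 <- function(a_pos, a_tot, b_pos, b_tot) {
  if (a_pos > a_tot || b_pos > b_tot || min(a_pos, b_pos) < 0)
    stop("invalid counts")
  tab <- matrix(c(a_pos, a_tot - a_pos, b_pos, b_tot - b_pos),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), pvalue = res$p.value)
}
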