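#' Simulation configuration for planted regulatory data
#'
#' Defines the study conditions emulated by the generator: sample count at
#' microarray-panel scale, a planted set of feed-forward loops whose edges
#' follow the linear regulatory model (targets are linear combinations of
#' their regulators plus Gaussian noise), and a prior catalog diluted with
#' decoy edges carrying no signal.
#'
#' @param n_samples number of samples (default 60, a cell-line-panel scale).
#' @param n_tfs,n_mirnas,n_genes feature-space sizes (TFs are genes and
#'   live in the mRNA matrix alongside the `n_genes` non-TF genes).
#' @param n_tf_ffls,n_mirna_ffls,n_composite_ffls planted loops per class.
#' @param effect_size_range range of |beta| for true edges.
#' @param mirna_sign sign of miRNA regulatory effects (default -1,
#'   repression).
#' @param noise_sd residual noise standard deviation (default 0.5).
#' @param decoy_edges_per_true decoy prior edges per true edge (default 4).
#' @param class_shift mean shift added to planted features in the first
#'   class when `class_sizes` is given (0 = unlabeled data).
#' @param class_sizes optional named vector of per-class sample counts
#'   summing to `n_samples`.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_samples = 60L, n_tfs = 10L, n_mirnas = 12L,
                       n_genes = 30L, n_tf_ffls = 4L, n_mirna_ffls = 4L,
                       n_composite_ffls = 2L,
                       effect_size_range = c(0.6, 1.2), mirna_sign = -1,
                       noise_sd = 0.5, decoy_edges_per_true = 4,
                       class_shift = 0, class_sizes = NULL, seed = 1L) {
  n_ffls <- n_tf_ffls + n_mirna_ffls + n_composite_ffls
  if (min(n_samples, n_tfs, n_mirnas, n_genes) < 1)
    stop("all counts must be positive")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (decoy_edges_per_true < 0) stop("decoy ratio must be >= 0")
  if (n_ffls > min(n_tfs, n_mirnas, n_genes))
    stop("need at least one distinct TF, miRNA and gene per planted loop")
  if (!is.null(class_sizes)) {
    if (sum(class_sizes) != n_samples)
      stop("class_sizes must sum to n_samples")
    if (is.null(names(class_sizes))) stop("class_sizes must be named")
  }
  structure(list(n_samples = as.integer(n_samples), n_tfs = as.integer(n_tfs),
                 n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
                 n_tf_ffls = as.integer(n_tf_ffls),
                 n_mirna_ffls = as.integer(n_mirna_ffls),
                 n_composite_ffls = as.integer(n_composite_ffls),
                 effect_size_range = effect_size_range,
                 mirna_sign = mirna_sign, noise_sd = noise_sd,
                 decoy_edges_per_true = decoy_edges_per_true,
                 class_shift = class_shift, class_sizes = class_sizes,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Preset simulation configurations
#'
#' Two dataset-scale presets: `"pan_cancer_like"` is an unlabeled 60-sample
#' panel (cell-line scale); `"prostate_like"` is a labeled two-class cohort
#' of 139 samples split 111 cancer / 28 normal, with planted features
#' mean-shifted by one standard deviation in the cancer class.
#'
#' @param name `"pan_cancer_like"` or `"prostate_like"`.
#' @param seed RNG seed passed through.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("pan_cancer_like", "prostate_like"),
                       seed = 1L) {
  name <- match.arg(name)
  switch(name,
         pan_cancer_like = sim_config(seed = seed),
         prostate_like = sim_config(n_samples = 139L,
                                    class_sizes = c(cancer = 111L, normal = 28L),
                                    class_shift = 1.0, seed = seed))
}

new_edge <- function(rtype, rid, ttype, tid, beta, tag) {
  data.frame(regulator_type = rtype, regulator_id = rid, target_type = ttype,
             target_id = tid, beta = beta, source_tag = tag,
             stringsAsFactors = FALSE)
}

#' Simulate a parallel expression dataset with planted feed-forward loops
#'
#' Regulator root profiles are drawn i.i.d. standard normal; every
#' regulated feature is a linear combination of its regulators' profiles
#' plus `N(0, noise_sd^2)` noise. TF effects on motif targets are positive
#' and miRNA effects negative (repression). Each planted loop uses its own
#' (TF, miRNA, gene) triple; for composite loops the mutually regulating
#' TF/miRNA pair is generated acyclically (the miRNA as a noisy negative
#' function of the TF) and both directed edges are recorded as true. The
#' prior catalog is the union of the true edges and uniformly sampled
#' decoy edges with zero effect. With `class_sizes` set, planted features
#' receive a `class_shift` mean offset in the first class and sample labels
#' are returned.
#'
#' @param config a [sim_config()].
#' @return list: `dataset` (`ParallelDataset`), `priors`
#'   ([prior_catalog()]), `tf_roster`, `truth` (list with `true_edges`,
#'   `decoy_edges`, `planted_ffls`, `shifted_features`, `config`).
#' @export
simulate_regulatory_data <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_samples
  tf_ids <- sprintf("TF%02d", seq_len(config$n_tfs))
  mir_ids <- sprintf("hsa-mir-%03d", seq_len(config$n_mirnas))
  gene_ids <- sprintf("G%03d", seq_len(config$n_genes))
  samples <- sprintf("S%03d", seq_len(n))

  rnoise <- function() stats::rnorm(n, sd = config$noise_sd)
  rbeta_eff <- function() stats::runif(1, config$effect_size_range[1],
                                       config$effect_size_range[2])
  msign <- config$mirna_sign

  expr <- list()  # one profile per feature, filled motif by motif
  for (id in c(tf_ids, mir_ids, gene_ids)) expr[[id]] <- stats::rnorm(n)

  classes <- c(rep("TF_FFL", config$n_tf_ffls),
               rep("miRNA_FFL", config$n_mirna_ffls),
               rep("composite_FFL", config$n_composite_ffls))
  edges <- list()
  ffls <- empty_ffl_table()
  for (i in seq_along(classes)) {
    tf <- tf_ids[i]; m <- mir_ids[i]; g <- gene_ids[i]
    cl <- classes[i]
    b_tg <- rbeta_eff(); b_mg <- msign * rbeta_eff()
    if (cl == "TF_FFL") {
      b_tm <- rbeta_eff()
      expr[[m]] <- b_tm * expr[[tf]] + rnoise()
      edges[[length(edges) + 1]] <-
        new_edge("TF", tf, "miRNA", m, b_tm, "sim_true")
    } else if (cl == "miRNA_FFL") {
      b_mt <- msign * rbeta_eff()
      expr[[tf]] <- b_mt * expr[[m]] + rnoise()
      edges[[length(edges) + 1]] <-
        new_edge("miRNA", m, "gene", tf, b_mt, "sim_true")
    } else {
      # mutual pair generated acyclically; both directions recorded as true
      b_tm <- msign * rbeta_eff()
      expr[[m]] <- b_tm * expr[[tf]] + rnoise()
      edges[[length(edges) + 1]] <-
        new_edge("TF", tf, "miRNA", m, b_tm, "sim_true")
      edges[[length(edges) + 1]] <-
        new_edge("miRNA", m, "gene", tf, b_tm, "sim_true")
    }
    expr[[g]] <- b_tg * expr[[tf]] + b_mg * expr[[m]] + rnoise()
    edges[[length(edges) + 1]] <- new_edge("TF", tf, "gene", g, b_tg, "sim_true")
    edges[[length(edges) + 1]] <- new_edge("miRNA", m, "gene", g, b_mg, "sim_true")
    ffls <- rbind(ffls, data.frame(ffl_class = cl, tf_id = tf, mirna_id = m,
                                   target_gene_id = g, stringsAsFactors = FALSE))
  }
  true_edges <- do.call(rbind, edges)

  # decoy prior edges: uniformly sampled allowed pairs with no planted effect
  mrna_ids <- c(tf_ids, gene_ids)
  pool <- rbind(
    expand.grid(regulator_type = "TF", regulator_id = tf_ids,
                target_type = "gene", target_id = mrna_ids,
                stringsAsFactors = FALSE),
    expand.grid(regulator_type = "TF", regulator_id = tf_ids,
                target_type = "miRNA", target_id = mir_ids,
                stringsAsFactors = FALSE),
    expand.grid(regulator_type = "miRNA", regulator_id = mir_ids,
                target_type = "gene", target_id = mrna_ids,
                stringsAsFactors = FALSE))
  pool <- pool[pool$regulator_id != pool$target_id, , drop = FALSE]
  true_key <- paste(true_edges$regulator_id, true_edges$target_id, sep = "\r")
  pool <- pool[!(paste(pool$regulator_id, pool$target_id, sep = "\r")
                 %in% true_key), , drop = FALSE]
  n_decoy <- round(config$decoy_edges_per_true * nrow(true_edges))
  if (n_decoy > nrow(pool))
    stop("decoy pool exhausted: requested ", n_decoy, " of ", nrow(pool))
  decoys <- pool[sample(nrow(pool), n_decoy), , drop = FALSE]
  decoys$beta <- 0
  decoys$source_tag <- "sim_decoy"

  labels <- NULL
  shifted <- character(0)
  if (!is.null(config$class_sizes)) {
    labels <- stats::setNames(
      rep(names(config$class_sizes), times = config$class_sizes), samples)
    if (config$class_shift != 0) {
      shifted <- unique(c(ffls$tf_id, ffls$mirna_id, ffls$target_gene_id))
      in_first <- labels == names(config$class_sizes)[1]
      for (id in shifted) expr[[id]][in_first] <- expr[[id]][in_first] +
          config$class_shift
    }
  }

  mk <- function(ids, type) {
    m <- do.call(rbind, expr[ids])
    dimnames(m) <- list(ids, samples)
    expression_matrix(m, type)
  }
  dataset <- align_parallel(mk(mrna_ids, "gene"), mk(mir_ids, "miRNA"),
                            labels = labels)
  priors <- prior_catalog(rbind(true_edges[, c(1, 2, 3, 4, 6)],
                                decoys[, c(1, 2, 3, 4, 6)]))
  list(dataset = dataset,
       priors = priors,
       tf_roster = tf_ids,
       truth = list(true_edges = true_edges, decoy_edges = decoys,
                    planted_ffls = sort_ffls(ffls), shifted_features = shifted,
                    config = config))
}
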