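#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline. The numeric defaults
#' are the method's operating constants: wrapper acceptance alpha = 0.01,
#' mRMR cap of 20 candidates, 100 expression permutations for the FDR, and
#' 1000 random-interaction draws for the loop null.
#'
#' @param out_dir run directory for all artifacts.
#' @param preset simulation preset used when no input paths are given.
#' @param mrna_path,mirna_path,priors_path,labels_path,tf_roster_path
#'   optional input files (TSV; roster = one TF id per line). When all of
#'   `mrna_path`, `mirna_path`, `priors_path` and `tf_roster_path` are set
#'   the pipeline runs on them instead of simulating.
#' @param alpha wrapper F-test threshold.
#' @param max_candidates mRMR cap.
#' @param mi_scheme,mi_bins,sd_factor discretization scheme parameters.
#' @param n_perm expression permutations per FDR repeat.
#' @param n_fdr_repeats FDR repeats.
#' @param n_null_draws random-interaction draws for the loop null.
#' @param svm_kernel,svm_cost SVM parameters.
#' @param n_class_perm label permutations for the classification baseline.
#' @param seed master RNG seed.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir = "ffloops_run",
                            preset = "pan_cancer_like",
                            mrna_path = NULL, mirna_path = NULL,
                            priors_path = NULL, labels_path = NULL,
                            tf_roster_path = NULL,
                            alpha = 0.01, max_candidates = 20L,
                            mi_scheme = "mean_sd_3state", mi_bins = 3L,
                            sd_factor = 0.5,
                            n_perm = 100L, n_fdr_repeats = 3L,
                            n_null_draws = 1000L,
                            svm_kernel = "linear", svm_cost = 1,
                            n_class_perm = 100L, seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirror the arguments of [pipeline_config()]. Entries in
#' `overrides` (e.g. parsed command-line flags) take precedence over the
#' file, which takes precedence over the defaults.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param overrides named list of overriding values.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Orchestrates simulate/load -> edge selection -> loop enumeration ->
#' statistical validation -> classification (when labels exist) -> network
#' analysis, writing all artifacts plus a machine-readable `summary.json`
#' into the run directory. Deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the summary list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (p in c(config$mrna_path, config$mirna_path, config$priors_path,
              config$labels_path, config$tf_roster_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  set.seed(config$seed)
  scheme <- disc_scheme(config$mi_scheme, n_bins = config$mi_bins,
                        sd_factor = config$sd_factor)
  summary <- list(seed = config$seed, stages = character(0))
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }

  use_files <- !is.null(config$mrna_path) && !is.null(config$mirna_path) &&
    !is.null(config$priors_path) && !is.null(config$tf_roster_path)
  truth <- NULL
  run_stage("data", {
    if (use_files) {
      logf("loading input files")
      tf_roster <- readLines(config$tf_roster_path)
      priors <- load_prior_catalog(config$priors_path, tf_roster)
      labels <- if (is.null(config$labels_path)) NULL
                else load_labels(config$labels_path)
      dataset <- align_parallel(load_expression(config$mrna_path, "gene"),
                                load_expression(config$mirna_path, "miRNA"),
                                labels = labels)
    } else {
      logf("simulating dataset (preset ", config$preset, ")")
      sim <- simulate_regulatory_data(sim_preset(config$preset,
                                                 seed = config$seed))
      dataset <- sim$dataset; priors <- sim$priors
      tf_roster <- sim$tf_roster; truth <- sim$truth
      write_edges(truth$true_edges,
                  file.path(config$out_dir, "true_edges.tsv"))
    }
    dataset; priors; tf_roster
  })
  summary$stages <- c(summary$stages, "data")
  summary$n_samples <- ncol(dataset$mrna)

  run_stage("select", {
    logf("selecting regulators (filter + wrapper)")
    edges <- identify_edges(dataset, priors, scheme = scheme,
                            alpha = config$alpha,
                            max_candidates = config$max_candidates)
    write_edges(edges, file.path(config$out_dir, "identified_edges.tsv"))
  })
  summary$stages <- c(summary$stages, "select")
  summary$n_identified_edges <- nrow(edges)
  summary$edge_type_counts <- as.list(edge_type_counts(edges))

  run_stage("ffl", {
    logf("enumerating feed-forward loops")
    ffls <- enumerate_ffls(edges, tf_roster)
    write_ffls(ffls, file.path(config$out_dir, "ffls.tsv"))
  })
  summary$stages <- c(summary$stages, "ffl")
  summary$ffl_counts <- as.list(count_ffls(ffls))

  run_stage("validate", {
    logf("validating (FDR + loop null + PCC shift)")
    identify_fun <- function(ds)
      identify_edges(ds, priors, scheme = scheme, alpha = config$alpha,
                     max_candidates = config$max_candidates)
    fdr <- if (nrow(edges) > 0)
      estimate_fdr(identify_fun, dataset, n_perm = config$n_perm,
                   n_repeat = config$n_fdr_repeats) else NULL
    nulltest <- if (nrow(ffls) > 0)
      null_ffl_test(count_ffls(ffls), priors, edge_type_counts(edges),
                    tf_roster, n_draws = config$n_null_draws) else NULL
    pair_list <- function(e) lapply(seq_len(nrow(e)), function(i)
      list(feature_profile(dataset, e$regulator_id[i]),
           feature_profile(dataset, e$target_id[i])))
    measured <- priors[vapply(seq_len(nrow(priors)), function(i)
      !is.null(feature_profile(dataset, priors$regulator_id[i])) &&
      !is.null(feature_profile(dataset, priors$target_id[i])),
      logical(1)), , drop = FALSE]
    pcc <- if (nrow(edges) > 0)
      pcc_shift_test(pair_list(measured), pair_list(edges)) else NULL
  })
  summary$stages <- c(summary$stages, "validate")
  if (!is.null(fdr)) {
    summary$fdr_mean <- fdr$fdr_mean
    summary$fdr_variance <- fdr$fdr_variance
  }
  if (!is.null(nulltest)) {
    summary$null_ffl_mean <- as.list(nulltest$null_mean)
    summary$null_ffl_pvalue <- as.list(nulltest$t_pvalue)
  }
  if (!is.null(pcc)) summary$pcc_u_pvalue <- pcc$u_pvalue

  if (!is.null(dataset$labels)) {
    run_stage("classify", {
      logf("classifying samples from loop features (LOOCV SVM)")
      feats <- unique(c(ffls$tf_id, ffls$mirna_id, ffls$target_gene_id))
      if (length(feats) == 0) feats <- rownames(dataset$mrna)
      cls <- loocv_svm(dataset, feats, kernel = config$svm_kernel,
                       cost = config$svm_cost)
      base <- permutation_baseline(dataset, feats,
                                   n_perm = config$n_class_perm,
                                   kernel = config$svm_kernel,
                                   cost = config$svm_cost)
      utils::write.table(cls$roc$points,
                         file.path(config$out_dir, "roc_points.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    summary$stages <- c(summary$stages, "classify")
    summary$classification <- list(acc = cls$acc, sn = cls$sn, sp = cls$sp,
                                   mcc = cls$mcc, auc = cls$roc$auc)
    summary$baseline <- list(acc = base$acc, mcc = base$mcc)
  }

  run_stage("network", {
    logf("building co-regulatory network")
    net <- build_network(ffls)
    if (igraph::vcount(net) > 0) {
      dh <- degree_and_hub(net)
      expo <- tryCatch(powerlaw_exponent(dh$degree), error = function(e) NA_real_)
      export_sif(net, file.path(config$out_dir, "network.sif"))
      export_graphml(net, file.path(config$out_dir, "network.graphml"))
      occ <- occurrence_ranking(list(run = ffls))
      utils::write.table(occ, file.path(config$out_dir, "occurrence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      dh <- NULL; expo <- NA_real_
    }
  })
  summary$stages <- c(summary$stages, "network")
  if (!is.null(dh)) {
    summary$network <- list(n_nodes = igraph::vcount(net),
                            n_edges = igraph::ecount(net),
                            hub = dh$hub, hub_degree = max(dh$degree),
                            powerlaw_exponent = expo)
  }
  if (!is.null(truth)) {
    true_key <- paste(truth$true_edges$regulator_id,
                      truth$true_edges$target_id)
    found_key <- paste(edges$regulator_id, edges$target_id)
    tp <- length(intersect(found_key, true_key))
    prec <- if (length(found_key) > 0) tp / length(found_key) else 0
    rec <- tp / length(true_key)
    summary$edge_recovery <- list(
      precision = prec, recall = rec,
      f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done; summary written to ", file.path(config$out_dir, "summary.json"))
  invisible(summary)
}
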