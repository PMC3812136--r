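zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

as_regulator_matrix <- function(regulators) {
  if (is.matrix(regulators)) {
    if (is.null(rownames(regulators))) stop("regulator matrix needs rownames")
    regulators <- stats::setNames(
      lapply(seq_len(nrow(regulators)), function(i) regulators[i, ]),
      rownames(regulators))
  }
  if (length(regulators) == 0) stop("need at least one regulator")
  ids <- names(regulators)
  if (is.null(ids) || any(ids == "")) stop("regulators must be named")
  n <- unique(vapply(regulators, length, integer(1)))
  if (length(n) != 1) stop("regulator profiles differ in length")
  X <- do.call(cbind, regulators)
  colnames(X) <- ids
  X
}

#' Ordinary least-squares fit of a target on its candidate regulators
#'
#' Models a target's expression as a linear combination of its regulators'
#' expression plus Gaussian noise. Target and regulators are z-score
#' standardized before fitting, so coefficients are comparable across
#' regulators regardless of measurement scale. Model quality is summarized
#' by the overall F-test against the intercept-only model.
#'
#' @param target numeric vector of target expression over samples.
#' @param regulators named list of regulator profiles (or matrix with
#'   regulators in rows) over the same samples.
#' @param target_id optional id recorded in the result.
#' @return list of class `RegressionFit` with elements `target_id`,
#'   `regulator_ids`, `beta` (standardized coefficients), `intercept`,
#'   `residual_variance`, `f_statistic`, `f_pvalue`, `n_samples`,
#'   `df_model`, `df_resid`.
#' @export
fit_linear <- function(target, regulators, target_id = NA_character_) {
  X <- as_regulator_matrix(regulators)
  n <- length(target)
  if (nrow(X) != n) stop("target and regulators differ in length")
  if (ncol(X) >= n - 1)
    stop("too many regulators (", ncol(X), ") for ", n,
         " samples; at most n - 2 are identifiable")
  Xs <- apply(X, 2, zscore)
  dup <- duplicated(asplit(Xs, 2))
  if (any(dup)) {
    warning("dropping exactly collinear duplicate regulator(s): ",
            paste(colnames(Xs)[dup], collapse = ", "))
    Xs <- Xs[, !dup, drop = FALSE]
  }
  y <- zscore(target)
  p <- ncol(Xs)
  qr_fit <- qr(cbind(`(Intercept)` = 1, Xs))
  coefs <- qr.coef(qr_fit, y)
  beta <- coefs[-1]
  beta[is.na(beta)] <- 0  # aliased columns contribute nothing
  fitted <- qr.fitted(qr_fit, y)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  rank_model <- qr_fit$rank - 1L
  df_resid <- n - rank_model - 1L
  if (df_resid < 1) stop("no residual degrees of freedom")
  if (tss == 0) {
    fstat <- 0
    pval <- 1
  } else {
    ess <- tss - rss
    fstat <- (ess / rank_model) / max(rss / df_resid, .Machine$double.xmin)
    pval <- stats::pf(fstat, rank_model, df_resid, lower.tail = FALSE)
  }
  structure(list(target_id = target_id,
                 regulator_ids = colnames(Xs),
                 beta = unname(beta),
                 intercept = unname(coefs[1]),
                 residual_variance = rss / df_resid,
                 f_statistic = fstat,
                 f_pvalue = pval,
                 n_samples = n,
                 df_model = rank_model,
                 df_resid = df_resid),
            class = "RegressionFit")
}

#' Backward elimination over linear-regression F-tests
#'
#' Recursive backward elimination: starting from all candidate regulators,
#' the model is refit and the regulator with the smallest absolute
#' standardized coefficient is deleted, down to the single-regulator model.
#' Every evaluated subset is recorded with its overall F-test p-value; the
#' optimal subset is the one with the smallest p-value (ties favour the
#' larger, earlier set) and it is accepted only if that p-value is below
#' `alpha`.
#'
#' @param target numeric target profile.
#' @param regulators named list (or row-named matrix) of regulator profiles.
#' @param alpha acceptance threshold on the optimal model's F-test p-value
#'   (default 0.01).
#' @param target_id optional id carried through.
#' @return list of class `EliminationPath` with `steps` (data frame: `size`,
#'   `f_pvalue`, `eliminated_regulator`), `regulator_sets` (list of ids per
#'   step), `fits` (the per-step `RegressionFit`s), `optimal_step_index`,
#'   `accepted`, `selected` (ids of the accepted optimal set, empty when
#'   rejected).
#' @export
backward_eliminate <- function(target, regulators, alpha = 0.01,
                               target_id = NA_character_) {
  X <- as_regulator_matrix(regulators)
  dup <- duplicated(asplit(apply(X, 2, zscore), 2))
  if (any(dup)) {
    warning("dropping duplicate regulator(s) before elimination: ",
            paste(colnames(X)[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
  }
  current <- sort(colnames(X))
  sets <- list()
  fits <- list()
  eliminated <- character(0)
  pvals <- numeric(0)
  while (length(current) > 0) {
    fit <- fit_linear(target, t(X[, current, drop = FALSE]),
                      target_id = target_id)
    sets[[length(sets) + 1L]] <- current
    fits[[length(fits) + 1L]] <- fit
    pvals <- c(pvals, fit$f_pvalue)
    absb <- abs(fit$beta)
    # smallest |standardized beta| leaves; ties -> lexicographically first id
    drop_id <- sort(fit$regulator_ids[absb == min(absb)])[1]
    eliminated <- c(eliminated, drop_id)
    current <- setdiff(current, drop_id)
  }
  optimal <- which.min(pvals)  # first minimum = largest set on ties
  accepted <- pvals[optimal] < alpha
  structure(list(
    steps = data.frame(size = lengths(sets),
                       f_pvalue = pvals,
                       eliminated_regulator = eliminated,
                       stringsAsFactors = FALSE),
    regulator_sets = sets,
    fits = fits,
    optimal_step_index = optimal,
    accepted = accepted,
    selected = if (accepted) sets[[optimal]] else character(0),
    target_id = target_id,
    alpha = alpha), class = "EliminationPath")
}

empty_identified_edges <- function(reason = NA_character_) {
  out <- data.frame(regulator_type = character(0), regulator_id = character(0),
                    target_type = character(0), target_id = character(0),
                    source_tag = character(0), beta = numeric(0),
                    f_pvalue = numeric(0), stringsAsFactors = FALSE)
  attr(out, "reason") <- reason
  out
}

#' Filter-wrapper regulator selection for one target
#'
#' Composes the mRMR filter ([rank_mrmr()], keeping up to `max_candidates`
#' regulators) with the backward-elimination wrapper
#' ([backward_eliminate()]). Candidate regulators come from the prior
#' catalog; regulators without an expression profile are excluded and
#' counted. The accepted optimal regulator set is returned as typed edges
#' annotated with the standardized coefficient and the accepted model's
#' F-test p-value.
#'
#' @param target_id feature id of the target (gene or miRNA).
#' @param dataset a [align_parallel()] `ParallelDataset`.
#' @param priors a [prior_catalog()].
#' @param scheme a [disc_scheme()].
#' @param alpha wrapper acceptance threshold (default 0.01).
#' @param max_candidates mRMR cap (default 20).
#' @return data frame of identified edges (possibly empty); attributes
#'   `reason` (`"target_not_measured"`, `"no_candidates"`, `"rejected"` or
#'   `NA`), `n_unmeasured` and `path` (the `EliminationPath`).
#' @export
select_regulators_for_target <- function(target_id, dataset, priors,
                                         scheme = disc_scheme(),
                                         alpha = 0.01, max_candidates = 20L) {
  ty <- feature_profile(dataset, target_id)
  if (is.null(ty)) return(empty_identified_edges("target_not_measured"))
  cand <- priors[priors$target_id == target_id, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_identified_edges("no_candidates"))
  profiles <- lapply(cand$regulator_id, feature_profile, dataset = dataset)
  names(profiles) <- cand$regulator_id
  measured <- !vapply(profiles, is.null, logical(1))
  n_unmeasured <- sum(!measured)
  profiles <- profiles[measured]
  cand <- cand[measured, , drop = FALSE]
  if (length(profiles) == 0) {
    out <- empty_identified_edges("no_candidates")
    attr(out, "n_unmeasured") <- n_unmeasured
    return(out)
  }
  ranking <- rank_mrmr(ty, profiles, scheme = scheme, max_keep = max_candidates)
  keep <- ranking$regulator_id
  # OLS identifiability: never hand the wrapper >= n - 2 regressors
  n <- length(ty)
  if (length(keep) > n - 3) keep <- keep[seq_len(n - 3)]
  path <- backward_eliminate(ty, profiles[keep], alpha = alpha,
                             target_id = target_id)
  if (!path$accepted) {
    out <- empty_identified_edges("rejected")
    attr(out, "n_unmeasured") <- n_unmeasured
    attr(out, "path") <- path
    return(out)
  }
  fit <- path$fits[[path$optimal_step_index]]
  sel <- cand[match(fit$regulator_ids, cand$regulator_id), , drop = FALSE]
  out <- data.frame(sel[, c("regulator_type", "regulator_id", "target_type",
                            "target_id", "source_tag")],
                    beta = fit$beta, f_pvalue = fit$f_pvalue,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reason") <- NA_character_
  attr(out, "n_unmeasured") <- n_unmeasured
  attr(out, "path") <- path
  out
}

#' Identify supported regulatory edges for every target in the prior catalog
#'
#' Runs regulator selection for each distinct target in the catalog and
#' concatenates the surviving edges. `method` controls how much selection is
#' applied: the full filter + wrapper (default), the mRMR filter alone
#' (every retained candidate becomes an edge, no model test), or no
#' selection at all (every measured prior edge is kept) — the latter two
#' exist for false-discovery-rate comparisons between selection depths.
#'
#' @param dataset a `ParallelDataset`.
#' @param priors a [prior_catalog()].
#' @param scheme a [disc_scheme()].
#' @param alpha wrapper threshold.
#' @param max_candidates mRMR cap.
#' @param method `"filter_wrapper"`, `"filter_only"` or `"none"`.
#' @param targets optional character vector restricting the targets scanned.
#' @return data frame of class `IdentifiedEdgeSet` (columns as in the prior
#'   catalog plus `beta`, `f_pvalue`; both `NA` for non-wrapper methods).
#' @export
identify_edges <- function(dataset, priors, scheme = disc_scheme(),
                           alpha = 0.01, max_candidates = 20L,
                           method = c("filter_wrapper", "filter_only", "none"),
                           targets = NULL) {
  method <- match.arg(method)
  if (is.null(targets)) targets <- sort(unique(priors$target_id))
  res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tid <- targets[i]
    if (method == "filter_wrapper") {
      res[[i]] <- select_regulators_for_target(tid, dataset, priors,
                                               scheme = scheme, alpha = alpha,
                                               max_candidates = max_candidates)
    } else {
      ty <- feature_profile(dataset, tid)
      if (is.null(ty)) next
      cand <- priors[priors$target_id == tid, , drop = FALSE]
      profiles <- lapply(cand$regulator_id, feature_profile, dataset = dataset)
      names(profiles) <- cand$regulator_id
      cand <- cand[!vapply(profiles, is.null, logical(1)), , drop = FALSE]
      profiles <- profiles[cand$regulator_id]
      if (nrow(cand) == 0) next
      if (method == "filter_only") {
        ranking <- rank_mrmr(ty, profiles, scheme = scheme,
                             max_keep = max_candidates)
        cand <- cand[match(ranking$regulator_id, cand$regulator_id), ,
                     drop = FALSE]
      }
      res[[i]] <- data.frame(cand[, c("regulator_type", "regulator_id",
                                      "target_type", "target_id", "source_tag")],
                             beta = NA_real_, f_pvalue = NA_real_,
                             stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, c(list(empty_identified_edges()), res))
  rownames(out) <- NULL
  attr(out, "reason") <- NULL
  class(out) <- c("IdentifiedEdgeSet", "data.frame")
  out
}
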