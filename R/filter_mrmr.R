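#' Discretization scheme for expression profiles
#'
#' Mutual information is computed on discretized profiles. Two schemes are
#' supported:
#' \describe{
#'   \item{mean_sd_3state}{three states split at mean +/- `sd_factor` * sd:
#'     below -> 0, within -> 1, above -> 2. The customary choice in the mRMR
#'     literature for expression data, default `sd_factor = 0.5`.}
#'   \item{equal_frequency}{`n_bins` quantile bins; ties are resolved by
#'     stable rank order so bins stay (near-)equally populated.}
#' }
#'
#' @param method `"mean_sd_3state"` or `"equal_frequency"`.
#' @param n_bins integer >= 2, used by `equal_frequency`.
#' @param sd_factor positive real, used by `mean_sd_3state`.
#' @return list of class `DiscretizationScheme`.
#' @export
disc_scheme <- function(method = c("mean_sd_3state", "equal_frequency"),
                        n_bins = 3L, sd_factor = 0.5) {
  method <- match.arg(method)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (sd_factor <= 0) stop("sd_factor must be > 0")
  structure(list(method = method, n_bins = as.integer(n_bins),
                 sd_factor = sd_factor),
            class = "DiscretizationScheme")
}

#' Discretize a numeric vector
#'
#' @param values numeric vector, length >= 2.
#' @param scheme a [disc_scheme()].
#' @return integer state vector of the same length (states start at 0).
#' @export
discretize <- function(values, scheme = disc_scheme()) {
  if (length(values) < 2) stop("need at least 2 values")
  if (scheme$method == "mean_sd_3state") {
    mu <- mean(values)
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) return(rep(1L, length(values)))
    lo <- mu - scheme$sd_factor * s
    hi <- mu + scheme$sd_factor * s
    as.integer((values >= lo) + (values > hi))
  } else {
    n <- length(values)
    r <- rank(values, ties.method = "first")
    as.integer(floor((r - 1) * scheme$n_bins / n))
  }
}

#' Mutual information of two discrete vectors, in bits
#'
#' Plug-in estimate over the observed joint frequencies:
#' \deqn{I(x;y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}}
#' with the convention 0 log 0 = 0. Small negative rounding residue is
#' clipped to 0.
#'
#' @param x,y integer state vectors of equal length >= 2.
#' @return mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (length(x) < 2) stop("need at least 2 observations")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  expected <- outer(px, py)
  nz <- joint > 0
  max(0, sum(joint[nz] * log2(joint[nz] / expected[nz])))
}

# empirical entropy in bits (used by tests and sanity checks)
#' Empirical Shannon entropy of a discrete vector, in bits
#' @param x state vector.
#' @return entropy in bits.
#' @export
entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank a target's candidate regulators by the mRMR criterion
#'
#' Greedy minimum-redundancy maximum-relevance selection. The first pick
#' maximizes mutual information with the target (relevance); every later
#' pick maximizes the difference form
#' `I(candidate; target) - mean_{s in S} I(candidate; s)` where `S` is the
#' already-selected set. Selection stops at `min(max_keep, #candidates)`.
#' Ties are broken by lexicographic regulator id for reproducibility.
#'
#' @param target_profile numeric expression profile of the target.
#' @param candidate_profiles named list (or row-named matrix) of candidate
#'   regulator profiles over the same samples.
#' @param scheme a [disc_scheme()] applied per profile before MI estimation.
#' @param max_keep maximum size of the selected set (default 20, the cap
#'   used when pruning predicted regulator lists).
#' @return data frame of class `CandidateRanking` with columns
#'   `regulator_id`, `relevance_mi`, `mrmr_score` in selection order;
#'   `attr(x, "target_relevance")` holds relevance for all candidates.
#' @export
rank_mrmr <- function(target_profile, candidate_profiles,
                      scheme = disc_scheme(), max_keep = 20L) {
  if (is.matrix(candidate_profiles))
    candidate_profiles <- stats::setNames(
      lapply(seq_len(nrow(candidate_profiles)),
             function(i) candidate_profiles[i, ]),
      rownames(candidate_profiles))
  if (length(candidate_profiles) == 0) stop("no candidate regulators")
  ids <- names(candidate_profiles)
  if (is.null(ids) || any(ids == "")) stop("candidates must be named")
  ids_order <- order(ids)  # lexicographic scan order makes ties deterministic
  ids <- ids[ids_order]
  candidate_profiles <- candidate_profiles[ids_order]

  dt <- discretize(target_profile, scheme)
  dc <- lapply(candidate_profiles, discretize, scheme = scheme)
  relevance <- vapply(dc, mutual_information, numeric(1), y = dt)

  k <- min(max_keep, length(ids))
  selected <- integer(0)
  remaining <- seq_along(ids)
  red_sum <- numeric(length(ids))  # sum of MI with already-selected set
  score <- numeric(k)
  for (step in seq_len(k)) {
    obj <- if (step == 1) relevance[remaining]
           else relevance[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(obj)]  # first max = lexicographically least id
    score[step] <- max(obj)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0)
      red_sum[remaining] <- red_sum[remaining] +
        vapply(dc[remaining], mutual_information, numeric(1), y = dc[[pick]])
  }
  out <- data.frame(regulator_id = ids[selected],
                    relevance_mi = unname(relevance[selected]),
                    mrmr_score = score,
                    stringsAsFactors = FALSE)
  attr(out, "target_relevance") <- relevance
  class(out) <- c("CandidateRanking", "data.frame")
  out
}
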