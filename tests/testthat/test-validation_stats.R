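test_that("permutation FDR hits its closed-form extremes", {
  sim <- simulate_regulatory_data(sim_config(seed = 30))
  ds <- sim$dataset
  real_mrna <- unclass(ds$mrna)
  one_edge <- data.frame(regulator_id = "a", target_id = "b")

  # recognizes only the untouched data -> no permuted discoveries -> FDR 0
  only_real <- function(d)
    if (identical(unclass(d$mrna), real_mrna)) one_edge else one_edge[0, ]
  fdr0 <- estimate_fdr(only_real, ds, n_perm = 5, n_repeat = 2, seed = 1)
  expect_equal(fdr0$fdr_mean, 0)
  expect_equal(length(fdr0$per_repeat_fdr), 2L)

  # permutation-invariant procedure -> FDR exactly 1
  constant <- function(d) one_edge
  fdr1 <- estimate_fdr(constant, ds, n_perm = 5, n_repeat = 2, seed = 1)
  expect_equal(fdr1$fdr_mean, 1)
  expect_equal(fdr1$fdr_variance, 0)

  expect_error(estimate_fdr(function(d) one_edge[0, ], ds, n_perm = 2,
                            n_repeat = 1),
               "undefined FDR")
})

test_that("feature-wise permutation preserves marginals and destroys covariation", {
  sim <- simulate_regulatory_data(sim_config(seed = 31))
  set.seed(9)
  perm <- permute_dataset(sim$dataset)
  expect_equal(sort(unname(unclass(perm$mrna)[1, ])),
               sort(unname(unclass(sim$dataset$mrna)[1, ])))
  # a TF-FFL miRNA is a direct noisy function of its TF: strongly correlated
  # on real data, decorrelated after feature-wise shuffling
  tf <- sim$truth$planted_ffls$tf_id[1]
  m <- sim$truth$planted_ffls$mirna_id[1]
  r_real <- abs(cor(unclass(sim$dataset$mrna)[tf, ],
                    unclass(sim$dataset$mirna)[m, ]))
  r_perm <- abs(cor(unclass(perm$mrna)[tf, ], unclass(perm$mirna)[m, ]))
  expect_gt(r_real, 0.6)
  expect_lt(r_perm, 0.5)
})

test_that("random-interaction null flags planted triangle concentration", {
  # priors: 6 complete TF-FFL triangles plus scattered non-loop edges
  tri <- do.call(rbind, lapply(1:6, function(i) data.frame(
    regulator_type = c("TF", "TF", "miRNA"),
    regulator_id = c(paste0("t", i), paste0("t", i), paste0("m", i)),
    target_type = c("miRNA", "gene", "gene"),
    target_id = c(paste0("m", i), paste0("g", i), paste0("g", i)),
    source_tag = "tri")))
  set.seed(11)
  scatter <- random_typed_edges(n_tf = 12, n_mir = 12, n_gene = 40,
                                p_edge = 0.04)$edges
  priors <- prior_catalog(rbind(tri, scatter))
  roster <- unique(c(paste0("t", 1:6), scatter$regulator_id[
    scatter$regulator_type == "TF"]))
  identified <- tri
  observed <- count_ffls(enumerate_ffls(identified, roster))
  expect_equal(unname(observed["TF_FFL"]), 6L)
  rep <- null_ffl_test(observed, priors, edge_type_counts(identified), roster,
                       n_draws = 200, seed = 5)
  expect_lt(rep$t_pvalue[["TF_FFL"]], 0.01)
  expect_lt(rep$empirical_pvalue[["TF_FFL"]], 0.01)
  expect_lt(rep$null_mean[["TF_FFL"]], observed[["TF_FFL"]])

  # observed at the null centre -> no rejection on either scale
  centred <- rep$null_mean
  centred[] <- round(centred)
  rep2 <- null_ffl_test(centred, priors, edge_type_counts(identified), roster,
                        n_draws = 200, seed = 6)
  expect_gt(rep2$t_pvalue[["TF_FFL"]], 0.1)
  expect_gt(rep2$empirical_pvalue[["TF_FFL"]], 0.2)

  expect_error(null_ffl_test(observed, priors, edge_type_counts(identified),
                             roster, n_draws = 1), "n_draws")
  too_many <- edge_type_counts(identified)
  too_many["TF_miRNA"] <- nrow(priors) + 1L
  expect_error(null_ffl_test(observed, priors, too_many, roster,
                             n_draws = 10), "exceed")
})

test_that("PCC shift test separates enriched from unchanged pair sets", {
  set.seed(12)
  noise_pairs <- lapply(1:50, function(i) list(rnorm(30), rnorm(30)))
  same <- pcc_shift_test(noise_pairs, noise_pairs)
  expect_gt(same$u_pvalue, 0.3)

  good_pairs <- lapply(1:50, function(i) {
    r <- rnorm(30); list(r, r * 2 + 1)
  })
  shift <- pcc_shift_test(noise_pairs, good_pairs)
  expect_lt(shift$u_pvalue, 1e-6)
  expect_true(all(shift$pcc_after > 0.99))

  expect_error(pcc_shift_test(list(), noise_pairs), "empty")
  expect_warning(flat <- pcc_shift_test(list(list(rep(1, 10), rnorm(10))),
                                        noise_pairs[1]),
                 "constant")
  expect_equal(flat$pcc_before, 0)
})

test_that("hypergeometric enrichment matches the tail-summation oracle", {
  mk_set <- function(ids) data.frame(regulator_id = "r", target_id = ids,
                                     stringsAsFactors = FALSE)
  universe <- mk_set(sprintf("e%03d", 1:100))
  known <- mk_set(sprintf("e%03d", 1:10))
  selected <- mk_set(sprintf("e%03d", c(1:5, 51:65)))  # 20 edges, overlap 5
  got <- known_interaction_enrichment(selected, known, universe)
  oracle_p <- sum(sapply(5:10, function(k)
    choose(10, k) * choose(90, 20 - k) / choose(100, 20)))
  expect_equal(got$hyper_pvalue, oracle_p, tolerance = 1e-12)
  expect_equal(got$fraction_selected, 5 / 20)
  expect_equal(got$fraction_universe, 10 / 100)

  all_known <- known_interaction_enrichment(selected, universe, universe)
  expect_equal(all_known$hyper_pvalue, 1)
  expect_equal(all_known$overlap, 20L)

  none <- known_interaction_enrichment(mk_set(sprintf("e%03d", 51:70)),
                                       known, universe)
  expect_gt(none$hyper_pvalue, 0.85)
  expect_error(known_interaction_enrichment(selected[0, ], known, universe),
               "empty")
})

test_that("2x2 chi-square has no continuity correction and sane edge cases", {
  same <- chi_square_2x2(10, 100, 10, 100)
  expect_equal(same$chi2, 0)
  expect_equal(same$pvalue, 1)
  expect_error(chi_square_2x2(0, 10, 0, 10), "margin")
  expect_error(chi_square_2x2(12, 10, 1, 10), "invalid")
})

test_that("chi-square p agrees with a Monte-Carlo margin-permutation oracle", {
  set.seed(13)
  tables <- list(c(30, 100, 15, 120), c(40, 90, 52, 95), c(25, 60, 12, 70))
  for (tb in tables) {
    got <- chi_square_2x2(tb[1], tb[2], tb[3], tb[4])
    obs <- matrix(c(tb[1], tb[2] - tb[1], tb[3], tb[4] - tb[3]), 2,
                  byrow = TRUE)
    stat <- function(m) {
      e <- outer(rowSums(m), colSums(m)) / sum(m)
      sum((m - e)^2 / e)
    }
    n_mc <- 50000
    sims <- vapply(r2dtable(n_mc, rowSums(obs), colSums(obs)), stat,
                   numeric(1))
    s0 <- stat(obs)
    # mid-p handles the point mass at the observed table, which a continuous
    # reference distribution splits in half
    p_mc <- mean(sims > s0 + 1e-9) + 0.5 * mean(abs(sims - s0) <= 1e-9)
    se <- sqrt(p_mc * (1 - p_mc) / n_mc)
    # 0.01 absolute allowance for the O(1/n) chi-square approximation error
    expect_lt(abs(got$pvalue - p_mc), 3 * se + 0.01)
  }
})
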