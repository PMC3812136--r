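test_that("a noiseless single regulator gives standardized beta 1 and tiny p", {
  set.seed(1)
  x <- rnorm(10)
  fit <- fit_linear(2 * x, list(x = x))
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  expect_lt(fit$f_pvalue, 1e-8)
})

test_that("coefficients and F statistic match the normal-equations oracle and lm", {
  set.seed(2)
  n <- 25
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 0.8 * X[, 1] - 1.1 * X[, 2] + rnorm(n, sd = 0.6)
  fit <- fit_linear(y, t(X))
  oracle <- ols_oracle(y, X)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-9)
  expect_equal(fit$f_statistic, oracle$f, tolerance = 1e-9)
  expect_equal(fit$f_pvalue, oracle$p, tolerance = 1e-9)
  # independent route: lm on the standardized variables
  zs <- function(v) (v - mean(v)) / sd(v)
  lm_fit <- lm(zs(y) ~ zs(X[, 1]) + zs(X[, 2]) + zs(X[, 3]))
  fstat <- summary(lm_fit)$fstatistic
  expect_equal(fit$f_pvalue,
               pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("the overall F-test is calibrated on independent noise", {
  rejections <- 0
  for (seed in 1:200) {
    set.seed(seed)
    fit <- fit_linear(rnorm(40), list(x = rnorm(40)))
    rejections <- rejections + (fit$f_pvalue < 0.05)
  }
  expect_equal(rejections / 200, 0.05, tolerance = 0.035)
})

test_that("duplicate collinear regulators are dropped with a warning", {
  set.seed(3)
  x <- rnorm(20)
  y <- x + rnorm(20, sd = 0.3)
  expect_warning(fit <- fit_linear(y, list(a = x, b = x, c = rnorm(20))),
                 "collinear")
  expect_setequal(fit$regulator_ids, c("a", "c"))
  expect_error(fit_linear(rnorm(5), setNames(lapply(1:5, function(i) rnorm(5)),
                                             letters[1:5])),
               "too many regulators")
})

test_that("backward elimination evaluates one shrinking model per regulator", {
  set.seed(4)
  n <- 30
  regs <- setNames(lapply(1:6, function(i) rnorm(n)), sprintf("r%d", 1:6))
  y <- 1.2 * regs$r1 - 0.9 * regs$r2 + rnorm(n, sd = 0.5)
  path <- backward_eliminate(y, regs, alpha = 0.01)
  expect_equal(nrow(path$steps), 6L)
  expect_identical(path$steps$size, 6:1)
  # each step's set is the previous minus the recorded casualty
  for (i in 2:6)
    expect_setequal(path$regulator_sets[[i]],
                    setdiff(path$regulator_sets[[i - 1]],
                            path$steps$eliminated_regulator[i - 1]))
  expect_equal(path$optimal_step_index, which.min(path$steps$f_pvalue))
  # optimal model is at least as good as the full-candidate model
  expect_lte(path$steps$f_pvalue[path$optimal_step_index],
             path$steps$f_pvalue[1])
  expect_true(path$accepted)
  expect_setequal(path$selected, c("r1", "r2"))
})

test_that("elimination is deterministic for identical inputs", {
  set.seed(5)
  n <- 40
  regs <- setNames(lapply(1:8, function(i) rnorm(n)), sprintf("r%d", 1:8))
  y <- regs$r3 - regs$r7 + rnorm(n, sd = 0.5)
  p1 <- backward_eliminate(y, regs)
  p2 <- backward_eliminate(y, regs)
  expect_identical(p1$steps, p2$steps)
  expect_identical(p1$selected, p2$selected)
})

test_that("planted regulators are recovered and pure noise is rejected", {
  recoveries <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    true <- list(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    decoys <- setNames(lapply(1:17, function(i) rnorm(n)),
                       sprintf("d%02d", 1:17))
    y <- 1.0 * true$a - 1.0 * true$b + 0.8 * true$c + rnorm(n, sd = 0.5)
    path <- backward_eliminate(y, c(true, decoys), alpha = 0.01)
    recoveries <- recoveries + setequal(path$selected, c("a", "b", "c"))
  }
  expect_gte(recoveries, 16)  # >= 80%

  null_accepts <- 0
  for (seed in 1:20) {
    set.seed(1000 + seed)
    n <- 60
    regs <- setNames(lapply(1:5, function(i) rnorm(n)), sprintf("d%d", 1:5))
    null_accepts <- null_accepts + backward_eliminate(rnorm(n), regs)$accepted
  }
  expect_lte(null_accepts, 2)
})

test_that("per-target selection reports reason codes and annotated edges", {
  sim <- simulate_regulatory_data(sim_config(seed = 21))
  tgt <- sim$truth$planted_ffls$target_gene_id[1]
  got <- select_regulators_for_target(tgt, sim$dataset, sim$priors)
  expect_gt(nrow(got), 0)
  truth <- sim$truth$true_edges[sim$truth$true_edges$target_id == tgt, ]
  expect_true(all(truth$regulator_id %in% got$regulator_id))
  # recovered coefficient signs match the planted signs
  m <- merge(got, truth, by = "regulator_id")
  expect_true(all(sign(m$beta.x) == sign(m$beta.y)))
  expect_true(all(got$f_pvalue < 0.01))

  expect_identical(attr(select_regulators_for_target("NOT_MEASURED",
                                                     sim$dataset, sim$priors),
                        "reason"), "target_not_measured")
  orphan <- sim$dataset$mrna
  got2 <- select_regulators_for_target(rownames(orphan)[1], sim$dataset,
                                       prior_catalog(data.frame(
                                         regulator_type = "TF",
                                         regulator_id = "ghost",
                                         target_type = "gene",
                                         target_id = rownames(orphan)[1],
                                         source_tag = "x")))
  expect_identical(attr(got2, "reason"), "no_candidates")
})

test_that("identified edges never leave the prior catalog", {
  sim <- simulate_regulatory_data(sim_config(seed = 22))
  edges <- identify_edges(sim$dataset, sim$priors)
  prior_keys <- paste(sim$priors$regulator_id, sim$priors$target_id)
  expect_true(all(paste(edges$regulator_id, edges$target_id) %in% prior_keys))
})
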