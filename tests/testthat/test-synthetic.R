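test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(reduced = TRUE, n_pbc = 300, n_cbc = 100, seed = 42)
  b1 <- ground_truth_network(cfg)
  b2 <- ground_truth_network(cfg)
  expect_identical(b1$dag$arcs, b2$dag$arcs)
  for (v in b1$dag$nodes)
    expect_identical(b1$cpts[[v]]$prob, b2$cpts[[v]]$prob)
  d1 <- sample_network(b1, 200, seed = 7)
  d2 <- sample_network(b2, 200, seed = 7)
  expect_identical(d1, d2)
})

test_that("zero effect strength severs all parent-child dependence", {
  cfg <- generator_config(reduced = TRUE, effect_strength = 0, seed = 3)
  bn <- ground_truth_network(cfg)
  for (v in setdiff(bn$dag$nodes, "cohort")) {
    m <- cvdbn:::cpt_config_matrix(bn$cpts[[v]])
    for (j in seq_len(ncol(m)))
      expect_lt(max(m[, j]) - min(m[, j]), 1e-12)
  }
})

test_that("the calibrated outcome prevalence is confirmed by forward sampling", {
  cfg <- generator_config(reduced = TRUE, target_prevalence = 0.02, seed = 11)
  bn <- ground_truth_network(cfg)
  expect_equal(attr(bn, "achieved_prevalence"), 0.02, tolerance = 0.2)
  samp <- sample_network(bn, 50000, seed = 12)
  rate <- mean(samp$cvds == "Yes")
  expect_gte(rate, 0.015)
  expect_lte(rate, 0.025)
})

test_that("forward-sampled marginals converge to enumeration marginals", {
  cfg <- generator_config(reduced = TRUE, seed = 5)
  bn <- ground_truth_network(cfg)
  n <- 100000
  samp <- sample_network(bn, n, seed = 6)
  for (v in bn$dag$nodes) {
    exact <- enumerate_posterior(bn, v)$probabilities
    for (s in names(exact)) {
      p <- exact[[s]]
      se <- sqrt(max(p * (1 - p), 1e-12) / n)
      expect_lt(abs(mean(samp[[v]] == s) - p), 3 * se + 1e-9,
                label = sprintf("marginal of %s=%s", v, s))
    }
  }
})

test_that("ancestral sampling honours root probabilities and deterministic links", {
  # root frequency within 3 binomial standard errors
  yn <- c("y", "n")
  bn <- chain_bn(p_a = 0.25, p_b_given_ay = 1, p_b_given_an = 0)
  samp <- sample_network(bn, 10000, seed = 9)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(samp$A == "y") - 0.25), 3 * se)
  # deterministic CPT copies the parent column
  expect_identical(samp$B, samp$A)
  # empty sample keeps the columns
  empty <- sample_network(bn, 0, seed = 1)
  expect_identical(names(empty), c("A", "B"))
  expect_identical(nrow(empty), 0L)
})

test_that("cohort missingness is exactly block-deterministic", {
  cfg <- generator_config(reduced = TRUE, n_pbc = 300, n_cbc = 150, seed = 21)
  sim <- simulate_cohorts(cfg)
  d <- sim$data
  pbc <- d$cohort == "PBC"
  # PBC loses the prognostic factors other than age
  expect_true(all(is.na(d$grade[pbc])))
  expect_false(anyNA(d$age35))
  # CBC loses the CVD follow-up block
  for (v in c("cvds", "cardiotoxicity", "ischemic_heart_disease")) {
    expect_true(all(is.na(d[[v]][!pbc])))
    expect_false(anyNA(d[[v]][pbc]))
  }
  # the missingness indicator is a function of the cohort column alone
  miss_pattern <- apply(is.na(d), 1, paste, collapse = "")
  expect_identical(length(unique(miss_pattern[pbc])), 1L)
  expect_identical(length(unique(miss_pattern[!pbc])), 1L)
  # pre-mask values are retained and agree where observed
  truth <- attr(d, "truth")
  expect_false(anyNA(truth))
  obs <- !is.na(d$cvds)
  expect_identical(d$cvds[obs], truth$cvds[obs])
})

test_that("the full 25-variable masks match the cohort designs", {
  cfg <- generator_config(n_pbc = 150, n_cbc = 60, seed = 8)
  sim <- simulate_cohorts(cfg)
  d <- sim$data
  pbc <- d$cohort == "PBC"
  for (v in c("grade", "histology", "vascular", "ki67", "receptors",
              "pT", "pN"))
    expect_true(all(is.na(d[[v]][pbc])), label = paste(v, "masked in PBC"))
  for (v in c("cvds", "cardiotoxicity", "ischemic_heart_disease"))
    expect_true(all(is.na(d[[v]][!pbc])), label = paste(v, "masked in CBC"))
})

test_that("an empty mask is the identity and unknown states are rejected", {
  dict <- reduced_dictionary()
  bn <- ground_truth_network(generator_config(reduced = TRUE, seed = 2))
  d <- sample_network(bn, 50, seed = 3)
  m0 <- cohort_mask(dict, list())
  out <- apply_cohort_missingness(d, m0)
  expect_equal(out, d, ignore_attr = TRUE)
  expect_false(anyNA(out))
  expect_error(cohort_mask(dict, list(XBC = "grade")), "unknown cohort state")
  expect_error(cohort_mask(dict, list(PBC = "nonexistent")),
               "unknown variable")
  expect_error(cohort_mask(dict, list(PBC = "cohort")), "cannot be masked")
})

test_that("the train/validation split keeps the outcome-free cohort in training", {
  cfg <- generator_config(n_pbc = 1036, n_cbc = 339, reduced = TRUE, seed = 13)
  sim <- simulate_cohorts(cfg)
  d <- sim$data
  sp <- train_validation_split(d, 413 / 1375, seed = 4)
  expect_identical(nrow(sp$validation), 413L)
  expect_true(all(sp$validation$cohort == "PBC"))
  expect_identical(sum(sp$train$cohort == "CBC"), sum(d$cohort == "CBC"))
  # exact partition of row ids
  ids <- c(rownames(sp$train), rownames(sp$validation))
  expect_setequal(ids, rownames(d))
  expect_identical(anyDuplicated(ids), 0L)
  # degenerate input: nothing eligible for validation
  cbc_only <- d[d$cohort == "CBC", ]
  expect_error(train_validation_split(cbc_only, 0.3, seed = 1), "exceeds")
  expect_error(train_validation_split(d, 0, seed = 1), "\\(0, 1\\)")
})
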