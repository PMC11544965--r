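test_that("enumeration recovers priors and Bayes-rule posteriors", {
  bn <- chain_bn(0.5, 0.8, 0.2)
  # root prior with no evidence
  expect_equal(unname(enumerate_posterior(bn, "A")$probabilities),
               c(0.5, 0.5))
  # P(A=y | B=y) = 0.4 / 0.5
  post <- enumerate_posterior(bn, "A", c(B = "y"))
  expect_equal(unname(post$probabilities["y"]), 0.8)
  # impossible evidence under a deterministic CPT
  det <- chain_bn(1, 1, 0)  # A always y, B copies A
  expect_error(enumerate_posterior(det, "A", c(B = "n")),
               class = "cvdbn_inconsistent_evidence")
  # the guard refuses oversized state spaces
  big <- random_bn(1, n_nodes = 9, max_arity = 3)
  expect_error(enumerate_posterior(big, big$dag$nodes[1], log2_guard = 2),
               "state space")
})

test_that("variable elimination equals enumeration on seeded random problems", {
  worst <- 0
  for (seed in 1:20) {
    bn <- random_bn(seed, n_nodes = sample(4:8, 1))
    nodes <- bn$dag$nodes
    cvdbn:::with_seed(seed + 99L, {
      q <- sample(nodes, 1)
      n_ev <- sample(0:2, 1)
      ev_vars <- setdiff(sample(nodes), q)[seq_len(n_ev)]
      ev <- vapply(ev_vars, function(v) sample(bn$cpts[[v]]$states, 1), "")
      p1 <- enumerate_posterior(bn, q, ev)$probabilities
      p2 <- eliminate_posterior(bn, q, ev)$probabilities
      worst <<- max(worst, max(abs(p1 - p2)))
    })
  }
  expect_lt(worst, 1e-10)
})

test_that("variable elimination handles evidenced queries and empty evidence", {
  bn <- ground_truth_network(generator_config(reduced = TRUE, seed = 4))
  post <- eliminate_posterior(bn, "grade", c(grade = "Grade 2"))
  expect_equal(unname(post$probabilities), c(0, 1, 0))
  for (v in bn$dag$nodes)
    expect_equal(sum(eliminate_posterior(bn, v)$probabilities), 1,
                 tolerance = 1e-9)
})

test_that("likelihood weighting is reproducible and converges to the exact posterior", {
  bn <- ground_truth_network(generator_config(reduced = TRUE, seed = 14))
  ev <- c(chemo_adju = "Yes", cohort = "PBC")
  lw1 <- likelihood_weighting(bn, "cvds", ev, n_samples = 5000, seed = 77)
  lw2 <- likelihood_weighting(bn, "cvds", ev, n_samples = 5000, seed = 77)
  expect_identical(lw1$probabilities, lw2$probabilities)
  exact <- eliminate_posterior(bn, "cvds", ev)$probabilities
  lw <- likelihood_weighting(bn, "cvds", ev, n_samples = 100000, seed = 5)
  for (s in names(exact))
    expect_lt(abs(lw$probabilities[[s]] - exact[[s]]),
              3 * max(lw$mc_standard_errors[[s]], 1e-6))
  # evidence on every variable gives a point mass with zero SE
  full_ev <- vapply(bn$dag$nodes, function(v) bn$cpts[[v]]$states[1], "")
  lw_full <- likelihood_weighting(bn, "cvds", full_ev, n_samples = 50,
                                  seed = 1)
  expect_equal(unname(lw_full$probabilities),
               as.numeric(bn$cpts$cvds$states == full_ev[["cvds"]]))
  expect_equal(unname(lw_full$mc_standard_errors), c(0, 0))
})

test_that("risk prediction follows the posterior and the threshold rule", {
  toy <- toy_forced_cvd_bn()
  # cardiotoxicity forces the outcome
  r <- predict_risk(toy, c(cardiotoxicity = "Yes"))
  expect_equal(r$probability, 1.0)
  expect_identical(r$classified, "at_risk")
  # with no evidence the risk is the model's marginal prevalence,
  # and the default threshold equals it (so the call is at_risk)
  r0 <- predict_risk(toy)
  marg <- eliminate_posterior(toy, "cvds")$probabilities[["Yes"]]
  expect_equal(r0$probability, marg)
  expect_equal(r0$threshold, marg)
  expect_error(predict_risk(toy, c(cvds = "Yes")), "must not appear")
  # exact engine matches the enumeration oracle on the reduced net
  bn <- ground_truth_network(generator_config(reduced = TRUE, seed = 9))
  ev <- c(chemo_adju = "Yes", hypertension = "Post")
  expect_equal(predict_risk(bn, ev)$probability,
               unname(enum_oracle(bn, "cvds", ev)["Yes"]),
               tolerance = 1e-10)
})

test_that("evidence d-separated from the outcome leaves the risk unchanged", {
  bn <- ground_truth_network(generator_config(reduced = TRUE, seed = 16))
  ev <- c(cardiotoxicity = "Yes", ischemic_heart_disease = "No")
  # given both toxicity parents, age35 is d-separated from cvds
  expect_true(d_separated(bn$dag, "age35", "cvds",
                          c("cardiotoxicity", "ischemic_heart_disease")))
  p0 <- predict_risk(bn, ev)$probability
  p1 <- predict_risk(bn, c(ev, age35 = "Yes"))$probability
  expect_equal(p0, p1, tolerance = 1e-10)
})

test_that("adding a cardiotoxic finding never lowers the predicted risk", {
  for (seed in c(2, 8, 31)) {
    bn <- ground_truth_network(generator_config(reduced = TRUE, seed = seed))
    for (ev in list(NULL, c(chemo_adju = "Yes"), c(hypertension = "Post"))) {
      p_base <- predict_risk(bn, ev)$probability
      p_ct <- predict_risk(bn, c(ev, cardiotoxicity = "Yes"))$probability
      expect_gte(p_ct, p_base - 1e-12)
    }
  }
})
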