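arc_in <- function(arcs, set) {
  paste(arcs[, 1], arcs[, 2]) %in% paste(set[, 1], set[, 2])
}
check_forbidden <- function(dg, con) {
  out <- character(0)
  for (i in seq_len(nrow(dg$arcs))) {
    f <- dg$arcs[i, 1]; t <- dg$arcs[i, 2]
    if (t == con$context_node) out <- c(out, "context")
    if (any(con$forbidden_arcs[, 1] == f & con$forbidden_arcs[, 2] == t))
      out <- c(out, "forbidden")
    if (con$tier_of[f] > con$tier_of[t]) out <- c(out, "tier")
  }
  out
}
complete_counts_provider_for_test <- function(sim) {
  d <- attr(sim$data, "truth")
  attr(d, "dictionary") <- sim$dictionary
  d
}

make_ab_data <- function(a, b, dict = NULL) {
  d <- data.frame(A = a, B = b, stringsAsFactors = FALSE)
  attr(d, "dictionary") <- ab_dict()
  d
}

ab_dict <- function() {
  data_dictionary(list(
    list(name = "A", states = c("y", "n"), group = "selection"),
    list(name = "B", states = c("y", "n"), group = "target")))
}

test_that("family counts tally complete rows and weighted completions", {
  d <- make_ab_data(rep(c("y", "n"), c(6, 4)), rep("y", 10))
  fc <- family_counts(d, "A")
  expect_equal(as.vector(fc$counts), c(6, 4))
  expect_equal(fc$effective_n, 10)
  # empty data
  d0 <- make_ab_data(character(0), character(0))
  expect_true(all(family_counts(d0, "A")$counts == 0))
  # fractional completions of one missing cell conserve the row weight
  comp <- make_ab_data(c("y", "y", "n"), c("y", "y", "y"))
  fc_w <- family_counts(comp, "A", weights = c(1, 0.3, 0.7))
  expect_equal(sum(fc_w$counts), 2)
  expect_equal(as.vector(fc_w$counts), c(1.3, 0.7))
})

test_that("maximum-likelihood fitting matches closed forms, with and without smoothing", {
  d <- make_ab_data(rep(c("y", "n"), c(6, 4)), rep(c("y", "n"), 5))
  g <- dag(c("A", "B"))
  fit0 <- fit_parameters_mle(g, d, alpha = 0)
  expect_equal(unname(fit0$cpts$A$prob["y"]), 0.6)
  fit1 <- fit_parameters_mle(g, d, alpha = 1)
  expect_equal(unname(fit1$cpts$A$prob["y"]), 7 / 12)
  # an unobserved configuration with Laplace smoothing is uniform
  d2 <- make_ab_data(rep("y", 5), rep("y", 5))
  g2 <- dag(c("A", "B"), rbind(c("A", "B")))
  fit2 <- fit_parameters_mle(g2, d2, alpha = 1)
  expect_equal(unname(fit2$cpts$B$prob[, "n"]), c(0.5, 0.5))
  # alpha = 0 on an empty configuration falls back to uniform
  fit3 <- fit_parameters_mle(g2, d2, alpha = 0)
  expect_equal(unname(fit3$cpts$B$prob[, "n"]), c(0.5, 0.5))
  expect_error(fit_parameters_mle(g, make_ab_data(c("y", NA), c("y", "y"))),
               "missing cells")
})

test_that("observed log-likelihood marginalizes missing cells exactly", {
  bn <- chain_bn(0.5, 0.8, 0.2)
  # complete data: sum of log joint probabilities
  d <- make_ab_data(c("y", "n"), c("y", "y"))
  expect_equal(as.numeric(observed_loglik(bn, d)),
               log(0.5 * 0.8) + log(0.5 * 0.2))
  # a fully missing row contributes log 1 = 0
  d2 <- make_ab_data(c("y", NA), c("y", NA))
  expect_equal(as.numeric(observed_loglik(bn, d2)), log(0.5 * 0.8))
  # one missing cell: the hand-summed two-term mixture
  d3 <- make_ab_data(NA_character_, "y")
  expect_equal(as.numeric(observed_loglik(bn, d3)),
               log(0.5 * 0.8 + 0.5 * 0.2))
})

test_that("EM reduces to the closed-form fit on complete data", {
  cfg <- generator_config(reduced = TRUE, n_pbc = 200, n_cbc = 80, seed = 31)
  bn <- ground_truth_network(cfg)
  d <- sample_network(bn, 400, seed = 32)
  g <- knowledge_dag(reduced_dictionary())
  res <- em_parameters(g, d, em_config(smoothing_alpha = 0), init = NULL)
  mle <- fit_parameters_mle(g, d, alpha = 0)
  for (v in g$nodes)
    expect_equal(res$network$cpts[[v]]$prob, mle$cpts[[v]]$prob,
                 tolerance = 1e-12)
})

test_that("EM recovers a 50%-MCAR-masked root against a closed-form oracle", {
  # A -> B, A missing completely at random on half the rows; the
  # observed-data MLE of P(A=y) solves a closed-form score equation,
  # approximated here on a fine grid (independent of the EM path)
  cvdbn:::with_seed(88, {
    n <- 2000
    a <- ifelse(stats::runif(n) < 0.3, "y", "n")
    b <- ifelse(stats::runif(n) < ifelse(a == "y", 0.9, 0.15), "y", "n")
    a_obs <- ifelse(stats::runif(n) < 0.5, a, NA_character_)
  })
  d <- make_ab_data(a_obs, b)
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  res <- em_parameters(g, d, em_config(smoothing_alpha = 0, rel_tol = 1e-8,
                                       max_iterations = 200))
  p_hat <- as.numeric(res$network$cpts$A$prob["y"])
  # grid-search oracle over the full observed-data likelihood
  ll_of <- function(pa) {
    pby <- res$network$cpts$B$prob["y", ]  # named by parent state
    miss <- is.na(d$A)
    ll <- sum(log(ifelse(d$A[!miss] == "y", pa, 1 - pa))) +
      sum(log(ifelse(d$B[!miss] == "y",
                     ifelse(d$A[!miss] == "y", pby["y"], pby["n"]),
                     1 - ifelse(d$A[!miss] == "y", pby["y"], pby["n"])))) +
      sum(log(ifelse(d$B[miss] == "y",
                     pa * pby["y"] + (1 - pa) * pby["n"],
                     pa * (1 - pby["y"]) + (1 - pa) * (1 - pby["n"]))))
    ll
  }
  grid <- seq(0.01, 0.99, by = 0.0005)
  p_oracle <- grid[which.max(vapply(grid, ll_of, numeric(1)))]
  expect_lt(abs(p_hat - p_oracle), 0.03)
  expect_lt(abs(p_hat - 0.3), 0.05)
})

test_that("the observed log-likelihood trace is monotone on seeded incomplete data", {
  for (seed in 1:8) {
    cfg <- generator_config(reduced = TRUE, n_pbc = 250, n_cbc = 100,
                            seed = seed)
    sim <- simulate_cohorts(cfg)
    g <- knowledge_dag(sim$dictionary)
    res <- em_parameters(g, sim$data,
                         em_config(smoothing_alpha = 0, rel_tol = 1e-6,
                                   max_iterations = 25),
                         dict = sim$dictionary)
    expect_gte(length(res$loglik_trace), 2)
    expect_true(all(diff(res$loglik_trace) >= -1e-8),
                label = sprintf("monotone trace, seed %d", seed))
  }
})

test_that("BIC prefers the true independence structure and decomposes by family", {
  cvdbn:::with_seed(55, {
    n <- 5000
    a_ind <- ifelse(stats::runif(n) < 0.5, "y", "n")
    b_ind <- ifelse(stats::runif(n) < 0.5, "y", "n")
    a_dep <- ifelse(stats::runif(n) < 0.5, "y", "n")
    b_dep <- ifelse(stats::runif(n) < 0.95, a_dep,
                    ifelse(a_dep == "y", "n", "y"))
  })
  dict <- ab_dict()
  score_of <- function(a, b, g) {
    d <- make_ab_data(a, b)
    counts <- lapply(stats::setNames(g$nodes, g$nodes), function(v)
      family_counts(d, v, cvdbn:::dag_parents(g, v), dict = dict)$counts)
    bic_score(counts, g, length(a))
  }
  g0 <- dag(c("A", "B"))
  g1 <- dag(c("A", "B"), rbind(c("A", "B")))
  expect_gt(score_of(a_ind, b_ind, g0), score_of(a_ind, b_ind, g1))
  expect_gt(score_of(a_dep, b_dep, g1), score_of(a_dep, b_dep, g0))
  # decomposability: total equals the sum of family terms
  d <- make_ab_data(a_dep, b_dep)
  c_a <- family_counts(d, "A", dict = dict)$counts
  c_b <- family_counts(d, "B", "A", dict = dict)$counts
  expect_equal(bic_score(list(A = c_a, B = c_b), g1, 5000),
               cvdbn:::family_bic(c_a, 2, 5000) +
                 cvdbn:::family_bic(c_b, 2, 5000))
})

test_that("hill climbing respects data and constraints", {
  dict <- ab_dict()
  tiers <- list("A", "B")
  con <- knowledge_constraints(tiers = tiers, context_node = "A")
  cvdbn:::with_seed(66, {
    n <- 2000
    a_ind <- ifelse(stats::runif(n) < 0.5, "y", "n")
    b_ind <- ifelse(stats::runif(n) < 0.5, "y", "n")
    a_dep <- ifelse(stats::runif(n) < 0.5, "y", "n")
    b_dep <- ifelse(stats::runif(n) < 0.9, a_dep,
                    ifelse(a_dep == "y", "n", "y"))
  })
  g0 <- dag(c("A", "B"))
  # independent data: no improving move
  res_ind <- hill_climb(make_ab_data(a_ind, b_ind), con, g0)
  expect_identical(nrow(res_ind$arcs), 0L)
  # planted dependence, tiers only allow A -> B: arc recovered
  res_dep <- hill_climb(make_ab_data(a_dep, b_dep), con, g0)
  expect_true(cvdbn:::has_arc(res_dep, "A", "B"))
  # the same beneficial arc, when forbidden, stays out
  con_f <- knowledge_constraints(forbidden_arcs = rbind(c("A", "B")),
                                 tiers = tiers, context_node = "A")
  res_f <- hill_climb(make_ab_data(a_dep, b_dep), con_f, g0)
  expect_false(cvdbn:::has_arc(res_f, "A", "B"))
  # score never decreases relative to the start
  expect_gte(attr(res_dep, "score"),
             attr(hill_climb(make_ab_data(a_dep, b_dep), con, res_dep,
                             max_parents = 1), "score") - 1e-9)
  # infeasible starts are rejected
  expect_error(hill_climb(make_ab_data(a_dep, b_dep), con_f,
                          dag(c("A", "B"), rbind(c("A", "B")))),
               "violates")
})

test_that("constraint soundness holds over random constraint sets", {
  for (seed in 1:10) {
    cfg <- generator_config(reduced = TRUE, n_pbc = 300, n_cbc = 120,
                            seed = seed)
    sim <- simulate_cohorts(cfg)
    dict <- sim$dictionary
    nodes <- cvdbn:::dict_names(dict)
    tiers <- model_tiers(dict)
    cvdbn:::with_seed(seed + 10L, {
      # random forbidden arcs on top of the tier constraints
      pool <- expand.grid(from = nodes, to = nodes,
                          stringsAsFactors = FALSE)
      pool <- pool[pool$from != pool$to, ]
      forb <- as.matrix(pool[sample(nrow(pool), 8), ])
    })
    truth <- knowledge_dag(dict)
    required <- truth$arcs[!(arc_in(truth$arcs, forb)), , drop = FALSE]
    con <- knowledge_constraints(required_arcs = required,
                                 forbidden_arcs = forb,
                                 tiers = tiers, context_node = "cohort")
    start <- dag(nodes, required)
    out <- hill_climb(complete_counts_provider_for_test(sim), con, start)
    expect_identical(check_forbidden(out, con), character(0))
  }
})

test_that("structural EM on complete data reduces to hill-climb plus MLE", {
  cfg <- generator_config(reduced = TRUE, n_pbc = 400, n_cbc = 150, seed = 77)
  bn <- ground_truth_network(cfg)
  dict <- reduced_dictionary()
  d <- sample_network(bn, 550, seed = 78)
  attr(d, "dictionary") <- dict
  con <- default_constraints(dict)
  prior <- knowledge_dag(dict)
  sem <- structural_em(prior, d, con, em_config(smoothing_alpha = 0),
                       dict = dict)
  hc <- hill_climb(d, con, prior, dict = dict)
  expect_true(cvdbn:::same_dag(sem$dag, hc))
  mle <- fit_parameters_mle(hc, d, dict = dict, alpha = 0)
  for (v in hc$nodes)
    expect_equal(sem$network$cpts[[v]]$prob, mle$cpts[[v]]$prob,
                 tolerance = 1e-10)
})

test_that("constraint validation rejects contradictory inputs", {
  expect_error(knowledge_constraints(required_arcs = rbind(c("A", "B")),
                                     forbidden_arcs = rbind(c("A", "B")),
                                     tiers = list("A", "B"),
                                     context_node = "A"),
               "required and forbidden")
  expect_error(knowledge_constraints(tiers = list(c("A", "B"), "B"),
                                     context_node = "A"),
               "more than one tier")
  expect_error(knowledge_constraints(required_arcs = rbind(c("B", "A")),
                                     tiers = list("A", "B"),
                                     context_node = "A"),
               "tier|context")
  expect_error(knowledge_constraints(tiers = list("A", "B"),
                                     context_node = "B"),
               "first tier")
})
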