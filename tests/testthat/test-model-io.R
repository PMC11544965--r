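test_that("networks survive a .net round trip exactly", {
  for (seed in c(1, 5, 9)) {
    bn <- random_bn(seed, n_nodes = 6)
    path <- withr::local_tempfile(fileext = ".net")
    write_net(bn, path)
    bn2 <- read_net(path)
    expect_identical(bn2$dag$nodes, bn$dag$nodes)
    expect_setequal(paste(bn2$dag$arcs[, 1], bn2$dag$arcs[, 2]),
                    paste(bn$dag$arcs[, 1], bn$dag$arcs[, 2]))
    for (v in bn$dag$nodes) {
      expect_identical(bn2$cpts[[v]]$parents, bn$cpts[[v]]$parents)
      expect_identical(bn2$cpts[[v]]$states, bn$cpts[[v]]$states)
      expect_lt(max(abs(bn2$cpts[[v]]$prob - bn$cpts[[v]]$prob)), 1e-9)
    }
  }
  # the reduced knowledge-skeleton network round-trips too
  bn <- ground_truth_network(generator_config(reduced = TRUE, seed = 3))
  path <- withr::local_tempfile(fileext = ".net")
  write_net(bn, path)
  bn2 <- read_net(path, dictionary = reduced_dictionary())
  expect_identical(validate_network(bn2), character(0))
  expect_equal(eliminate_posterior(bn2, "cvds")$probabilities,
               eliminate_posterior(bn, "cvds")$probabilities,
               tolerance = 1e-12)
})

test_that("a hand-written two-node document parses to the expected network", {
  doc <- c(
    "net { }",
    "node A { states = ( \"y\" \"n\" ); }",
    "node B { states = ( \"y\" \"n\" ); }",
    "potential ( A ) { data = ( 0.5 0.5 ); }",
    "potential ( B | A ) { data = (( 0.8 0.2 ) ( 0.2 0.8 )); }")
  bn <- read_net(lines = doc)
  ref <- chain_bn(0.5, 0.8, 0.2)
  expect_identical(bn$dag$nodes, c("A", "B"))
  expect_equal(as.vector(bn$cpts$B$prob), as.vector(ref$cpts$B$prob))
  expect_equal(joint_probability(bn, c(A = "y", B = "y")), 0.4)
})

test_that("malformed .net documents produce named errors", {
  base <- c("net { }",
            "node A { states = ( \"y\" \"n\" ); }",
            "node B { states = ( \"y\" \"n\" ); }")
  # wrong row length
  expect_error(read_net(lines = c(base,
    "potential ( A ) { data = ( 0.5 0.5 ); }",
    "potential ( B | A ) { data = (( 0.8 0.2 0.1 ) ( 0.2 0.8 )); }")),
    "node 'B'")
  # non-normalized potential
  expect_error(read_net(lines = c(base,
    "potential ( A ) { data = ( 0.6 0.6 ); }",
    "potential ( B | A ) { data = (( 1 0 ) ( 0 1 )); }")),
    "not normalized")
  # unknown block keyword
  expect_error(read_net(lines = c(base, "blob X { }")), "unknown block")
  # missing potential
  expect_error(read_net(lines = base), "no potential")
})

test_that("datasets round-trip through CSV with empty-cell missingness", {
  sim <- simulate_cohorts(generator_config(reduced = TRUE, n_pbc = 120,
                                           n_cbc = 60, seed = 19))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$data, path)
  back <- suppressMessages(read_dataset(path, sim$dictionary))
  expect_equal(back, sim$data[, names(back)], ignore_attr = TRUE)
  # unknown state labels are rejected with coordinates
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  raw$grade[raw$cohort == "CBC"][1] <- "Grade 4"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path2, row.names = FALSE, na = "")
  expect_error(suppressMessages(read_dataset(path2, sim$dictionary)),
               "Grade 4")
  # empty file with a header reads as a 0-row dataset
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(cvdbn:::dict_names(sim$dictionary), collapse = ","),
             path3)
  empty <- suppressMessages(read_dataset(path3, sim$dictionary))
  expect_identical(nrow(empty), 0L)
})

test_that("dictionaries round-trip through JSON and YAML", {
  dict <- cvd_dictionary()
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_dictionary(dict, path)
    back <- read_dictionary(path)
    expect_identical(cvdbn:::dict_names(back), cvdbn:::dict_names(dict))
    for (v in cvdbn:::dict_names(dict)) {
      expect_identical(cvdbn:::dict_states(back, v),
                       cvdbn:::dict_states(dict, v))
      expect_identical(cvdbn:::dict_group(back, v),
                       cvdbn:::dict_group(dict, v))
    }
  }
})

test_that("the shipped constraints match the in-code prior knowledge", {
  path <- system.file("extdata", "constraints_full.yaml", package = "cvdbn")
  con <- read_constraints(path)
  ref <- default_constraints(cvd_dictionary())
  expect_identical(con$context_node, "cohort")
  expect_identical(con$tiers[[1]], "cohort")
  expect_setequal(paste(con$required_arcs[, 1], con$required_arcs[, 2]),
                  paste(ref$required_arcs[, 1], ref$required_arcs[, 2]))
  dict <- read_dictionary(system.file("extdata", "dictionary_full.json",
                                      package = "cvdbn"))
  expect_identical(cvdbn:::dict_names(dict),
                   cvdbn:::dict_names(cvd_dictionary()))
})

test_that("constraints round-trip and are validated on read", {
  dict <- reduced_dictionary()
  con <- default_constraints(dict)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_constraints(con, path)
  back <- read_constraints(path)
  expect_identical(back$context_node, "cohort")
  expect_identical(back$tiers[[1]], "cohort")
  expect_setequal(paste(back$required_arcs[, 1], back$required_arcs[, 2]),
                  paste(con$required_arcs[, 1], con$required_arcs[, 2]))
  # contradictions are rejected
  bad <- con
  bad$forbidden_arcs <- con$required_arcs[1, , drop = FALSE]
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_constraints(bad, path2)
  expect_error(read_constraints(path2), "required and forbidden")
})
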