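test_that("per-rule compliance follows the majority-with-magnitude rule", {
  r <- truth_rule("r1", stimulus = c(S = 1), response = c(X = 1, Y = -1))
  expect_true(rule_complied(c(S = 1, X = 0.6, Y = -0.2), r))
  expect_false(rule_complied(c(S = 1, X = 0.05, Y = -0.05), r))
  # single response protein at exactly the magnitude threshold counts
  r1 <- truth_rule("r2", stimulus = c(S = 1), response = c(X = 1))
  expect_true(rule_complied(c(S = 1, X = 0.1), r1))
  expect_false(rule_complied(c(S = 1, X = 0.0999), r1))
})

test_that("accuracy counts complied rules; edgeless networks score zero", {
  fx <- small_fixture(seed = 5)
  cfg <- training_config(steps = fx$spec$steps)
  expect_equal(
    solution_accuracy(fx$network, fx$ground_truth$weights, fx$rules, cfg),
    1.0)
  # no edges: nothing reaches the responses
  bare <- protein_network(
    data.frame(from = character(), to = character()),
    nodes = fx$network$nodes)
  expect_equal(solution_accuracy(bare, numeric(0), fx$rules, cfg), 0)
})

test_that("annealing is seed-deterministic and self-consistent", {
  fx <- small_fixture(seed = 5)
  cfg <- training_config(iterations = 300, steps = fx$spec$steps)
  a <- sample_solution(fx$network, fx$rules, cfg, seed = 17)
  b <- sample_solution(fx$network, fx$rules, cfg, seed = 17)
  expect_identical(a$weights, b$weights)
  expect_identical(a$accuracy, b$accuracy)
  # the accuracy the annealer reports matches an R-side recomputation
  expect_equal(a$accuracy,
               solution_accuracy(fx$network, a, fx$rules, cfg))
  # zero iterations returns the random initialisation, also consistent
  z <- sample_solution(fx$network, fx$rules,
                       training_config(iterations = 0,
                                       steps = fx$spec$steps), seed = 17)
  expect_equal(z$accuracy,
               solution_accuracy(fx$network, z, fx$rules,
                                 training_config(steps = fx$spec$steps)))
  # weights respect the prior signs of the network edges
  prior <- fx$network$edges$sign
  expect_true(all(a$weights[!is.na(prior)] * prior[!is.na(prior)] >= 0))
})

test_that("annealing reliably recovers high accuracy on a planted fixture", {
  fx <- small_fixture(seed = 11)
  cfg <- training_config(iterations = 2000, steps = fx$spec$steps)
  accs <- vapply(1:20, function(k) {
    sample_solution(fx$network, fx$rules, cfg, seed = 1000 + k)$accuracy
  }, numeric(1))
  expect_gte(mean(accs >= 0.9), 0.8)
})

test_that("ensembles retain only solutions above the threshold", {
  fx <- small_fixture(seed = 11)
  cfg <- training_config(target_size = 8, max_attempts = 100,
                         iterations = 800, steps = fx$spec$steps, seed = 2)
  ens <- build_ensemble(fx$network, fx$rules, cfg)
  expect_length(ens$solutions, 8)
  expect_true(min(ens$accuracies) > cfg$retention_threshold)
  expect_equal(ens$mean_accuracy, mean(ens$accuracies))
  expect_lte(ens$mean_accuracy, 1)
  # reproducibility: identical config and seed give the identical ensemble
  ens2 <- build_ensemble(fx$network, fx$rules, cfg)
  expect_identical(ens$accuracies, ens2$accuracies)
  expect_identical(ens$solutions[[1]]$weights, ens2$solutions[[1]]$weights)
  # a single-solution ensemble works
  one <- build_ensemble(fx$network, fx$rules,
                        training_config(target_size = 1, iterations = 800,
                                        steps = fx$spec$steps, seed = 2))
  expect_length(one$solutions, 1)
})

test_that("a near-one threshold admits only perfect solutions", {
  fx <- small_fixture(seed = 11)
  cfg <- training_config(retention_threshold = 1 - 1e-9, target_size = 3,
                         max_attempts = 150, iterations = 2000,
                         steps = fx$spec$steps, seed = 4)
  ens <- build_ensemble(fx$network, fx$rules, cfg)
  expect_true(all(ens$accuracies == 1))
})

test_that("trained ensembles beat weight-shuffled null ensembles", {
  fx <- small_fixture(seed = 11)
  cfg <- training_config(target_size = 6, max_attempts = 80,
                         iterations = 800, steps = fx$spec$steps, seed = 3)
  ens <- build_ensemble(fx$network, fx$rules, cfg)
  set.seed(123)
  null_means <- vapply(1:50, function(i) {
    mean(vapply(ens$solutions, function(s) {
      solution_accuracy(fx$network, sample(s$weights), fx$rules, cfg)
    }, numeric(1)))
  }, numeric(1))
  p <- (1 + sum(null_means >= ens$mean_accuracy)) / 51
  expect_lt(p, 0.05)
})

test_that("bioflags join their drug's rule as extra response constraints", {
  fx <- small_fixture(seed = 5)
  drug <- fx$drugs[[1]]
  rules <- attach_bioflags(fx$rules, list(drug))
  drug_rule <- Filter(function(r) r$relation == "treats", rules)[[1]]
  plain_rule <- Filter(function(r) r$relation == "treats", fx$rules)[[1]]
  expect_setequal(setdiff(names(drug_rule$response),
                          names(plain_rule$response)),
                  drug$bioflags$protein)
  # non-drug rules untouched
  others <- Filter(function(r) r$relation == "causes", rules)
  others0 <- Filter(function(r) r$relation == "causes", fx$rules)
  expect_equal(lapply(others, `[[`, "response"),
               lapply(others0, `[[`, "response"))
})

test_that("training configs load from YAML with defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("target_size: 10", "iterations: 500", "seed: 9"), path)
  cfg <- load_training_config(path)
  expect_equal(cfg$target_size, 10L)
  expect_equal(cfg$iterations, 500L)
  expect_equal(cfg$retention_threshold, 0.9)
  writeLines("bogus_key: 1", path)
  expect_error(load_training_config(path), "unknown config key")
})

test_that("ensemble export writes accuracies and long-format weights", {
  fx <- small_fixture(seed = 5)
  cfg <- training_config(target_size = 2, max_attempts = 40,
                         iterations = 500, steps = fx$spec$steps, seed = 8)
  ens <- build_ensemble(fx$network, fx$rules, cfg)
  prefix <- file.path(withr::local_tempdir(), "ens")
  write_ensemble(ens, fx$network, prefix)
  acc <- read.delim(paste0(prefix, "_accuracies.tsv"))
  expect_equal(acc$accuracy, ens$accuracies)
  w <- read.delim(paste0(prefix, "_weights.tsv"))
  expect_equal(nrow(w), 2 * nrow(fx$network$edges))
  expect_equal(w$weight[w$solution_id == 2], ens$solutions[[2]]$weights)
})
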