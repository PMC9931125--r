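test_that("preferential attachment yields m*(n-m) edges, deterministically", {
  spec <- fixture_spec(n_nodes = 200, m = 2, seed = 7)
  net <- generate_network(spec)
  expect_length(net$nodes, 200)
  expect_equal(nrow(net$edges), 396)
  expect_false(any(net$edges$from == net$edges$to))
  expect_false(any(duplicated(paste(net$edges$from, net$edges$to))))
  # minimal case
  tiny <- generate_network(fixture_spec(n_nodes = 3, m = 1, seed = 1))
  expect_equal(nrow(tiny$edges), 2)
  # determinism
  net2 <- generate_network(spec)
  expect_identical(net$edges, net2$edges)
  # alternative topology generates and propagates too
  er <- generate_network(fixture_spec(n_nodes = 50, m = 2,
                                      model = "erdos_renyi", seed = 3))
  expect_gt(nrow(er$edges), 0)
})

test_that("planted effectors are all reversed by the true weights", {
  fx <- generate_fixture(fixture_spec(seed = 7))
  for (d in fx$drugs) {
    eff <- fx$ground_truth$effectors
    eff <- eff[eff$drug == d$name, ]
    prof <- propagate(fx$network, fx$ground_truth$weights, drug_stimulus(d),
                      steps = fx$spec$steps)
    expect_true(all(is_reversed(prof[eff$protein], eff$sign)))
    # a planted path exists for every effector with full weight coverage
    paths <- fx$ground_truth$planted_paths[[d$name]]
    expect_true(any(!is.na(paths)))
  }
  # effector disease signs oppose the drug-induced signs by construction
  expect_setequal(unique(fx$ground_truth$effectors$sign), c(-1L, 1L))
})

test_that("a single planted chain fixture is valid", {
  fx <- generate_fixture(fixture_spec(
    n_nodes = 30, m = 2, n_motives = 1, effectors_per_motive = 1,
    n_drugs = 1, targets_per_drug = 1, n_bioflags = 0, n_rules = 1,
    n_terms = 2, term_size_range = c(2, 5), seed = 13))
  expect_length(fx$rules, 1)
  expect_equal(nrow(fx$ground_truth$effectors), 1)
  expect_length(fx$drugs, 1)
})

test_that("planting fails cleanly on a hub-and-spoke network", {
  nodes <- paste0("P", 1:10)
  star <- protein_network(
    data.frame(from = nodes[-1], to = nodes[1]), nodes = nodes)
  spec <- fixture_spec(n_nodes = 10, m = 1, n_motives = 2,
                       effectors_per_motive = 3, seed = 1)
  expect_error(plant_ground_truth(star, spec),
               "too sparse|insufficient reachable")
})

test_that("noiseless truth tables are perfectly complied by the truth", {
  fx <- small_fixture(seed = 5)
  cfg <- training_config(steps = fx$spec$steps)
  expect_equal(
    solution_accuracy(fx$network, fx$ground_truth$weights, fx$rules, cfg), 1)
})

test_that("the noise rate flips the expected fraction of response signs", {
  fracs <- vapply(1:10, function(s) {
    spec0 <- fixture_spec(n_nodes = 60, m = 2, n_motives = 2,
                          effectors_per_motive = 4, n_drugs = 1,
                          targets_per_drug = 2, n_rules = 12, seed = s)
    specn <- fixture_spec(n_nodes = 60, m = 2, n_motives = 2,
                          effectors_per_motive = 4, n_drugs = 1,
                          targets_per_drug = 2, n_rules = 12,
                          noise = 0.4, seed = s)
    net <- generate_network(spec0)
    pl <- plant_ground_truth(net, spec0)
    r0 <- generate_truth_table(net, pl$ground_truth, pl$drugs, spec0)
    rn <- generate_truth_table(net, pl$ground_truth, pl$drugs, specn)
    a <- unlist(lapply(r0, `[[`, "response"))
    b <- unlist(lapply(rn, `[[`, "response"))
    mean(a != b)
  }, numeric(1))
  expect_gt(mean(fracs), 0.3)
  expect_lt(mean(fracs), 0.5)
})

test_that("annotations include planted terms and honour size bounds", {
  fx <- small_fixture(seed = 5)
  ann <- fx$annotations
  drug <- fx$drugs[[1]]$name
  planted <- ann$terms[[paste0("PLANTED_", drug)]]
  eff <- fx$ground_truth$effectors
  expect_setequal(planted, eff$protein[eff$drug == drug])
  sizes <- lengths(ann$terms)
  expect_true(all(sizes >= 1))
  # a >=500-node fixture carries an oversized term that the filter removes
  big <- generate_annotations(
    generate_network(fixture_spec(n_nodes = 520, m = 1, seed = 2)),
    fx$ground_truth,
    fixture_spec(n_nodes = 520, m = 1, n_terms = 2, seed = 2))
  expect_true("OVERSIZED_TERM" %in% names(big$terms))
  expect_false("OVERSIZED_TERM" %in%
                 names(filter_collection(big)$terms))
})

test_that("enrichment of the true-weight down set top-ranks a planted term", {
  fx <- small_fixture(seed = 19, n_nodes = 40L)
  drug <- fx$drugs[[1]]
  prof <- propagate(fx$network, fx$ground_truth$weights,
                    drug_stimulus(drug), steps = fx$spec$steps)
  res <- enrich(prof, fx$annotations, fx$network$nodes)
  eff <- fx$ground_truth$effectors
  dn_sign <- sign(prof[eff$protein])
  dir_most <- if (mean(dn_sign < 0) > 0.5) "down" else "up"
  fam <- res[res$direction == dir_most, ]
  expect_equal(fam$term[which.min(fam$p_value)],
               paste0("PLANTED_", drug$name))
})

test_that("fixture directories round-trip bit-identically", {
  fx <- small_fixture(seed = 23)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  suppressWarnings(back <- suppressMessages(load_fixture(dir)))
  expect_equal(back$network$edges, fx$network$edges)
  expect_equal(back$characterization, fx$characterization)
  expect_equal(lapply(back$rules, unclass), lapply(fx$rules, unclass))
  expect_equal(back$annotations$terms, fx$annotations$terms)
  expect_equal(back$ground_truth$weights$weights,
               fx$ground_truth$weights$weights)
  expect_length(back$drugs, length(fx$drugs))
  expect_equal(back$drugs[[1]]$targets, fx$drugs[[1]]$targets)
})

test_that("ensemble accuracy degrades (weakly) with truth-table noise", {
  etas <- c(0, 0.1, 0.2)
  spec_at <- function(eta, s) fixture_spec(
    n_nodes = 50, m = 2, n_motives = 2, effectors_per_motive = 3,
    n_drugs = 1, targets_per_drug = 2, n_rules = 10, noise = eta, seed = s)
  # true-weight accuracy: flips are nested across eta at a common seed,
  # so this is non-increasing by construction
  for (s in 1:3) {
    accs <- vapply(etas, function(eta) {
      spec <- spec_at(eta, s)
      net <- generate_network(spec)
      pl <- plant_ground_truth(net, spec)
      rules <- generate_truth_table(net, pl$ground_truth, pl$drugs, spec)
      solution_accuracy(net, pl$ground_truth$weights, rules,
                        training_config(steps = spec$steps))
    }, numeric(1))
    expect_true(all(diff(accs) <= 0))
  }
  # trained ensembles, averaged over seeds
  mean_acc <- vapply(etas, function(eta) {
    mean(vapply(1:3, function(s) {
      spec <- spec_at(eta, s)
      net <- generate_network(spec)
      pl <- plant_ground_truth(net, spec)
      rules <- generate_truth_table(net, pl$ground_truth, pl$drugs, spec)
      cfg <- training_config(target_size = 10, max_attempts = 120,
                             iterations = 800, steps = spec$steps, seed = s)
      ens <- tryCatch(suppressWarnings(build_ensemble(net, rules, cfg)),
                      error = function(e) NULL)
      if (is.null(ens)) 0 else ens$mean_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) <= 1e-8))
})
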