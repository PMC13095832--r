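test_that("birth-death trees are ultrametric with the requested size and age", {
  tr <- simulate_bd_tree(34, birth = 0.3, death = 0.1, seed = 8,
                         scale_root_age = 16.72)
  expect_equal(ape::Ntip(tr), 34)
  expect_silent(validate_chronogram(tr))
  expect_equal(root_age(tr), 16.72, tolerance = 1e-9)
  expect_silent(node_ages(tr, tol = 1e-8))

  cherry <- simulate_bd_tree(2, birth = 1, seed = 1)
  expect_equal(ape::Ntip(cherry), 2)
  expect_silent(validate_chronogram(cherry))

  expect_error(simulate_bd_tree(1, birth = 1), "n_tips")
  expect_error(simulate_bd_tree(10, birth = 0.2, death = 0.5), "birth > death")

  # extinct lineages are pruned completely: every tip is extant
  withr::local_seed(3)
  for (i in 1:10) {
    tr <- simulate_bd_tree(12, birth = 0.6, death = 0.4)
    expect_equal(ape::Ntip(tr), 12)
    expect_silent(validate_chronogram(tr))
  }
})

test_that("pure-birth lineage growth matches the Yule expectation", {
  lambda <- 0.8
  t_max <- 2
  withr::local_seed(5)
  n_rep <- 500
  counts <- vapply(seq_len(n_rep), function(i) {
    lin <- cutevo:::.bd_forward(lambda, 0, t_max = t_max)
    sum(lin$status == "extant")
  }, numeric(1))
  target <- exp(lambda * t_max)  # E[N(t)] from one stem lineage
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - target), 3 * se)
})

test_that("forward Mk histories have consistent ground truth", {
  tr <- simulate_bd_tree(20, birth = 0.5, seed = 14, scale_root_age = 10)
  model <- mk_model(cutting_states(), 0.06)
  sc <- simulate_mk_history(tr, model, root_state = "dicot", seed = 15)
  # tip states equal the tip ends of the true history
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    m <- sc$history$edge_maps[[e]]
    expect_identical(names(m)[length(m)], sc$history$node_states[ch])
  }
  expect_equal(unname(sc$tip_states),
               unname(sc$history$node_states[seq_len(20)]))
  # segments tile each branch exactly
  sums <- vapply(sc$history$edge_maps, sum, numeric(1))
  expect_equal(sums, tr$edge.length, tolerance = 1e-12)

  # q -> 0: evolution frozen at the root state
  frozen <- simulate_mk_history(tr, mk_model(cutting_states(), 1e-12),
                                root_state = "grass", seed = 1)
  expect_true(all(frozen$tip_states == "grass"))
  expect_equal(nrow(extract_transitions(frozen$history)), 0)

  # determinism
  again <- simulate_mk_history(tr, model, root_state = "dicot", seed = 15)
  expect_identical(sc$tip_states, again$tip_states)
  expect_identical(sc$history$edge_maps, again$history$edge_maps)
})

test_that("saturated evolution reaches the uniform stationary tip distribution", {
  tr <- simulate_bd_tree(200, birth = 1, seed = 44, scale_root_age = 1)
  model <- mk_model(cutting_states(), 20)  # k q T = 60 per unit path
  sc <- simulate_mk_history(tr, model, root_state = "dicot", seed = 45)
  freq <- table(factor(sc$tip_states, levels = cutting_states())) / 200
  # tip states are phylogenetically correlated; allow a generous 3-sigma
  # band treating tips as independent plus a correlation cushion
  expect_true(all(abs(freq - 1 / 3) < 0.12))
})

test_that("the frozen study scenario matches the empirical frame", {
  sc <- scenario_fixture()
  expect_equal(ape::Ntip(sc$tree), 34)
  expect_equal(root_age(sc$tree), 16.72, tolerance = 1e-9)
  expect_silent(validate_chronogram(sc$tree))
  expect_equal(sc$true_root_state, "dicot")
  expect_equal(sc$true_q, 0.03)
  # informative tip composition within the screening band
  informative <- sc$tip_states[names(sc$tip_states) != sc$parasite_tip]
  counts <- table(factor(informative, levels = cutting_states()))
  expect_gte(counts[["dicot"]], 15); expect_lte(counts[["dicot"]], 29)
  expect_gte(counts[["grass"]], 6); expect_lte(counts[["grass"]], 12)
  expect_gte(counts[["dicot_grass"]], 1); expect_lte(counts[["dicot_grass"]], 3)
  # deterministic regeneration
  sc2 <- study_scenario()
  expect_identical(sc$tip_states, sc2$tip_states)
  expect_identical(write_newick(sc$tree), write_newick(sc2$tree))
  # parasite analog enters the likelihood as fully ambiguous
  tv <- scenario_tip_vectors(sc)
  expect_equal(tv[[sc$parasite_tip]], c(1, 1, 1))
})

test_that("scenario files are faithful plain-text views of the object", {
  sc <- scenario_fixture()
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  expect_true(all(file.exists(paths)))
  tr <- parse_newick(paste(readLines(paths[["tree"]]), collapse = ""))
  expect_equal(ape::Ntip(tr), 34)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$true_q, sc$true_q)
  expect_equal(truth$true_root_state, "dicot")
  tt <- load_trait_table(paths[["traits"]],
                         parasite_species = truth$parasite_species)
  expect_equal(nrow(tt), 34)
  expect_equal(sum(tt$state == "parasite"), 1)
  # round trip through the normalization recovers the simulated states
  informative <- sc$tip_states[names(sc$tip_states) != sc$parasite_tip]
  got <- stats::setNames(as.character(tt$state), tt$species)[names(informative)]
  expect_equal(got, informative)
})

test_that("rate estimation recovers the generating rate in the identifiable regime", {
  # the module's reason to exist: simulate at known q, re-estimate
  withr::local_seed(100)
  n_rep <- 20
  ratio <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- simulate_bd_tree(100, birth = 1, scale_root_age = 1)
    q_true <- stats::runif(1, 0.5, 1.5) / 3  # k q depth in [0.5, 1.5]
    sc <- simulate_mk_history(tr, mk_model(cutting_states(), q_true))
    fit <- suppressWarnings(fit_er_rate(tr, scenario_tip_vectors(sc)))
    ratio[i] <- fit$q_hat / q_true
  }
  expect_gt(stats::median(ratio), 0.8)
  expect_lt(stats::median(ratio), 1.25)
})
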