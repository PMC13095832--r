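# 10-tip fixture reused across the sampling checks
.map_fixture <- function() {
  tr <- simulate_bd_tree(10, birth = 0.5, death = 0.1, seed = 77,
                         scale_root_age = 10)
  model <- mk_model(cutting_states(), 0.08)
  sc <- simulate_mk_history(tr, model, root_state = "dicot", seed = 78)
  list(tree = tr, model = model, tv = scenario_tip_vectors(sc))
}

test_that("joint node-state draws respect the tips and are reproducible", {
  fx <- .map_fixture()
  s1 <- sample_joint_node_states(fx$tree, fx$tv, fx$model, seed = 5)
  s2 <- sample_joint_node_states(fx$tree, fx$tv, fx$model, seed = 5)
  expect_identical(s1, s2)
  # observed tips always receive their observed state
  obs <- vapply(fx$tv, function(v) cutting_states()[which.max(v)],
                character(1))
  certain <- vapply(fx$tv, function(v) sum(v > 0) == 1, logical(1))
  expect_equal(s1[seq_len(10)][certain], unname(obs[certain]),
               ignore_attr = TRUE)

  # q -> 0 with monomorphic tips: everything fixed in that state
  tvd <- lapply(fx$tv, function(v) c(1, 0, 0))
  frozen <- sample_joint_node_states(fx$tree, tvd,
                                     mk_model(cutting_states(), 1e-9),
                                     seed = 1)
  expect_true(all(frozen == "dicot"))
})

test_that("sampled node-state frequencies converge to the ASR marginals", {
  fx <- .map_fixture()
  rec <- marginal_asr_rerooting(fx$tree, fx$tv, fx$model)
  lik <- pruning_log_likelihood(fx$tree, fx$tv, fx$model)
  n_draw <- 10000
  counts <- matrix(0, nrow(rec$probs), 3,
                   dimnames = list(NULL, cutting_states()))
  set.seed(99)
  for (i in seq_len(n_draw)) {
    st <- cutevo:::.sample_nodes(lik)
    counts[cbind(seq_along(st), match(st, cutting_states()))] <-
      counts[cbind(seq_along(st), match(st, cutting_states()))] + 1
  }
  freq <- counts / n_draw
  tv_dist <- apply(abs(freq - rec$probs), 1, sum) / 2
  expect_lt(max(tv_dist), 0.02)
})

test_that("branch path sampling honours endpoints and the t = 0 edge cases", {
  model <- mk_model(cutting_states(), 0.5)
  seg0 <- sample_branch_history("grass", "grass", 0, model)
  expect_equal(seg0, c(grass = 0))
  expect_error(sample_branch_history("grass", "dicot", 0, model),
               "impossible")
  withr::local_seed(17)
  for (i in 1:200) {
    a <- sample(cutting_states(), 1)
    b <- sample(cutting_states(), 1)
    t <- stats::runif(1, 0.1, 3)
    segs <- sample_branch_history(a, b, t, model)
    expect_equal(sum(segs), t, tolerance = 1e-12)
    expect_equal(names(segs)[1], a)
    expect_equal(names(segs)[length(segs)], b)
    if (a != b) expect_gte(length(segs), 2)
    # merged segments: no consecutive repeats
    if (length(segs) > 1) {
      expect_true(all(names(segs)[-1] != names(segs)[-length(segs)]))
    }
  }
})

test_that("uniformization matches a rejection sampler on transition counts", {
  k <- 2; q <- 1; t <- 1
  model <- mk_model(k, q)
  n <- 20000
  set.seed(123)
  uni <- vapply(seq_len(n), function(i) {
    length(sample_branch_history(1, 2, t, model)) - 1L
  }, integer(1))
  rej <- vapply(seq_len(n), function(i) {
    rejection_path_transitions(1, 2, t, k, q)
  }, numeric(1))
  # means within 3 pooled standard errors
  se <- sqrt(stats::var(uni) / n + stats::var(rej) / n)
  expect_lt(abs(mean(uni) - mean(rej)), 3 * se)
  # full distributions: chi-square on pooled categories
  cap <- max(uni, rej)
  tab <- rbind(tabulate(uni + 1, cap + 1), tabulate(rej + 1, cap + 1))
  keep <- colSums(tab) >= 10
  tab <- cbind(tab[, keep], rowSums(tab[, !keep, drop = FALSE]))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("stochastic maps satisfy the history invariants in bulk", {
  fx <- .map_fixture()
  maps <- stochastic_map(fx$tree, fx$tv, fx$model, nsim = 1000, seed = 31)
  expect_length(maps, 1000)
  obs <- vapply(fx$tv, function(v) cutting_states()[which.max(v)],
                character(1))
  certain <- which(vapply(fx$tv, function(v) sum(v > 0) == 1, logical(1)))
  max_sum_dev <- 0
  endpoint_ok <- TRUE
  tips_ok <- TRUE
  for (h in maps) {
    sums <- vapply(h$edge_maps, sum, numeric(1))
    max_sum_dev <- max(max_sum_dev, max(abs(sums - fx$tree$edge.length)))
    first <- vapply(h$edge_maps, function(m) names(m)[1], character(1))
    last <- vapply(h$edge_maps, function(m) names(m)[length(m)], character(1))
    endpoint_ok <- endpoint_ok &&
      identical(first, h$node_states[fx$tree$edge[, 1]]) &&
      identical(last, h$node_states[fx$tree$edge[, 2]])
    tips_ok <- tips_ok &&
      identical(unname(h$node_states[certain]), unname(obs[certain]))
  }
  expect_lt(max_sum_dev, 1e-9)
  expect_true(endpoint_ok)
  expect_true(tips_ok)
})

test_that("same seed gives byte-identical SIMMAP output; seeds are substreamed", {
  fx <- .map_fixture()
  m1 <- stochastic_map(fx$tree, fx$tv, fx$model, nsim = 4, seed = 20)
  m2 <- stochastic_map(fx$tree, fx$tv, fx$model, nsim = 4, seed = 20)
  expect_identical(vapply(m1, write_simmap, character(1)),
                   vapply(m2, write_simmap, character(1)))
  # realization i depends only on (seed, i), so prefixes of longer runs
  # agree, and different root seeds give different histories
  m1b <- stochastic_map(fx$tree, fx$tv, fx$model, nsim = 2, seed = 20)
  expect_identical(write_simmap(m1b[[2]]), write_simmap(m1[[2]]))
  m3 <- stochastic_map(fx$tree, fx$tv, fx$model, nsim = 4, seed = 21)
  expect_false(identical(vapply(m3, write_simmap, character(1)),
                         vapply(m1, write_simmap, character(1))))
  expect_error(stochastic_map(fx$tree, fx$tv, fx$model, nsim = 2),
               "seed")
})

test_that("map summaries count transitions and dwell times correctly", {
  # hand-built two-branch history
  tr <- parse_newick("(A:1,B:2);")
  maps <- list(c(dicot = 0.4, grass = 0.6),
               c(dicot = 1.5, grass = 0.25, dicot = 0.25))
  names(maps[[2]]) <- c("dicot", "grass", "dicot")
  h <- cutevo:::new_character_history(tr, maps,
                                      c("grass", "dicot", "dicot"),
                                      cutting_states(), seed = 0L)
  s <- summarize_map(h)
  expect_equal(s$counts["dicot", "grass"], 2)
  expect_equal(s$counts["grass", "dicot"], 1)
  expect_equal(sum(s$dwell), sum(tr$edge.length))
  expect_equal(unname(s$dwell["dicot"]), 0.4 + 1.5 + 0.25)
  expect_equal(unname(s$into["grass"]), 2)
  td <- tidy(s)
  expect_equal(td$transitions_into[td$state == "grass"], 2)

  # no-transition history
  h0 <- cutevo:::new_character_history(
    tr, list(c(dicot = 1), c(dicot = 2)), c("dicot", "dicot", "dicot"),
    cutting_states(), seed = 0L)
  s0 <- summarize_map(h0)
  expect_equal(sum(s0$counts), 0)
  expect_equal(unname(s0$dwell["dicot"]), 3)
})

test_that("long-branch dwell fractions approach the uniform stationary law", {
  model <- mk_model(cutting_states(), 1)
  t <- 50  # k q t >> 1
  set.seed(7)
  n <- 2000
  dwell <- matrix(0, n, 3, dimnames = list(NULL, cutting_states()))
  for (i in seq_len(n)) {
    b <- sample(cutting_states(), 1)
    segs <- sample_branch_history("dicot", b, t, model)
    for (s in cutting_states()) dwell[i, s] <- sum(segs[names(segs) == s])
  }
  frac <- colMeans(dwell) / t
  se <- apply(dwell / t, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(frac - 1 / 3) < 3 * se + 0.01))
})
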