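test_that("ER rate matrix construction follows the definition", {
  expect_equal(build_er_q(2, 1), matrix(c(-1, 1, 1, -1), 2))
  Q <- build_er_q(3, 0.5)
  expect_equal(diag(Q), rep(-1, 3))
  expect_equal(Q[row(Q) != col(Q)], rep(0.5, 6))
  expect_equal(rowSums(Q), rep(0, 3))
  expect_error(build_er_q(1, 1), "k")
  expect_error(build_er_q(3, 0), "positive")
  expect_error(mk_model(cutting_states(), -1), "positive")
})

test_that("transition probabilities match the closed form, limits, and the series expm", {
  expect_equal(transition_matrix(build_er_q(3, 0.7), 0), diag(3))
  # stationary limit
  P <- transition_matrix(build_er_q(3, 1), 50)
  expect_lt(max(abs(P - 1 / 3)), 1e-12)
  # hand-derived value
  expect_equal(transition_matrix(build_er_q(2, 1), 1)[1, 1],
               1 / 2 + exp(-2) / 2, tolerance = 1e-14)
  # independent series matrix exponential across regimes
  for (k in 2:4) {
    for (kqt in c(0.01, 0.5, 2, 10, 100)) {
      q <- 0.3
      t <- kqt / (k * q)
      Q <- build_er_q(k, q)
      expect_lt(max(abs(transition_matrix(Q, t) - series_expm(Q * t))), 1e-10)
    }
  }
  expect_error(transition_matrix(build_er_q(2, 1), -1), "nonnegative")
})

test_that("Chapman-Kolmogorov holds: P(s) P(t) = P(s+t)", {
  withr::local_seed(4)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    q <- stats::runif(1, 0.05, 2)
    s <- stats::runif(1, 0, 3)
    t <- stats::runif(1, 0, 3)
    Q <- build_er_q(k, q)
    expect_lt(max(abs(transition_matrix(Q, s) %*% transition_matrix(Q, t) -
                        transition_matrix(Q, s + t))), 1e-10)
  }
})

test_that("pruning log-likelihood equals exhaustive enumeration", {
  # the two-tip closed form first
  t <- 0.7; q <- 0.4
  tr <- parse_newick(sprintf("(A:%g,B:%g);", t, t))
  model <- mk_model(2, q)
  P <- transition_matrix(model$Q, t)
  manual <- log(sum(model$pi * P[, 1]^2))
  got <- pruning_log_likelihood(tr, list(A = c(1, 0), B = c(1, 0)), model)
  expect_equal(got$log_likelihood, manual, tolerance = 1e-12)

  # randomized battery against enumeration over internal-state assignments
  withr::local_seed(42)
  for (i in 1:30) {
    k <- sample(2:3, 1)
    tr <- random_tree(sample(3:7, 1))
    tv <- random_tip_vectors(tr, k, p_ambiguous = 0.15)
    model <- mk_model(k, stats::runif(1, 0.05, 1.5))
    ll <- pruning_log_likelihood(tr, tv, model)$log_likelihood
    oracle <- enum_log_likelihood(tr, tv, model)
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("all-ones tip vectors give likelihood one, zero vectors error", {
  tr <- random_tree(6)
  tv <- lapply(setNames(tr$tip.label, tr$tip.label), function(x) rep(1, 3))
  ll <- pruning_log_likelihood(tr, tv, mk_model(3, 0.5))
  expect_equal(ll$log_likelihood, 0, tolerance = 1e-12)
  tv[[2]] <- c(0, 0, 0)
  expect_error(pruning_log_likelihood(tr, tv, mk_model(3, 0.5)),
               "all-zero")
})

test_that("log-likelihood is invariant to re-rooting (ER reversibility)", {
  withr::local_seed(9)
  for (i in 1:8) {
    tr <- random_tree(sample(5:12, 1))
    k <- 3
    tv <- random_tip_vectors(tr, k)
    model <- mk_model(k, stats::runif(1, 0.1, 1))
    base <- pruning_log_likelihood(tr, tv, model)$log_likelihood
    nodes <- ape::Ntip(tr) + seq_len(ape::Nnode(tr))[-1]
    for (nd in sample(nodes, min(3, length(nodes)))) {
      rr <- ape::root(tr, node = nd, resolve.root = FALSE)
      expect_equal(pruning_log_likelihood(rr, tv, model)$log_likelihood,
                   base, tolerance = 1e-10)
    }
  }
})

test_that("the fitted rate matches a dense grid-search argmax", {
  tr <- parse_newick("(A:1,B:1);")
  tv <- list(A = c(1, 0), B = c(0, 1))
  fit <- fit_er_rate(tr, tv, 2)
  qs <- exp(seq(log(fit$bounds["q_lo"]), log(fit$bounds["q_hi"]),
                length.out = 1e4))
  ll <- vapply(qs, function(q) {
    pruning_log_likelihood(tr, tv, mk_model(2, q))$log_likelihood
  }, numeric(1))
  # on a 2-tip clock tree with opposite states the profile rises to a
  # saturation plateau; the optimizer must attain the grid maximum
  expect_gte(fit$log_likelihood, max(ll) - 1e-9)

  # concordant cherries with discordant states across them: sharp interior
  # optimum, where the argmax itself is identifiable
  tr2 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tv2 <- list(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1))
  fit2 <- fit_er_rate(tr2, tv2, 2)
  ll2 <- vapply(qs, function(q) {
    pruning_log_likelihood(tr2, tv2, mk_model(2, q))$log_likelihood
  }, numeric(1))
  i_max <- which.max(ll2)
  spacing <- qs[i_max] * log(fit2$bounds[["q_hi"]] / fit2$bounds[["q_lo"]]) / 1e4
  expect_lt(abs(fit2$q_hat - qs[i_max]), 3 * spacing)
  expect_gte(fit2$log_likelihood, max(ll2) - 1e-9)
})

test_that("invariant data yields the boundary rate with a warning", {
  tr <- random_tree(8)
  tv <- lapply(setNames(tr$tip.label, tr$tip.label), function(x) c(1, 0, 0))
  expect_warning(fit <- fit_er_rate(tr, tv), "no transitions")
  expect_equal(fit$q_hat, unname(fit$bounds["q_lo"]))
  expect_true(fit$at_bound)
})

test_that("fitted rate agrees with an independent ER fitter on the scenario", {
  skip_if_not_installed("phytools")
  sc <- scenario_fixture()
  tv <- scenario_tip_vectors(sc)
  fit <- fit_er_rate(sc$tree, tv)
  x <- do.call(rbind, tv)
  colnames(x) <- cutting_states()
  ref <- phytools::fitMk(sc$tree, x, model = "ER")
  expect_equal(fit$q_hat, ref$rates[1], tolerance = 1e-4)
  expect_equal(fit$log_likelihood, ref$logLik, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom style", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tv <- list(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1))
  fit <- fit_er_rate(tr, tv, 2)
  td <- tidy(fit)
  expect_equal(td$term, "q")
  expect_equal(td$estimate, fit$q_hat)
  gl <- glance(fit)
  expect_equal(gl$n_tips, 4)
  expect_false(gl$at_bound)
})
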