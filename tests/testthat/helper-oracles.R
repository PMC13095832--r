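# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Exhaustive-enumeration Mk log-likelihood: sum over every assignment of
# states to internal nodes; tip observations are marginalized directly.
# Only feasible for small trees (k^Nnode terms).
enum_log_likelihood <- function(tree, tip_vectors, model) {
  k <- model$k
  n_tip <- ape::Ntip(tree)
  n_int <- ape::Nnode(tree)
  tipmat <- do.call(rbind, tip_vectors[tree$tip.label])
  pmat <- lapply(seq_len(nrow(tree$edge)),
                 function(e) transition_matrix(model$Q, tree$edge.length[e]))
  int_ids <- n_tip + seq_len(n_int)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    state_of <- function(node) assign[node - n_tip]
    term <- model$pi[state_of(n_tip + 1L)]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sp <- state_of(par)
      if (ch <= n_tip) {
        term <- term * sum(pmat[[e]][sp, ] * tipmat[ch, ])
      } else {
        term <- term * pmat[[e]][sp, state_of(ch)]
      }
      if (term == 0) break
    }
    total <- total + term
  }
  log(total)
}

# Forward-simulation rejection sampler for endpoint-conditioned ER paths:
# simulate the unconditioned chain on [0, t] from state a, keep draws that
# end in b. Returns the number of real transitions of one accepted path.
rejection_path_transitions <- function(a, b, t, k, q, max_tries = 1e6) {
  rate_out <- (k - 1) * q
  for (i in seq_len(max_tries)) {
    s <- a; tt <- 0; n_trans <- 0
    repeat {
      w <- stats::rexp(1, rate_out)
      if (tt + w >= t) break
      tt <- tt + w
      cand <- setdiff(seq_len(k), s)
      s <- cand[sample.int(length(cand), 1)]
      n_trans <- n_trans + 1
    }
    if (s == b) return(n_trans)
  }
  stop("rejection sampler failed to accept")
}

# Random rooted tree with uniform branch lengths (wrapper kept so the
# random-instance batteries read uniformly).
random_tree <- function(n_tips, min_len = 0.1, max_len = 2) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# Random tip observation vectors: mostly certain states, some ambiguous.
random_tip_vectors <- function(tree, k, p_ambiguous = 0.1) {
  vecs <- lapply(tree$tip.label, function(l) {
    if (stats::runif(1) < p_ambiguous) rep(1, k)
    else { v <- numeric(k); v[sample.int(k, 1)] <- 1; v }
  })
  names(vecs) <- tree$tip.label
  vecs
}

# Matrix exponential by scaling-and-squaring on the series (independent of
# the closed form and of eigendecomposition).
series_expm <- function(A, terms = 30) {
  nrm <- max(abs(A))
  s <- max(0, ceiling(log2(max(nrm, 1e-16))) + 4)
  As <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(terms)) {
    term <- term %*% As / i
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# Study-scenario fixture shared across files (built once per test run).
scenario_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- study_scenario()
    cache
  }
})
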