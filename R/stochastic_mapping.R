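# Constructor shared by stochastic_map(), simulate_mk_history() and
# read_simmap(). edge_maps follows the SIMMAP convention: one named numeric
# vector per edge (names = states, values = durations, parent-to-child).
new_character_history <- function(tree, edge_maps, node_states, state_labels,
                                  seed) {
  structure(
    list(tree = tree, edge_maps = edge_maps, node_states = node_states,
         state_labels = state_labels, seed = seed),
    class = "character_history"
  )
}

#' @export
print.character_history <- function(x, ...) {
  n_trans <- sum(vapply(x$edge_maps, length, integer(1)) - 1L)
  cat("Character history on", ape::Ntip(x$tree), "tips:",
      n_trans, "transition(s); seed", x$seed, "\n")
  invisible(x)
}

#' Sample node states jointly, conditioned on the tip data
#'
#' The node-state half of stochastic character mapping: the root state is
#' drawn proportionally to `pi_s D_root(s)`, then each child state in
#' preorder proportionally to `P(parent_state -> s, t_child) D_child(s)`,
#' where `D` are the pruning partials. Tips whose observation is a certain
#' state always receive it.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_vectors Named list or matrix of length-k observation vectors.
#' @param model An `mk_model`.
#' @param seed Optional integer; when given the draw is reproducible.
#' @return Character vector of sampled states, indexed by ape node id.
#' @export
sample_joint_node_states <- function(tree, tip_vectors, model, seed = NULL) {
  lik <- pruning_log_likelihood(tree, tip_vectors, model)
  if (!is.null(seed)) set.seed(seed)
  .sample_nodes(lik)
}

# Internal: joint draw given a prepared mk_lik (reuses partials).
.sample_nodes <- function(lik) {
  model <- lik$model
  tree <- lik$tree
  k <- model$k
  D <- lik$partials
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  states <- integer(n_tip + ape::Nnode(tree))
  w <- model$pi * D[root, ]
  states[root] <- sample.int(k, 1, prob = w)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  for (e in rev(seq_len(nrow(edge)))) {   # preorder: parents first
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- .er_pmat(k, model$q, elen[e])
    w <- P[states[par], ] * D[ch, ]
    states[ch] <- sample.int(k, 1, prob = w)
  }
  model$state_labels[states]
}

# Uniformization setup for endpoint-conditioned ER path sampling on an
# interval of length t. Dominating rate Lambda = max_i |Q_ii| = (k-1) q;
# the uniformized jump chain R = I + Q/Lambda has zero diagonal for ER.
# Precomputes R powers and the conditioned jump-count distribution
# p(n | a, b) propto Pois(n; Lambda t) R^n[a, b].
.unif_cache <- new.env(parent = emptyenv())

.unif_setup <- function(k, q, t, tol = 1e-13) {
  key <- paste(k, q, t, sep = "|")
  hit <- .unif_cache[[key]]
  if (!is.null(hit)) return(hit)
  lam <- (k - 1) * q
  R <- matrix(1 / (k - 1), k, k)
  diag(R) <- 0
  n_cap <- max(4, stats::qpois(1 - 1e-14, lam * t) + 4)
  Rpow <- vector("list", n_cap + 1)
  Rpow[[1]] <- diag(k)
  for (n in seq_len(n_cap)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  pois <- stats::dpois(0:n_cap, lam * t)
  list(k = k, t = t, R = R, Rpow = Rpow, pois = pois, n_cap = n_cap)
}

# One endpoint-conditioned path given a setup; returns integer state path
# and jump times. a, b are state indices.
.unif_path <- function(su, a, b) {
  w <- su$pois * vapply(su$Rpow, function(M) M[a, b], numeric(1))
  tot <- sum(w)
  if (tot <= 0) stop("impossible endpoint pair under the model", call. = FALSE)
  n <- sample.int(su$n_cap + 1, 1, prob = w) - 1L
  if (n == 0) return(list(states = a, times = numeric(0)))
  times <- sort(stats::runif(n, 0, su$t))
  states <- integer(n + 1)
  states[1] <- a
  if (n >= 2) {
    for (j in seq_len(n - 1)) {
      w2 <- su$R[states[j], ] * su$Rpow[[n - j + 1]][, b]
      states[j + 1] <- sample.int(su$k, 1, prob = w2)
    }
  }
  states[n + 1] <- b
  list(states = states, times = times)
}

# Collapse a jump path into merged (state, duration) segments.
.path_segments <- function(states, times, t, labels) {
  bounds <- c(0, times, t)
  durs <- diff(bounds)
  st <- states
  keep <- c(TRUE, st[-1] != st[-length(st)])
  grp <- cumsum(keep)
  segs <- tapply(durs, grp, sum)
  stats::setNames(as.numeric(segs), labels[st[keep]])
}

#' Sample an endpoint-conditioned CTMC path on one branch
#'
#' Draws a complete state path of the Mk chain on `[0, t]` that starts in
#' `s_a` and ends in `s_b`, from the exact conditional distribution, via
#' uniformization: the number of candidate jumps comes from the
#' Poisson mixture conditioned on the endpoints, jump times are uniform
#' order statistics, and jump states follow the uniformized chain bridged
#' to the endpoint. Consecutive equal states are merged, so only real
#' transitions appear in the output.
#'
#' @param s_a,s_b Start and end states (labels or indices).
#' @param t Branch length (>= 0).
#' @param model An `mk_model`.
#' @param seed Optional integer seed.
#' @return Named numeric vector of segment durations (names = states,
#'   parent-to-child order) summing to `t`.
#' @examples
#' sample_branch_history("grass", "dicot", 1, mk_model(cutting_states(), 0.5),
#'                       seed = 1)
#' @export
sample_branch_history <- function(s_a, s_b, t, model, seed = NULL) {
  stopifnot(inherits(model, "mk_model"))
  labels <- model$state_labels
  a <- if (is.character(s_a)) match(s_a, labels) else as.integer(s_a)
  b <- if (is.character(s_b)) match(s_b, labels) else as.integer(s_b)
  if (is.na(a) || is.na(b)) stop("unknown state label", call. = FALSE)
  if (t < 0) stop("branch length must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (t == 0) {
    if (a != b) stop("impossible path: different endpoints on a ",
                     "zero-length branch", call. = FALSE)
    return(stats::setNames(0, labels[a]))
  }
  su <- .unif_setup(model$k, model$q, t)
  p <- .unif_path(su, a, b)
  .path_segments(p$states, p$times, t, labels)
}

# Derive the substream seed for counter i under a root seed: one step of a
# Lehmer generator keyed by the seed, plus the counter (documented scheme;
# independent of execution order, and distinct root seeds diverge).
.substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i - 1) %% 2147483647)
}

#' Stochastic character mapping
#'
#' Samples `nsim` complete character histories conditioned on the tip data:
#' node states are drawn jointly from their exact conditional distribution
#' (root downward, using the pruning partials), then every branch is filled
#' in with an endpoint-conditioned CTMC path by uniformization. Histories
#' are reproducible: realization `i` uses the substream seed
#' `(48271 * seed + i - 1) mod (2^31 - 1)`, so prefixes of longer runs
#' agree and distinct root seeds give distinct streams.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_vectors Named list or matrix of length-k observation vectors.
#' @param model An `mk_model` (typically at the fitted rate `q_hat`).
#' @param nsim Number of realizations (>= 1; 100 is the conventional
#'   default for accumulation summaries).
#' @param seed Integer root seed (required, for reproducibility).
#' @return A list of `character_history` objects with class
#'   `character_history_set`; attributes `tree`, `model`, `seed`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tv <- list(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1))
#' maps <- stochastic_map(tr, tv, mk_model(2, 0.4), nsim = 3, seed = 7)
#' @export
stochastic_map <- function(tree, tip_vectors, model, nsim = 100, seed) {
  stopifnot(nsim >= 1)
  if (missing(seed) || is.null(seed)) {
    stop("stochastic_map requires an explicit integer seed", call. = FALSE)
  }
  lik <- pruning_log_likelihood(tree, tip_vectors, model)
  labels <- model$state_labels
  k <- model$k
  edge <- tree$edge
  elen <- tree$edge.length
  setups <- lapply(elen, function(t) if (t > 0) .unif_setup(k, model$q, t) else NULL)

  histories <- lapply(seq_len(nsim), function(i) {
    set.seed(.substream_seed(seed, i))
    node_states <- .sample_nodes(lik)
    maps <- vector("list", nrow(edge))
    for (e in seq_len(nrow(edge))) {
      a <- match(node_states[edge[e, 1]], labels)
      b <- match(node_states[edge[e, 2]], labels)
      if (elen[e] == 0) {
        if (a != b) stop("sampled different endpoint states on a ",
                         "zero-length branch", call. = FALSE)
        maps[[e]] <- stats::setNames(0, labels[a])
      } else {
        p <- .unif_path(setups[[e]], a, b)
        maps[[e]] <- .path_segments(p$states, p$times, elen[e], labels)
      }
    }
    new_character_history(tree, maps, node_states, labels,
                          seed = .substream_seed(seed, i))
  })
  structure(histories, class = c("character_history_set", "list"),
            tree = tree, model = model, seed = seed)
}

#' @export
print.character_history_set <- function(x, ...) {
  cat("Set of", length(x), "stochastic character maps on",
      ape::Ntip(attr(x, "tree")), "tips (seed", attr(x, "seed"), ")\n")
  invisible(x)
}

#' Summarize one character history
#'
#' Transition counts, per-state dwell times, and per-state counts of
#' transitions *into* each state, read off the segment lists.
#'
#' @param history A `character_history`.
#' @return Object of class `map_summary`: `counts` (k x k matrix of
#'   transition counts, zero diagonal), `dwell` (named per-state total
#'   time), `into` (named per-state transition-into counts).
#' @export
summarize_map <- function(history) {
  stopifnot(inherits(history, "character_history"))
  labels <- history$state_labels
  k <- length(labels)
  counts <- matrix(0L, k, k, dimnames = list(from = labels, to = labels))
  dwell <- stats::setNames(numeric(k), labels)
  for (m in history$edge_maps) {
    st <- names(m)
    for (j in seq_along(m)) dwell[st[j]] <- dwell[st[j]] + m[j]
    if (length(m) > 1) {
      for (j in seq_len(length(m) - 1)) {
        counts[st[j], st[j + 1]] <- counts[st[j], st[j + 1]] + 1L
      }
    }
  }
  structure(list(counts = counts, dwell = dwell, into = colSums(counts)),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Stochastic-map summary:", sum(x$counts), "transitions\n")
  print(x$counts)
  cat("dwell times:\n"); print(round(x$dwell, 4))
  invisible(x)
}

#' Tidy per-state map summary
#'
#' @param x A `map_summary`.
#' @param ... Unused.
#' @return Tibble with `state`, `dwell`, `transitions_into`.
#' @exportS3Method generics::tidy
tidy.map_summary <- function(x, ...) {
  tibble::tibble(state = names(x$dwell), dwell = unname(x$dwell),
                 transitions_into = unname(x$into[names(x$dwell)]))
}
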