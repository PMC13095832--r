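#' Construct an equal-rates Mk model
#'
#' The Mk model is a continuous-time Markov chain on k discrete character
#' states. Under the equal-rates (ER) parameterization every between-state
#' transition shares one instantaneous rate `q` (per time unit, here per
#' Ma), so `Q[i, j] = q` for `i != j` and `Q[i, i] = -(k - 1) q`. The root
#' prior defaults to the uniform distribution, which is the ER stationary
#' distribution and keeps the chain time-reversible — a requirement of the
#' re-rooting ancestral-state method.
#'
#' @param state_labels Ordered character vector of state names (k >= 2), or
#'   an integer k (labels become `s1..sk`).
#' @param q Positive transition rate.
#' @param root_prior Length-k probability vector; default uniform.
#' @return An object of class `mk_model`: list with `k`, `state_labels`,
#'   `q`, `Q`, `pi`.
#' @examples
#' mk_model(cutting_states(), q = 0.05)
#' @export
mk_model <- function(state_labels, q, root_prior = NULL) {
  if (is.numeric(state_labels) && length(state_labels) == 1) {
    state_labels <- paste0("s", seq_len(state_labels))
  }
  k <- length(state_labels)
  if (k < 2) stop("an Mk model needs k >= 2 states", call. = FALSE)
  if (anyDuplicated(state_labels)) stop("duplicate state labels", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1 || !is.finite(q) || q <= 0) {
    stop("rate q must be a single positive number", call. = FALSE)
  }
  pi <- if (is.null(root_prior)) rep(1 / k, k) else root_prior
  if (length(pi) != k || any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("root_prior must be a length-k probability vector", call. = FALSE)
  }
  structure(
    list(k = k, state_labels = state_labels, q = q,
         Q = build_er_q(k, q), pi = pi),
    class = "mk_model"
  )
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk model (equal rates), k =", x$k, "states:",
      paste(x$state_labels, collapse = ", "), "\n")
  cat("  q =", format(x$q, digits = 6), "per time unit;  root prior:",
      paste(format(x$pi, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Equal-rates rate matrix
#'
#' @param k Number of states (>= 2).
#' @param q Positive rate of each off-diagonal transition.
#' @return The k x k rate matrix with `q` off-diagonal and `-(k-1) q` on the
#'   diagonal (rows sum to zero).
#' @examples
#' build_er_q(3, 0.5)
#' @export
build_er_q <- function(k, q) {
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k)) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || !is.finite(q)) {
    stop("rate q must be positive", call. = FALSE)
  }
  Q <- matrix(q, k, k)
  diag(Q) <- -(k - 1) * q
  Q
}

# Closed-form ER transition probabilities:
#   P_ii(t) = 1/k + (1 - 1/k) exp(-k q t),  P_ij(t) = (1 - exp(-k q t)) / k
.er_pmat <- function(k, q, t) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- (1 - e) / k + e
  P
}

# Is Q an ER matrix? (all off-diagonals equal, rows sum to zero)
.is_er_q <- function(Q, tol = 1e-12) {
  off <- Q[row(Q) != col(Q)]
  scale <- max(abs(Q), 1e-300)
  diff(range(off)) <= tol * scale && all(abs(rowSums(Q)) <= 1e-10 * scale)
}

#' CTMC transition probability matrix
#'
#' Computes `P(t) = exp(Q t)`. For an equal-rates `Q` the exact closed form
#' is used; any other rate matrix falls back to an eigendecomposition.
#'
#' @param Q A k x k rate matrix (rows summing to zero), or an `mk_model`.
#' @param t Nonnegative elapsed time.
#' @return The k x k stochastic matrix `P(t)`.
#' @examples
#' transition_matrix(build_er_q(2, 1), 1)[1, 1] # 1/2 + exp(-2)/2
#' @export
transition_matrix <- function(Q, t) {
  if (inherits(Q, "mk_model")) Q <- Q$Q
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("time t must be a single nonnegative number", call. = FALSE)
  }
  k <- nrow(Q)
  if (t == 0) return(diag(k))
  if (.is_er_q(Q)) {
    q <- Q[1, 2]
    return(.er_pmat(k, q, t))
  }
  ev <- eigen(Q)
  P <- Re(ev$vectors %*% diag(exp(ev$values * t), k) %*% solve(ev$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Align tip vectors (named list or matrix) to tree tip order; validate.
.tip_matrix <- function(tree, tip_vectors, k) {
  n_tip <- ape::Ntip(tree)
  if (is.list(tip_vectors)) {
    miss <- setdiff(tree$tip.label, names(tip_vectors))
    if (length(miss)) {
      stop("tips without observation vectors: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    m <- do.call(rbind, tip_vectors[tree$tip.label])
  } else {
    m <- tip_vectors[tree$tip.label, , drop = FALSE]
  }
  if (ncol(m) != k) stop("tip vectors have wrong number of states", call. = FALSE)
  if (any(m < 0)) stop("tip weight vectors must be nonnegative", call. = FALSE)
  if (any(rowSums(m) == 0)) {
    bad <- tree$tip.label[rowSums(m) == 0]
    stop("all-zero (impossible) observation at tip(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(m) <- tree$tip.label
  m
}

# Postorder pruning pass. Returns scaled per-node conditional likelihoods
# ("partials"), per-node accumulated log-scalers, and the total logL.
# D_n(s) = prod over children c of sum_{s'} P_{s s'}(t_c) D_c(s').
.prune <- function(tree, tipmat, model) {
  k <- model$k
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + ape::Nnode(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, n_all, k)
  L[seq_len(n_tip), ] <- tipmat
  logscale <- numeric(n_all)
  edge <- po$edge
  elen <- po$edge.length
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]
    ch <- edge[e, 2]
    P <- .er_pmat(k, model$q, elen[e])
    v <- as.vector(P %*% L[ch, ])
    L[par, ] <- L[par, ] * v
    logscale[par] <- logscale[par] + logscale[ch]
    m <- max(L[par, ])
    if (m <= 0 || !is.finite(m)) {
      stop("zero likelihood encountered during pruning (conflicting ",
           "observations on a zero-length path?)", call. = FALSE)
    }
    L[par, ] <- L[par, ] / m
    logscale[par] <- logscale[par] + log(m)
  }
  root <- n_tip + 1L
  loglik <- log(sum(model$pi * L[root, ])) + logscale[root]
  list(partials = L, logscale = logscale, log_likelihood = loglik,
       edge = edge, edge_length = elen)
}

#' Pruning log-likelihood of tip data under an Mk model
#'
#' Felsenstein's pruning algorithm: a postorder pass computing per-node
#' conditional likelihood vectors, with per-node rescaling so deep trees do
#' not underflow. The likelihood is
#' `L = sum_s pi_s D_root(s)` where `D_n(s)` conditions on all observations
#' below node n.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_vectors Named list (or matrix with tip-label rownames) of
#'   length-k observation weight vectors; see [tip_state_vectors()].
#' @param model An `mk_model`.
#' @return An object of class `mk_lik`: `log_likelihood`, `partials`
#'   (scaled per-node conditional likelihoods, rows indexed by ape node id),
#'   `logscale`, `model`, `tree`.
#' @export
pruning_log_likelihood <- function(tree, tip_vectors, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mk_model"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  tipmat <- .tip_matrix(tree, tip_vectors, model$k)
  pr <- .prune(tree, tipmat, model)
  structure(
    list(log_likelihood = pr$log_likelihood, partials = pr$partials,
         logscale = pr$logscale, model = model, tree = tree,
         tip_matrix = tipmat),
    class = "mk_lik"
  )
}

#' @export
print.mk_lik <- function(x, ...) {
  cat("Mk pruning likelihood: logL =", format(x$log_likelihood, digits = 8),
      " (k =", x$model$k, ", q =", format(x$model$q, digits = 6), ")\n")
  invisible(x)
}

#' Maximum-likelihood estimate of the equal-rates transition rate
#'
#' Profiles the pruning log-likelihood over the single ER rate `q` by
#' bounded one-dimensional optimization on the log scale. The search
#' bracket is scale-free: `q_lo = 1e-8 / T` to `q_hi = 1e3 / T` with `T`
#' the root age (root-to-tip depth), spanning effectively-frozen to
#' saturated regimes. When every tip carries the same certain state the
#' likelihood is monotone decreasing in `q`; the boundary estimate `q_lo`
#' is returned with a warning.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_vectors As in [pruning_log_likelihood()].
#' @param state_labels State order (defaults to [cutting_states()]); an
#'   integer k is also accepted.
#' @param root_prior Optional root prior (default uniform).
#' @return An object of class `mk_fit`: `q_hat`, `log_likelihood`, `model`
#'   (an `mk_model` at `q_hat`), `n_tips`, `bounds`, plus the `mk_lik`
#'   pieces evaluated at the optimum.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tv <- list(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1))
#' fit_er_rate(tr, tv, state_labels = 2)
#' @export
fit_er_rate <- function(tree, tip_vectors, state_labels = cutting_states(),
                        root_prior = NULL) {
  if (is.numeric(state_labels) && length(state_labels) == 1) {
    state_labels <- paste0("s", seq_len(state_labels))
  }
  k <- length(state_labels)
  tipmat <- .tip_matrix(tree, tip_vectors, k)
  if (sum(tree$edge.length) <= 0) stop("tree has zero total length", call. = FALSE)
  T_root <- max(ape::node.depth.edgelength(tree))
  q_lo <- 1e-8 / T_root
  q_hi <- 1e3 / T_root

  obj <- function(logq) {
    model <- mk_model(state_labels, exp(logq), root_prior)
    .prune(tree, tipmat, model)$log_likelihood
  }

  # No variation: all tips certain and identical -> monotone likelihood.
  certain <- rowSums(tipmat > 0) == 1
  invariant <- all(certain) &&
    length(unique(apply(tipmat, 1, which.max))) == 1
  if (invariant) {
    warning("all tips share one certain state; no transitions observed - ",
            "returning the lower-bound rate estimate", call. = FALSE)
    q_hat <- q_lo
  } else {
    opt <- stats::optimize(obj, interval = c(log(q_lo), log(q_hi)),
                           maximum = TRUE, tol = 1e-10)
    q_hat <- exp(opt$maximum)
  }
  model <- mk_model(state_labels, q_hat, root_prior)
  lik <- pruning_log_likelihood(tree, tip_vectors = tipmat, model = model)
  structure(
    list(q_hat = q_hat, log_likelihood = lik$log_likelihood, model = model,
         n_tips = ape::Ntip(tree), bounds = c(q_lo = q_lo, q_hi = q_hi),
         at_bound = invariant, lik = lik, tree = tree, tip_matrix = lik$tip_matrix),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Equal-rates Mk fit:", x$n_tips, "tips, k =", x$model$k, "states\n")
  cat("  q_hat =", format(x$q_hat, digits = 6),
      "  logL =", format(x$log_likelihood, digits = 8),
      if (x$at_bound) "  [boundary estimate]" else "", "\n")
  invisible(x)
}

#' Tidy an Mk fit
#'
#' @param x An `mk_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(term = "q", estimate = x$q_hat)
}

#' One-row model summary of an Mk fit
#'
#' @param x An `mk_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `q_hat`, `k`, `n_tips`, `at_bound`.
#' @exportS3Method generics::glance
glance.mk_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, q_hat = x$q_hat,
                 k = x$model$k, n_tips = x$n_tips, at_bound = x$at_bound)
}
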