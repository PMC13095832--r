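#' Marginal ancestral states by the re-rooting method (two-pass)
#'
#' For a time-reversible Mk model whose root prior is the stationary
#' distribution, the marginal posterior of the state at any node equals the
#' root marginal of the tree re-rooted at that node. This implementation
#' computes all node marginals in a single inside-outside sweep: the
#' postorder ("inside") partials `D_n(s)` from [pruning_log_likelihood()],
#' then a preorder ("outside") pass propagating the evidence from the rest
#' of the tree, so that `P(state(n) = s | data) propto pi_s D_n(s) U_n(s)`.
#' The result is identical to literally re-rooting at every node
#' ([marginal_asr_direct()] does exactly that, independently, as the slow
#' reference).
#'
#' Marginals are also reported at the tips: for a tip observed with
#' certainty they collapse to the indicator of the observed state, while
#' ambiguous tips (social parasite, unknown preference) receive a genuine
#' posterior conditional on the rest of the data ("imputed tips").
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_vectors Named list or matrix of length-k observation vectors.
#' @param model An `mk_model` (ER; the root prior must be the stationary
#'   distribution, which holds for the uniform default).
#' @return Object of class `asr`: `probs` (matrix, rows = ape node ids
#'   `1..Ntip+Nnode`, cols = states; each row a probability simplex),
#'   `q_used`, `state_labels`, `tree`, `imputed_tip` (logical per tip).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tv <- list(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1))
#' marginal_asr_rerooting(tr, tv, mk_model(2, 0.3))
#' @export
marginal_asr_rerooting <- function(tree, tip_vectors, model) {
  stopifnot(inherits(model, "mk_model"))
  if (max(abs(model$pi - 1 / model$k)) > 1e-9) {
    stop("the re-rooting method requires a time-reversible model with the ",
         "stationary root prior; for ER this is the uniform prior",
         call. = FALSE)
  }
  k <- model$k
  tipmat <- .tip_matrix(tree, tip_vectors, k)
  pr <- .prune(tree, tipmat, model)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + ape::Nnode(tree)
  root <- n_tip + 1L
  D <- pr$partials

  # Outside pass in preorder (reverse postorder edge order): parent before
  # child. U[n, s] carries the likelihood of all data NOT below n, given
  # state s at n; scaled per node (constants cancel in the marginals).
  U <- matrix(1, n_all, k)
  edge <- pr$edge
  elen <- pr$edge_length
  children <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]
    ch <- edge[e, 2]
    # Product over siblings of ch of (P(t_b) %*% D_b); recomputed
    # excluding ch (no division: partials may contain exact zeros).
    sib <- rep(1, k)
    for (e2 in children[[as.character(par)]]) {
      if (e2 == e) next
      sib <- sib * as.vector(.er_pmat(k, model$q, elen[e2]) %*% D[edge[e2, 2], ])
    }
    msg <- U[par, ] * sib
    # ER P(t) is symmetric; written with t() for general reversible Q.
    U[ch, ] <- as.vector(t(.er_pmat(k, model$q, elen[e])) %*% msg)
    m <- max(U[ch, ])
    if (m > 0 && is.finite(m)) U[ch, ] <- U[ch, ] / m
  }

  probs <- D * U * rep(model$pi, each = n_all)
  probs <- probs / rowSums(probs)
  colnames(probs) <- model$state_labels
  imputed <- rowSums(tipmat > 0) > 1
  structure(
    list(probs = probs, q_used = model$q, state_labels = model$state_labels,
         tree = tree, imputed_tip = stats::setNames(imputed, tree$tip.label)),
    class = "asr"
  )
}

#' Marginal ancestral states by literal per-node re-rooting
#'
#' The slow reference implementation of the re-rooting method: for every
#' node the tree is treated as an unrooted graph, a fresh pruning recursion
#' is run with that node as the root, and the node's marginal is the
#' normalized `pi_s D_node(s)`. Shares no traversal code with
#' [marginal_asr_rerooting()]; intended for verification on trees up to a
#' few hundred tips (O(n^2) cost).
#'
#' @inheritParams marginal_asr_rerooting
#' @return An `asr` object (same contract as [marginal_asr_rerooting()]).
#' @export
marginal_asr_direct <- function(tree, tip_vectors, model) {
  stopifnot(inherits(model, "mk_model"))
  if (max(abs(model$pi - 1 / model$k)) > 1e-9) {
    stop("the re-rooting method requires a time-reversible model with the ",
         "stationary root prior", call. = FALSE)
  }
  k <- model$k
  tipmat <- .tip_matrix(tree, tip_vectors, k)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + ape::Nnode(tree)

  # Undirected adjacency: neighbor node and connecting edge length.
  nbr <- vector("list", n_all)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; t <- tree$edge.length[e]
    nbr[[a]] <- rbind(nbr[[a]], c(b, t))
    nbr[[b]] <- rbind(nbr[[b]], c(a, t))
  }
  base_obs <- function(n) if (n <= n_tip) tipmat[n, ] else rep(1, k)

  # Conditional likelihood of everything on the far side of the edge
  # (from -> n), seen from n. Normalized at each step; constants cancel.
  down <- function(n, from) {
    v <- base_obs(n)
    for (i in seq_len(NROW(nbr[[n]]))) {
      m <- nbr[[n]][i, 1]
      if (m == from) next
      v <- v * as.vector(.er_pmat(k, model$q, nbr[[n]][i, 2]) %*% down(m, n))
    }
    v / max(v)
  }

  probs <- matrix(NA_real_, n_all, k)
  for (n in seq_len(n_all)) {
    v <- base_obs(n)
    for (i in seq_len(NROW(nbr[[n]]))) {
      m <- nbr[[n]][i, 1]
      v <- v * as.vector(.er_pmat(k, model$q, nbr[[n]][i, 2]) %*% down(m, n))
    }
    p <- model$pi * v
    probs[n, ] <- p / sum(p)
  }
  colnames(probs) <- model$state_labels
  imputed <- rowSums(tipmat > 0) > 1
  structure(
    list(probs = probs, q_used = model$q, state_labels = model$state_labels,
         tree = tree, imputed_tip = stats::setNames(imputed, tree$tip.label)),
    class = "asr"
  )
}

#' @export
print.asr <- function(x, ...) {
  n_tip <- ape::Ntip(x$tree)
  cat("Marginal ancestral-state reconstruction: ",
      nrow(x$probs) - n_tip, " internal nodes, k = ",
      length(x$state_labels), ", q = ", format(x$q_used, digits = 6), "\n",
      sep = "")
  root <- n_tip + 1L
  cat("  root marginal:",
      paste(sprintf("%s %.3f", x$state_labels, x$probs[root, ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy node-by-state ancestral probabilities
#'
#' @param x An `asr` object.
#' @param ... Unused.
#' @return Long tibble with `node`, `type` (tip/internal), `state`, `prob`.
#' @exportS3Method generics::tidy
tidy.asr <- function(x, ...) {
  n_tip <- ape::Ntip(x$tree)
  tibble::as_tibble(x$probs) |>
    dplyr::mutate(node = dplyr::row_number(),
                  type = ifelse(.data$node <= n_tip, "tip", "internal")) |>
    tidyr::pivot_longer(cols = dplyr::all_of(x$state_labels),
                        names_to = "state", values_to = "prob") |>
    dplyr::select("node", "type", "state", "prob")
}

#' Summarize an ancestral reconstruction into a per-node report
#'
#' For every node: the modal (argmax) state, its probability, and whether
#' it clears the support threshold. Exact ties are broken by state-label
#' order and flagged.
#'
#' @param recon An `asr` object.
#' @param threshold Support threshold on the modal probability (default
#'   0.8).
#' @param tol Numerical tolerance for declaring a tie.
#' @return Tibble with `node`, `type`, `age` (when the tree is ultrametric;
#'   `NA` otherwise), one `P_<state>` column per state, `modal`, `prob`,
#'   `supported`, `tie`, `imputed_tip`.
#' @export
summarize_asr <- function(recon, threshold = 0.8, tol = 1e-12) {
  stopifnot(inherits(recon, "asr"))
  probs <- recon$probs
  labels <- recon$state_labels
  modal_i <- apply(probs, 1, which.max)
  modal_p <- probs[cbind(seq_len(nrow(probs)), modal_i)]
  tie <- apply(probs, 1, function(p) sum(p >= max(p) - tol) > 1)
  n_tip <- ape::Ntip(recon$tree)
  age <- tryCatch(node_ages(recon$tree)$age,
                  error = function(e) rep(NA_real_, nrow(probs)))
  wide <- tibble::as_tibble(probs)
  names(wide) <- paste0("P_", labels)
  dplyr::bind_cols(
    tibble::tibble(
      node = seq_len(nrow(probs)),
      type = ifelse(seq_len(nrow(probs)) <= n_tip, "tip", "internal"),
      age = age
    ),
    wide,
    tibble::tibble(
      modal = labels[modal_i],
      prob = modal_p,
      supported = modal_p >= threshold,
      tie = tie,
      imputed_tip = c(unname(recon$imputed_tip),
                      rep(FALSE, nrow(probs) - n_tip))
    )
  )
}

#' Plot ancestral-state probabilities along node ages
#'
#' Stacked probability bars for every internal node, ordered by node age,
#' giving a quick view of where on the time axis the reconstruction is
#' confident.
#'
#' @param object An `asr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.asr <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$type == "internal") |>
    dplyr::left_join(node_ages(object$tree)[, c("node", "age")], by = "node") |>
    dplyr::mutate(state = factor(.data$state, levels = object$state_labels))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(factor(.data$node), -.data$age),
                                   y = .data$prob, fill = .data$state)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "internal node (oldest to youngest)",
                  y = "marginal probability", fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}
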