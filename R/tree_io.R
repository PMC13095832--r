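#' Parse a newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is
#' the package's working representation of a chronogram: a rooted `phylo`
#' object with nonnegative branch lengths in absolute time units (Ma).
#' Polytomies are allowed.
#'
#' @param text A newick string (must end in `;`).
#' @return A `phylo` object.
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  txt <- trimws(text)
  opens <- gregexpr("(", txt, fixed = TRUE)[[1]]
  closes <- gregexpr(")", txt, fixed = TRUE)[[1]]
  n_open <- sum(opens > 0)
  n_close <- sum(closes > 0)
  if (n_open != n_close) {
    stop("newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')') near character ",
         max(c(opens[opens > 0], closes[closes > 0])), call. = FALSE)
  }
  if (!grepl(";\\s*$", txt)) {
    stop("newick parse error: missing terminal ';' at character ",
         nchar(txt), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("newick parse error: malformed tree string", call. = FALSE)
  }
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
      stop("newick parse error: NaN or non-finite branch length", call. = FALSE)
    }
    if (any(tree$edge.length < 0)) {
      stop("newick parse error: negative branch length", call. = FALSE)
    }
  }
  tree
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when written to `file`.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root age of a chronogram
#'
#' @param tree An ultrametric `phylo`.
#' @return Maximum root-to-tip path length (the root's age).
#' @export
root_age <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Validate ultrametricity of a chronogram
#'
#' All root-to-tip path sums must agree within `tol` (relative to root age);
#' time-calibrated trees carry numeric rounding noise, hence a tolerance.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tol Relative tolerance (default `1e-6` of the root age).
#' @return `tree`, invisibly, on success; otherwise an error reporting the
#'   maximum deviation.
#' @export
validate_chronogram <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  depth <- ape::node.depth.edgelength(tree)
  tips <- seq_len(ape::Ntip(tree))
  dev <- max(depth[tips]) - min(depth[tips])
  if (dev > tol * max(depth)) {
    stop("tree is not ultrametric: max root-to-tip deviation ",
         format(dev, digits = 6), " exceeds tolerance ",
         format(tol * max(depth), digits = 6), call. = FALSE)
  }
  invisible(tree)
}

#' Node ages and forward times
#'
#' Ages are measured backwards from the present (every tip has age 0, the
#' root has the maximum age); forward time runs the other way,
#' `time_forward = root_age - age`, from 0 at the root to `root_age` at the
#' present. Both coordinates are reported for every node.
#'
#' @param tree An ultrametric `phylo` (checked via [validate_chronogram()]).
#' @param tol Ultrametricity tolerance passed through.
#' @return A tibble with columns `node` (ape node id: tips `1..Ntip`, root
#'   `Ntip+1`), `label` (tip label or `NA`), `age`, `time_forward`.
#' @examples
#' node_ages(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
node_ages <- function(tree, tol = 1e-6) {
  validate_chronogram(tree, tol = tol)
  depth <- ape::node.depth.edgelength(tree)
  ra <- max(depth)
  n_tip <- ape::Ntip(tree)
  age <- ra - depth
  age[seq_len(n_tip)] <- 0  # snap rounding noise at the tips
  tibble::tibble(
    node = seq_along(depth),
    label = c(tree$tip.label, rep(NA_character_, ape::Nnode(tree))),
    age = age,
    time_forward = ra - age
  )
}

#' Prune a tree to a set of taxa
#'
#' Retains exactly the requested tips, summing branch lengths through any
#' suppressed degree-2 nodes, so patristic distances between retained tips
#' (and ultrametricity) are preserved.
#'
#' @param tree A `phylo`.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo`.
#' @examples
#' write_newick(prune_to_taxa(parse_newick("((A:1,B:1):1,C:2);"), c("A", "C")))
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2) stop("need at least 2 taxa to keep", call. = FALSE)
  ape::keep.tip(tree, keep)
}

#' Read trees from a NEXUS file
#'
#' Read-only convenience over [ape::read.nexus()].
#'
#' @param file Path to a NEXUS file with a trees block.
#' @return A `phylo` or `multiPhylo`.
#' @export
read_nexus_trees <- function(file) {
  ape::read.nexus(file)
}

# --- SIMMAP serialization -------------------------------------------------

# Serialize the subtree below `node`, annotating each branch with its
# segment list in {state,dur:state,dur} form, parent-to-child order.
.simmap_subtree <- function(tree, node, maps, digits) {
  n_tip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (length(kids) == 0) {
    return(tree$tip.label[node])
  }
  parts <- vapply(kids, function(ch) {
    e <- which(tree$edge[, 2] == ch)
    m <- rev(maps[[e]])  # v1 dialect lists segments child-to-parent
    ann <- paste(sprintf("%s,%s", names(m),
                         sprintf(paste0("%.", digits, "g"), unname(m))),
                 collapse = ":")
    paste0(.simmap_subtree(tree, ch, maps, digits), ":{", ann, "}")
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Serialize a stochastic map in SIMMAP dialect
#'
#' Writes one character history as a SIMMAP-annotated newick string: each
#' branch length is replaced by `{state,duration:state,duration:...}` with
#' segments ordered from the parent end to the child end. The output is
#' readable by [read_simmap()] (and by the usual SIMMAP readers in the
#' field).
#'
#' @param history A `character_history` from [stochastic_map()].
#' @param digits Significant digits for durations.
#' @param check Verify that per-branch segment durations sum to the branch
#'   length (within `1e-8` relative) before writing.
#' @return A single SIMMAP newick string (with trailing `;`).
#' @export
write_simmap <- function(history, digits = 12, check = TRUE) {
  stopifnot(inherits(history, "character_history"))
  tree <- history$tree
  maps <- history$edge_maps
  if (check) {
    sums <- vapply(maps, sum, numeric(1))
    dev <- abs(sums - tree$edge.length)
    tol <- 1e-8 * max(1, max(tree$edge.length))
    if (any(dev > tol)) {
      stop("segment durations do not sum to branch lengths (max deviation ",
           format(max(dev), digits = 4), ")", call. = FALSE)
    }
  }
  root <- ape::Ntip(tree) + 1L
  paste0(.simmap_subtree(tree, root, maps, digits), ";")
}

#' Write a set of stochastic maps to a file
#'
#' One SIMMAP newick string per line (phylip-style container).
#'
#' @param histories A list of `character_history` objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_simmap_file <- function(histories, file) {
  lines <- vapply(histories, write_simmap, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read SIMMAP-annotated trees
#'
#' Parses SIMMAP newick strings (as produced by [write_simmap()] or other
#' stochastic-mapping tools) back into `character_history` objects. Parsing
#' is delegated to `phytools::read.simmap`.
#'
#' @param file Path to a file of SIMMAP newick strings, or `NULL` if `text`
#'   is given.
#' @param text SIMMAP newick text.
#' @param state_labels Canonical state order for the reconstructed
#'   histories; defaults to the states present, sorted.
#' @return A list of `character_history` objects.
#' @export
read_simmap <- function(file = NULL, text = NULL, state_labels = NULL) {
  if (!requireNamespace("phytools", quietly = TRUE)) {
    stop("read_simmap requires the phytools package", call. = FALSE)
  }
  trees <- if (is.null(text)) {
    phytools::read.simmap(file = file, format = "phylip", version = 1)
  } else {
    phytools::read.simmap(text = text, format = "phylip", version = 1)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(tr) {
    maps <- tr$maps
    if (is.null(state_labels)) {
      state_labels <- sort(unique(unlist(lapply(maps, names))))
    }
    plain <- tr
    plain$maps <- NULL
    plain$mapped.edge <- NULL
    attr(plain, "map.order") <- NULL
    class(plain) <- "phylo"
    node_states <- rep(NA_character_, ape::Ntip(plain) + ape::Nnode(plain))
    for (e in seq_len(nrow(plain$edge))) {
      node_states[plain$edge[e, 1]] <- names(maps[[e]])[1]
      node_states[plain$edge[e, 2]] <- names(maps[[e]])[length(maps[[e]])]
    }
    new_character_history(plain, maps, node_states, state_labels, seed = NA_integer_)
  })
}
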