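# Forward-time interval spanned by each edge: time_forward of parent and
# child nodes (0 at the root, root_age at the present).
.edge_forward_times <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  start <- depth[tree$edge[, 1]]
  end <- depth[tree$edge[, 2]]
  cbind(start = start, end = end)
}

#' Extract timed transition events from a character history
#'
#' Walks every branch's segment list and emits one event per state change,
#' timed in forward time from the root (`time_forward = 0` at the root,
#' `root_age` at the present). Helpers for the age coordinate
#' (`age = root_age - time_forward`) are included in the output.
#'
#' @param history A `character_history`.
#' @param tree The tree the history was sampled on (defaults to the one
#'   stored in the history).
#' @return Tibble, sorted by time, with `branch` (edge index), `child`
#'   (ape id of the child node), `time_forward`, `age`, `from_state`,
#'   `to_state`.
#' @export
extract_transitions <- function(history, tree = history$tree) {
  stopifnot(inherits(history, "character_history"))
  if (ape::Ntip(tree) != ape::Ntip(history$tree) ||
      nrow(tree$edge) != length(history$edge_maps)) {
    stop("history does not match tree (edge count mismatch)", call. = FALSE)
  }
  ft <- .edge_forward_times(tree)
  ra <- max(ape::node.depth.edgelength(tree))
  rows <- list()
  for (e in seq_along(history$edge_maps)) {
    m <- history$edge_maps[[e]]
    if (length(m) < 2) next
    sums <- abs(sum(m) - tree$edge.length[e])
    if (sums > 1e-8 * max(1, tree$edge.length[e])) {
      stop("segment durations on branch ", e,
           " do not sum to its length", call. = FALSE)
    }
    t_bound <- ft[e, "start"] + cumsum(m)[-length(m)]
    rows[[length(rows) + 1]] <- tibble::tibble(
      branch = e,
      child = tree$edge[e, 2],
      time_forward = unname(t_bound),
      from_state = names(m)[-length(m)],
      to_state = names(m)[-1]
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(branch = integer(), child = integer(),
                   time_forward = numeric(), from_state = character(),
                   to_state = character())
  }
  out |>
    dplyr::mutate(age = ra - .data$time_forward) |>
    dplyr::arrange(.data$time_forward) |>
    dplyr::select("branch", "child", "time_forward", "age",
                  "from_state", "to_state")
}

#' Accumulation of trait transitions through time
#'
#' The trait-accumulation statistic: for each stochastic map, the
#' cumulative number of transitions *into* each state is evaluated on a
#' uniform forward-time grid spanning root (`t_f = 0`) to present
#' (`t_f = root_age`), then averaged across maps. Events falling exactly on
#' a grid point count at that point (closed-left convention). The grid has
#' 200 points by default.
#'
#' @param histories A `character_history_set` (or list of histories on one
#'   tree).
#' @param tree The common tree (defaults to the set attribute).
#' @param grid_size Number of grid points (>= 2; default 200).
#' @param states State order for the output (defaults to the histories'
#'   state labels).
#' @return Object of class `accumulation_curve`: `grid` (forward times),
#'   `mean` (states x grid matrix of mean cumulative counts), `per_sim`
#'   (nsim x grid x states array), `nsim`, `root_age`, `state_labels`.
#' @export
accumulation_curves <- function(histories, tree = attr(histories, "tree"),
                                grid_size = 200, states = NULL) {
  if (inherits(histories, "character_history")) histories <- list(histories)
  stopifnot(length(histories) >= 1, grid_size >= 2)
  if (is.null(tree)) tree <- histories[[1]]$tree
  n_edge <- nrow(tree$edge)
  ok <- vapply(histories, function(h) length(h$edge_maps) == n_edge &&
                 ape::Ntip(h$tree) == ape::Ntip(tree), logical(1))
  if (!all(ok)) stop("histories were sampled on a different tree", call. = FALSE)
  if (is.null(states)) states <- histories[[1]]$state_labels
  ra <- max(ape::node.depth.edgelength(tree))
  grid <- seq(0, ra, length.out = grid_size)
  nsim <- length(histories)
  per_sim <- array(0, dim = c(nsim, grid_size, length(states)),
                   dimnames = list(NULL, NULL, states))
  for (i in seq_len(nsim)) {
    ev <- extract_transitions(histories[[i]], tree)
    for (s in states) {
      ts <- ev$time_forward[ev$to_state == s]
      if (length(ts)) {
        # counts events with time_forward <= grid point (closed left)
        per_sim[i, , s] <- findInterval(grid, sort(ts),
                                        left.open = FALSE)
      }
    }
  }
  mean_mat <- t(apply(per_sim, c(2, 3), mean))  # states x grid
  structure(
    list(grid = grid, mean = mean_mat, per_sim = per_sim, nsim = nsim,
         root_age = ra, state_labels = states),
    class = "accumulation_curve"
  )
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat("Accumulation curve: ", length(x$grid), "grid points over [0, ",
      format(x$root_age, digits = 6), "] forward time; mean of ",
      x$nsim, " map(s)\n", sep = "")
  cat("  final mean transitions into each state:\n")
  print(round(x$mean[, ncol(x$mean)], 3))
  invisible(x)
}

#' Tidy an accumulation curve
#'
#' @param x An `accumulation_curve`.
#' @param ... Unused.
#' @return Long tibble with `time_forward`, `age`, `state`,
#'   `mean_cumulative`.
#' @exportS3Method generics::tidy
tidy.accumulation_curve <- function(x, ...) {
  tibble::tibble(
    time_forward = rep(x$grid, times = length(x$state_labels)),
    age = x$root_age - rep(x$grid, times = length(x$state_labels)),
    state = rep(x$state_labels, each = length(x$grid)),
    mean_cumulative = as.vector(t(x$mean))
  )
}

#' Export an accumulation curve as TSV
#'
#' One row per grid point: `time_forward`, `age`, and one column of mean
#' cumulative transitions-into per state.
#'
#' @param curve An `accumulation_curve`.
#' @param file Output path; `NULL` returns the tibble without writing.
#' @return The wide tibble, invisibly when written.
#' @export
export_curves <- function(curve, file = NULL) {
  stopifnot(inherits(curve, "accumulation_curve"))
  wide <- tibble::tibble(time_forward = curve$grid,
                         age = curve$root_age - curve$grid)
  for (s in curve$state_labels) wide[[s]] <- curve$mean[s, ]
  if (is.null(file)) return(wide)
  readr::write_tsv(wide, file)
  invisible(wide)
}

#' Read back an exported accumulation-curve TSV
#'
#' @param file Path written by [export_curves()].
#' @return The wide tibble.
#' @export
read_curves <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(.default = readr::col_double()),
                  progress = FALSE)
}

#' Plot accumulation curves
#'
#' Mean cumulative transitions into each state against forward time.
#'
#' @param object An `accumulation_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.accumulation_curve <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(state = factor(.data$state, levels = object$state_labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_forward,
                                   y = .data$mean_cumulative,
                                   colour = .data$state)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time since root (Ma)",
                  y = "mean cumulative transitions into state",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Standing lineage counts per state through time
#'
#' A secondary statistic, distinct from [accumulation_curves()]: the number
#' of live branches occupying each state at every grid time, averaged
#' across histories. A branch is counted at grid time `t` when its forward
#' interval covers `t` (half-open at the child end, except the present,
#' so lineages are never double-counted across a speciation).
#'
#' @inheritParams accumulation_curves
#' @return Long tibble with `time_forward`, `age`, `state`,
#'   `mean_lineages`.
#' @export
lineage_state_counts <- function(histories, tree = attr(histories, "tree"),
                                 grid_size = 200, states = NULL) {
  if (inherits(histories, "character_history")) histories <- list(histories)
  if (is.null(tree)) tree <- histories[[1]]$tree
  if (is.null(states)) states <- histories[[1]]$state_labels
  ra <- max(ape::node.depth.edgelength(tree))
  grid <- seq(0, ra, length.out = grid_size)
  ft <- .edge_forward_times(tree)
  acc <- matrix(0, length(states), grid_size, dimnames = list(states, NULL))
  for (h in histories) {
    for (e in seq_along(h$edge_maps)) {
      m <- h$edge_maps[[e]]
      bounds <- ft[e, "start"] + c(0, cumsum(m))
      is_present_end <- abs(ft[e, "end"] - ra) <= 1e-9 * max(1, ra)
      for (j in seq_along(m)) {
        lo <- bounds[j]; hi <- bounds[j + 1]
        last_seg <- j == length(m)
        inside <- grid >= lo & (grid < hi |
                                  (last_seg & is_present_end & grid <= hi))
        acc[names(m)[j], ] <- acc[names(m)[j], ] + inside
      }
    }
  }
  acc <- acc / length(histories)
  tibble::tibble(
    time_forward = rep(grid, times = length(states)),
    age = ra - rep(grid, times = length(states)),
    state = rep(states, each = length(grid)),
    mean_lineages = as.vector(t(acc))
  )
}
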