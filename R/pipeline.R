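#' Assemble a validated pipeline run configuration
#'
#' Collects everything one analysis run needs: input paths (or in-memory
#' objects), the analysis states, the number of stochastic maps, the
#' accumulation grid size, the seed, and the ASR support threshold.
#' Defaults mirror the conventional analysis settings: 100 stochastic
#' realizations and a 200-point time grid.
#'
#' @param tree Path to a newick file, or a `phylo` object.
#' @param traits Path to a trait CSV (see [load_trait_table()]), or a
#'   `trait_table`.
#' @param out_dir Output directory for run artifacts.
#' @param states Analysis state order (default [cutting_states()]).
#' @param nsim Number of stochastic maps (>= 1, default 100).
#' @param grid_size Accumulation grid points (>= 2, default 200).
#' @param seed Integer seed driving every stochastic stage.
#' @param asr_threshold Support threshold for the node report (default 0.8).
#' @param parasite_species Species treated as fully ambiguous social
#'   parasites (passed to [load_trait_table()]).
#' @param include_unknown Admit species with undocumented preference as
#'   ambiguous tips instead of erroring (default `FALSE`).
#' @param plots Also render PDF figures (default `TRUE`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(tree, traits, out_dir, states = cutting_states(),
                       nsim = 100, grid_size = 200, seed = 1,
                       asr_threshold = 0.8,
                       parasite_species = "Acromyrmex ameliae",
                       include_unknown = FALSE, plots = TRUE) {
  stopifnot(nsim >= 1, grid_size >= 2, length(states) >= 2,
            !anyDuplicated(states))
  structure(
    list(tree = tree, traits = traits, out_dir = out_dir, states = states,
         nsim = as.integer(nsim), grid_size = as.integer(grid_size),
         seed = as.integer(seed), asr_threshold = asr_threshold,
         parasite_species = parasite_species,
         include_unknown = include_unknown, plots = plots),
    class = "run_config"
  )
}

# Run one stage, rewriting any error to name the failing stage.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full cutting-preference analysis pipeline
#'
#' traits -> tree validation and pruning -> equal-rates Mk fit -> marginal
#' ancestral-state reconstruction -> stochastic character maps ->
#' accumulation curves. Writes, into `config$out_dir`:
#' `fit.tsv` (q_hat, logL, tips used), `nodes.tsv` (per-node ages, state
#' probabilities, modal state and support), `maps.simmap` (one
#' SIMMAP-annotated newick per realization), `curves.tsv` (the accumulation
#' grid), optional PDF figures, and `manifest.json` (input checksums, seed,
#' settings, output checksums). The same config and seed reproduce
#' byte-identical TSV/SIMMAP outputs.
#'
#' @param config A `run_config`.
#' @return Object of class `cutevo_run`: the fitted pieces (`fit`, `asr`,
#'   `maps`, `curves`), the node report, file `paths`, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  traits <- .stage("trait_data", {
    if (inherits(config$traits, "trait_table")) config$traits
    else load_trait_table(config$traits,
                          parasite_species = config$parasite_species)
  })

  tree <- .stage("tree_io", {
    tr <- if (inherits(config$tree, "phylo")) {
      config$tree
    } else {
      if (!file.exists(config$tree)) {
        stop("tree file not found: ", config$tree)
      }
      parse_newick(paste(readLines(config$tree), collapse = ""))
    }
    validate_chronogram(tr)
    # keep the tips that have usable trait records
    key <- tolower(paste(traits$genus, traits$species, sep = "_"))
    idx <- match(tolower(tr$tip.label), key)
    usable <- !is.na(idx) &
      (config$include_unknown | as.character(traits$state)[idx] != "unknown")
    if (sum(usable) < 2) stop("fewer than 2 usable tips after matching")
    if (!all(usable)) tr <- prune_to_taxa(tr, tr$tip.label[usable])
    tr
  })

  tip_vecs <- .stage("trait_data", {
    tip_state_vectors(traits, tree, include_unknown = config$include_unknown)
  })

  fit <- .stage("fit", fit_er_rate(tree, tip_vecs, config$states))
  asr <- .stage("asr", marginal_asr_rerooting(tree, tip_vecs, fit$model))
  nodes <- summarize_asr(asr, threshold = config$asr_threshold)
  maps <- .stage("simmap", stochastic_map(tree, tip_vecs, fit$model,
                                          nsim = config$nsim,
                                          seed = config$seed))
  curves <- .stage("accumulate",
                   accumulation_curves(maps, tree,
                                       grid_size = config$grid_size))

  paths <- c(fit = file.path(config$out_dir, "fit.tsv"),
             nodes = file.path(config$out_dir, "nodes.tsv"),
             maps = file.path(config$out_dir, "maps.simmap"),
             curves = file.path(config$out_dir, "curves.tsv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  readr::write_tsv(tibble::tibble(q_hat = fit$q_hat,
                                  logL = fit$log_likelihood,
                                  n_tips_used = fit$n_tips),
                   paths[["fit"]])
  readr::write_tsv(nodes, paths[["nodes"]])
  write_simmap_file(maps, paths[["maps"]])
  export_curves(curves, paths[["curves"]])

  if (isTRUE(config$plots)) {
    .stage("plots", {
      ggplot2::ggsave(file.path(config$out_dir, "asr.pdf"), autoplot(asr),
                      width = 9, height = 4)
      ggplot2::ggsave(file.path(config$out_dir, "curves.pdf"),
                      autoplot(curves), width = 7, height = 4)
    })
  }

  input_sums <- list()
  for (nm in c("tree", "traits")) {
    if (is.character(config[[nm]]) && file.exists(config[[nm]])) {
      input_sums[[nm]] <- unname(tools::md5sum(config[[nm]]))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cutevo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, nsim = config$nsim, grid_size = config$grid_size,
    states = config$states, asr_threshold = config$asr_threshold,
    inputs = input_sums,
    outputs = as.list(tools::md5sum(unname(paths[c("fit", "nodes", "maps",
                                                   "curves")])))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)

  structure(
    list(config = config, fit = fit, asr = asr, nodes = nodes, maps = maps,
         curves = curves, paths = paths, manifest = manifest),
    class = "cutevo_run"
  )
}

#' @export
print.cutevo_run <- function(x, ...) {
  cat("cutevo pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  q_hat = ", format(x$fit$q_hat, digits = 6),
      ", logL = ", format(x$fit$log_likelihood, digits = 8),
      ", ", x$fit$n_tips, " tips\n", sep = "")
  root <- ape::Ntip(x$fit$tree) + 1L
  cat("  root marginal: ",
      paste(sprintf("%s %.3f", x$asr$state_labels, x$asr$probs[root, ]),
            collapse = ", "), "\n", sep = "")
  fin <- x$curves$mean[, ncol(x$curves$mean)]
  cat("  mean transitions into state (", x$curves$nsim, " maps): ",
      paste(sprintf("%s %.2f", names(fin), fin), collapse = ", "),
      "\n  outputs: ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}
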