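#' Analysis states for cutting preference
#'
#' The three analysed cutting-preference states, in canonical order. This
#' order fixes the meaning of every state-indexed vector and matrix in the
#' package (tip weight vectors, Q, ancestral-state probabilities).
#'
#' @return Character vector `c("dicot", "grass", "dicot_grass")`.
#' @export
cutting_states <- function() c("dicot", "grass", "dicot_grass")

# Bookkeeping states that never enter the Mk machinery as their own state.
.aux_states <- c("unknown", "parasite")

#' Normalize a raw cutting-preference annotation
#'
#' Maps the verbatim annotation of the compiled preference table onto one of
#' the analysis states, an `unknown` (no documented preference), or —
#' for designated taxa — a `parasite` bookkeeping state. A trailing or
#' embedded question mark marks the preference as poorly documented; such
#' annotations still resolve to their stated state but are flagged
#' `uncertain` (the published per-state totals require that they count).
#'
#' @param raw Character vector of verbatim annotation cells (e.g. `"Dicot"`,
#'   `"Grass?"`, `"Dicot?-Grass"`, `"?"`, `""`).
#' @param species Optional character vector, same length as `raw`, of
#'   `"Genus species"` names used to apply `parasite_species`.
#' @param parasite_species Character vector of species-level overrides that
#'   resolve to state `"parasite"` regardless of annotation. Defaults to the
#'   one known social parasite in the group.
#' @return A tibble with columns `state` (factor over the analysis states
#'   plus `unknown`, `parasite`) and `uncertain` (logical).
#' @examples
#' normalize_annotation(c("Grass?", "Dicot", "Dicot?-Grass", "?"))
#' @export
normalize_annotation <- function(raw, species = NULL,
                                 parasite_species = "Acromyrmex ameliae") {
  stopifnot(is.character(raw) | all(is.na(raw)))
  raw_chr <- as.character(raw)
  key <- tolower(trimws(raw_chr))
  key[is.na(key) | key == ""] <- "?"
  lookup <- c(
    "dicot"        = "dicot|FALSE",
    "grass"        = "grass|FALSE",
    "dicot-grass"  = "dicot_grass|FALSE",
    "grass-dicot"  = "dicot_grass|FALSE",
    "dicot?"       = "dicot|TRUE",
    "grass?"       = "grass|TRUE",
    "dicot?-grass" = "dicot_grass|TRUE",
    "dicot-grass?" = "dicot_grass|TRUE",
    "?"            = "unknown|FALSE"
  )
  hit <- lookup[key]
  if (anyNA(hit)) {
    bad <- unique(raw_chr[is.na(hit)])
    stop("unrecognized cutting-preference annotation(s): ",
         paste(sprintf('"%s"', bad), collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(unname(hit), "|", fixed = TRUE)
  state <- vapply(parts, `[[`, character(1), 1L)
  uncertain <- vapply(parts, `[[`, character(1), 2L) == "TRUE"
  if (!is.null(species) && length(parasite_species)) {
    is_par <- tolower(trimws(species)) %in% tolower(parasite_species)
    state[is_par] <- "parasite"
    uncertain[is_par] <- FALSE
  }
  tibble::tibble(
    state = factor(state, levels = c(cutting_states(), .aux_states)),
    uncertain = uncertain
  )
}

#' Load the species-by-cutting-preference table
#'
#' Reads a CSV of compiled cutting preferences (columns `genus`, `species`,
#' `cutting_preference`, `in_phylogeny`, `refs`), normalizes every raw
#' annotation, and validates the result. `source = "table1"` (the default)
#' loads the packaged compilation of cutting preferences for all 46 valid
#' leaf-cutting ant species.
#'
#' @param source Path to a CSV file, or `"table1"` for the builtin fixture.
#' @param parasite_species Passed to [normalize_annotation()].
#' @return A tibble of class `trait_table` with one row per species, in file
#'   order: `genus`, `species`, `raw_annotation`, `state`, `uncertain`,
#'   `in_phylogeny` (logical), `refs` (list of reference codes). The
#'   attribute `state_labels` carries the analysis-state order.
#' @examples
#' traits <- load_trait_table()
#' nrow(traits) # 46
#' @export
load_trait_table <- function(source = "table1",
                             parasite_species = "Acromyrmex ameliae") {
  path <- if (identical(source, "table1")) {
    system.file("extdata", "table1_cutting_preferences.csv",
                package = "cutevo", mustWork = TRUE)
  } else {
    source
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  needed <- c("genus", "species", "cutting_preference", "in_phylogeny", "refs")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("trait table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  full <- paste(df$genus, df$species)
  if (anyDuplicated(tolower(full))) {
    dup <- unique(full[duplicated(tolower(full))])
    stop("duplicated (genus, species) record(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  norm <- normalize_annotation(ifelse(is.na(df$cutting_preference), "",
                                      df$cutting_preference),
                               species = full,
                               parasite_species = parasite_species)
  out <- tibble::tibble(
    genus = df$genus,
    species = df$species,
    raw_annotation = as.character(ifelse(is.na(df$cutting_preference), "", df$cutting_preference)),
    state = norm$state,
    uncertain = norm$uncertain,
    in_phylogeny = !is.na(df$in_phylogeny) & trimws(df$in_phylogeny) != "",
    refs = lapply(strsplit(as.character(ifelse(is.na(df$refs), "", df$refs)), ","), trimws)
  )
  attr(out, "state_labels") <- cutting_states()
  class(out) <- c("trait_table", class(out))
  out
}

#' Count species per state and genus
#'
#' Tabulates the normalized table into per-(state, genus) counts plus
#' per-state totals. The `unknown` and `parasite` bookkeeping states are
#' reported in their own rows and never folded into the three analysis
#' states.
#'
#' @param table A `trait_table` from [load_trait_table()].
#' @return A tibble with columns `state`, `genus`, `n`; rows with
#'   `genus = "total"` give the per-state totals. All counts are integers
#'   and the totals sum to `nrow(table)`.
#' @examples
#' count_by_state(load_trait_table())
#' @export
count_by_state <- function(table) {
  stopifnot(inherits(table, "trait_table") || all(c("state", "genus") %in% names(table)))
  if (nrow(table) == 0) {
    return(tibble::tibble(state = factor(character(), levels = c(cutting_states(), .aux_states)),
                          genus = character(), n = integer()))
  }
  by_genus <- table |>
    dplyr::count(.data$state, .data$genus, .drop = FALSE, name = "n") |>
    dplyr::filter(.data$n > 0 | .data$genus %in% unique(table$genus))
  totals <- table |>
    dplyr::count(.data$state, .drop = FALSE, name = "n") |>
    dplyr::mutate(genus = "total")
  dplyr::bind_rows(by_genus, totals) |>
    dplyr::arrange(.data$state, .data$genus != "total", .data$genus)
}

#' Convert a trait table to per-tip state weight vectors
#'
#' Builds, for every tip of a tree, the length-k observation vector that the
#' pruning algorithm conditions on: an indicator vector for a known state,
#' and an all-ones (fully ambiguous) vector for `parasite` tips and — when
#' admitted — `unknown` tips. Tip labels are expected in `Genus_species`
#' form; matching against the table is case-insensitive on both fields.
#'
#' @param table A `trait_table`.
#' @param tree A rooted `phylo` tree whose tip labels match table records.
#' @param include_unknown If `FALSE` (default) an error is raised when the
#'   tree contains a species with no documented preference; if `TRUE` such
#'   tips enter as fully ambiguous observations.
#' @return A named list (one element per tip label) of numeric length-k
#'   vectors, k = `length(cutting_states())`, in canonical state order.
#' @examples
#' tr <- ape::read.tree(text = "(Atta_sexdens:1,Acromyrmex_heyeri:1);")
#' tip_state_vectors(load_trait_table(), tr)
#' @export
tip_state_vectors <- function(table, tree, include_unknown = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  key <- tolower(paste(table$genus, table$species, sep = "_"))
  idx <- match(tolower(labels), key)
  if (anyNA(idx)) {
    stop("tree tips with no matching trait record: ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  states <- as.character(table$state)[idx]
  if (!include_unknown && any(states == "unknown")) {
    stop("tips with unknown cutting preference (set include_unknown = TRUE ",
         "to admit them as ambiguous): ",
         paste(labels[states == "unknown"], collapse = ", "), call. = FALSE)
  }
  k <- length(cutting_states())
  vecs <- lapply(states, function(s) {
    if (s %in% .aux_states) return(rep(1, k))
    v <- numeric(k)
    v[match(s, cutting_states())] <- 1
    v
  })
  names(vecs) <- labels
  vecs
}
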