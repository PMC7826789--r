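# Chemotype binning: priority-ordered SMARTS substructure classification of
# inhibitors by their hinge-binding scaffold, with an "other" fallback bin
# for compounds lacking any catalogued hinge binder.
#
# Matching is substructure containment with aromaticity perception and no
# stereochemistry, through Open Babel (ChemmineOB). When several patterns
# match, the bin with the smallest priority number wins; priority ties in a
# catalog are a hard error, never broken silently.

# Logical matrix [molecules x patterns] of substructure containment.
# Each SMILES is parsed once; every pattern is evaluated on the live
# Open Babel molecule (robust to bond-free molecules like methane).
ob_match_matrix <- function(smiles, smarts) {
  rows <- lapply(smiles, function(s) {
    ChemmineOB::forEachMol("SMILES", s, function(mol) {
      vapply(smarts, function(p) {
        ChemmineOB::smartsSearch_OB(list(mol), p, uniqueMatches = FALSE) > 0
      }, logical(1))
    })
  })
  matrix(unlist(rows), nrow = length(smiles), byrow = TRUE)
}

#' Load a chemotype bin catalog
#'
#' A catalog is a TSV of named SMARTS patterns with a unique priority rank
#' (lower number = higher priority) and at most one fallback bin, the
#' "other" bin that collects compounds matching no pattern. Each SMARTS is
#' compiled against the matching engine at load time; an invalid pattern is
#' an error naming the bin. If the catalog has no fallback, an `other` bin
#' is appended after the lowest-priority entry.
#'
#' The package ships a small demonstration catalog of common hinge-binder
#' scaffolds (indazole, oxindole, quinazoline, quinoline, pyrimidine, ...):
#' `system.file("extdata", "demo_bins.tsv", package = "kinoset")`.
#'
#' @param path TSV with columns `name`, `smarts`, `priority` and optionally
#'   `is_fallback` (0/1).
#' @return tibble of bins sorted by priority with columns `name`, `smarts`,
#'   `priority`, `is_fallback`.
#' @export
load_bin_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("name", "smarts", "priority"), "bin catalog")
  if (!"is_fallback" %in% names(df)) df$is_fallback <- 0
  bin_catalog(tibble(
    name = as.character(df$name),
    smarts = as.character(df$smarts),
    priority = as.integer(df$priority),
    is_fallback = as.logical(as.integer(df$is_fallback))
  ))
}

#' Construct and validate a bin catalog from a data frame
#'
#' @param bins data frame with columns `name`, `smarts`, `priority`,
#'   optionally `is_fallback`.
#' @return validated catalog tibble sorted by priority, with a fallback bin
#'   guaranteed present and last.
#' @export
bin_catalog <- function(bins) {
  check_columns(bins, c("name", "smarts", "priority"), "`bins`")
  bins <- as_tibble(bins)
  if (!"is_fallback" %in% names(bins)) bins$is_fallback <- FALSE
  bins$is_fallback <- as.logical(bins$is_fallback)
  bins$priority <- as.integer(bins$priority)
  if (any(is.na(bins$priority)) || any(bins$priority <= 0)) {
    abort("bin priorities must be positive integers")
  }
  dup <- unique(bins$priority[duplicated(bins$priority)])
  if (length(dup)) {
    abort(sprintf("duplicate priority value(s): %s (bins: %s)",
                  paste(dup, collapse = ", "),
                  paste(bins$name[bins$priority %in% dup], collapse = ", ")))
  }
  if (any(duplicated(bins$name))) abort("duplicate bin name(s) in catalog")
  n_fb <- sum(bins$is_fallback)
  if (n_fb > 1) abort("a catalog may contain at most one fallback bin")
  if (n_fb == 0) {
    bins <- dplyr::bind_rows(bins, tibble(
      name = "other", smarts = NA_character_,
      priority = max(bins$priority) + 1L, is_fallback = TRUE
    ))
  } else if (bins$priority[bins$is_fallback] != max(bins$priority)) {
    abort("the fallback bin must have the lowest priority (largest rank)")
  }
  # compile every non-fallback pattern once, against a probe molecule
  for (i in which(!bins$is_fallback)) {
    ok <- tryCatch(
      {
        ob_match_matrix("c1ccccc1C", bins$smarts[i])
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      abort(sprintf("invalid SMARTS for bin '%s': %s",
                    bins$name[i], bins$smarts[i]))
    }
  }
  dplyr::arrange(bins, .data$priority)
}

#' Assign compounds to chemotype bins
#'
#' Runs every catalog SMARTS over every structure and assigns each compound
#' to the highest-priority (smallest rank) matching bin, or to the fallback
#' bin when nothing matches. All matching bins are retained in the
#' `matched` list column for audit. Assignment depends only on the
#' structure and the catalog: compound order and catalog row order
#' (priorities fixed) are irrelevant.
#'
#' @param compounds tibble with columns `id` and `smiles` (as from
#'   [read_compounds()]), or a character vector of SMILES (ids are then
#'   taken from names or generated).
#' @param catalog bin catalog from [load_bin_catalog()] / [bin_catalog()].
#' @return tibble with one row per compound: `id`, `bin`, `priority`,
#'   `matched` (list of all matching bin names, by priority).
#' @export
assign_chemotypes <- function(compounds, catalog) {
  if (is.character(compounds)) {
    ids <- names(compounds) %||% paste0("mol", seq_along(compounds))
    compounds <- tibble(id = ids, smiles = unname(compounds))
  }
  check_columns(compounds, c("id", "smiles"), "`compounds`")
  if (nrow(compounds) == 0) {
    return(tibble(id = character(), bin = character(),
                  priority = integer(), matched = list()))
  }
  parse_smiles(compounds$smiles, compounds$id)  # validate, error by record
  pats <- catalog[!catalog$is_fallback, ]
  hit <- ob_match_matrix(compounds$smiles, pats$smarts)
  fallback <- catalog$name[catalog$is_fallback]
  rows <- map(seq_len(nrow(compounds)), function(i) {
    matched <- pats$name[hit[i, ]]
    if (length(matched)) {
      tibble(id = compounds$id[i], bin = matched[1],
             priority = pats$priority[hit[i, ]][1],
             matched = list(matched))
    } else {
      tibble(id = compounds$id[i], bin = fallback,
             priority = catalog$priority[catalog$is_fallback],
             matched = list(character()))
    }
  })
  dplyr::bind_rows(rows)
}

#' Assign a single structure to a chemotype bin
#'
#' Convenience wrapper around [assign_chemotypes()] for one SMILES.
#'
#' @param smiles a single SMILES string.
#' @param catalog bin catalog.
#' @return one-row tibble (`id`, `bin`, `priority`, `matched`).
#' @export
assign_chemotype <- function(smiles, catalog) {
  stopifnot(length(smiles) == 1)
  assign_chemotypes(c(compound = smiles), catalog)
}

#' Bin occupancy histogram
#'
#' Summarizes how many catalog bins are occupied and stratifies occupied
#' bins into singletons, small bins (2-5 members) and large bins (>= 6
#' members). The strata always sum to the occupied-bin count.
#'
#' @param assignments tibble from [assign_chemotypes()] (columns `id`,
#'   `bin`).
#' @return one-row tibble: `n_occupied`, `n_single`, `n_2_5`, `n_6_plus`,
#'   plus a `counts` list column holding the per-bin member counts.
#' @export
bin_histogram <- function(assignments) {
  check_columns(assignments, c("id", "bin"), "`assignments`")
  counts <- assignments |>
    dplyr::count(.data$bin, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$bin)
  tibble(
    n_occupied = nrow(counts),
    n_single = sum(counts$n == 1),
    n_2_5 = sum(counts$n >= 2 & counts$n <= 5),
    n_6_plus = sum(counts$n >= 6),
    counts = list(counts)
  )
}

#' Write chemotype assignments
#' @param assignments tibble from [assign_chemotypes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- tibble(
    id = assignments$id, bin = assignments$bin,
    priority = assignments$priority,
    matched = map_chr(assignments$matched, paste, collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
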