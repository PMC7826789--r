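# Coverage analytics: family-level coverage tables, chemotype redundancy,
# and dark-kinase accounting.

#' Family-level kinome coverage table
#'
#' One row per kinome family in the panel plus a totals row. For each
#' family: the number of human kinases in the family (when `family_sizes`
#' is supplied, otherwise NA), the number with assays in the panel, the
#' number of assayed kinases covered by at least one selected inhibitor,
#' and the coverage percentage 100 * covered / assayed rounded half-up to
#' an integer (NA when the family has no assays). The totals row aggregates
#' the counts and recomputes the percentage from the aggregated counts.
#'
#' @param panel panel tibble ([kinase_panel()]).
#' @param covered character vector of covered kinase symbols; every entry
#'   must be in the panel.
#' @param family_sizes optional tibble (`family`, `n_kinases`) giving the
#'   total human kinase count per family, beyond what the panel assays.
#' @return tibble with columns `family`, `n_kinases`, `n_assays`,
#'   `n_covered`, `pct`; last row `family == "Total"`.
#' @export
family_coverage <- function(panel, covered, family_sizes = NULL) {
  check_columns(panel, c("kinase", "family"), "`panel`")
  covered <- unique(as.character(covered))
  unknown <- setdiff(covered, panel$kinase)
  if (length(unknown)) {
    abort(sprintf("covered kinase(s) absent from panel: %s",
                  paste(unknown, collapse = ", ")))
  }
  rows <- panel |>
    dplyr::group_by(family = .data$family) |>
    dplyr::summarise(
      n_assays = dplyr::n(),
      n_covered = sum(.data$kinase %in% covered),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family)
  if (!is.null(family_sizes)) {
    check_columns(family_sizes, c("family", "n_kinases"), "`family_sizes`")
    rows <- dplyr::left_join(rows, family_sizes, by = "family")
  } else {
    rows$n_kinases <- NA_integer_
  }
  rows <- rows |>
    dplyr::mutate(pct = ifelse(
      .data$n_assays > 0,
      round_half_up(100 * .data$n_covered / .data$n_assays),
      NA_real_
    )) |>
    dplyr::select("family", "n_kinases", "n_assays", "n_covered", "pct")
  total <- tibble(
    family = "Total",
    n_kinases = if (all(is.na(rows$n_kinases))) NA_integer_
                else sum(rows$n_kinases, na.rm = TRUE),
    n_assays = sum(rows$n_assays),
    n_covered = sum(rows$n_covered),
  )
  total$pct <- if (total$n_assays > 0) {
    round_half_up(100 * total$n_covered / total$n_assays)
  } else NA_real_
  dplyr::bind_rows(rows, total)
}

#' Chemotype redundancy report
#'
#' Splits covered kinases by chemotype depth: those covered by two or more
#' distinct chemotypes versus those covered by exactly one. The split is
#' driven by distinct chemotypes, not inhibitor count — two same-scaffold
#' inhibitors of a kinase still leave it single-chemotype.
#'
#' @param depth depth table from a [greedy_assemble()] result (`$depth`):
#'   columns `kinase`, `n_chemotypes`.
#' @return one-row tibble: `n_kinases_multi`, `n_kinases_single`,
#'   `n_covered`.
#' @export
redundancy_report <- function(depth) {
  check_columns(depth, c("kinase", "n_chemotypes"), "`depth`")
  tibble(
    n_kinases_multi = sum(depth$n_chemotypes >= 2),
    n_kinases_single = sum(depth$n_chemotypes == 1),
    n_covered = nrow(depth)
  )
}

#' Dark-kinase coverage
#'
#' Intersects the covered kinases with a user-supplied list of understudied
#' ("dark") kinases, symbol-exact. The dark-kinase list (for example the
#' set nominated by the NIH Illuminating the Druggable Genome initiative)
#' is an input table, never fetched.
#'
#' @param covered character vector of covered kinase symbols.
#' @param idg_list character vector of dark-kinase symbols (non-empty).
#' @return one-row tibble: `n_dark`, `n_covered_dark`, `covered_dark`
#'   (list column, sorted).
#' @export
dark_kinase_coverage <- function(covered, idg_list) {
  if (!length(idg_list)) abort("`idg_list` must be non-empty")
  hit <- sort(intersect(unique(covered), unique(idg_list)))
  tibble(
    n_dark = length(unique(idg_list)),
    n_covered_dark = length(hit),
    covered_dark = list(hit)
  )
}

#' Write a family coverage report
#' @param coverage tibble from [family_coverage()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(coverage, path) {
  readr::write_tsv(coverage, path, progress = FALSE)
  invisible(path)
}
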