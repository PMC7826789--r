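# Selectivity scoring: activity profiles, the S10 index, K_D follow-up
# sets, and the set-inclusion decision.
#
# S10 is the fraction of assayed kinases with PoC strictly below a 10%
# cutoff at the screening concentration. All threshold comparisons here are
# strict ("<"): boundary values fail. The denominator is the number of
# non-missing, wild-type, human assay cells for the compound — unassayed
# kinases are not evidence of selectivity, so missing cells leave both
# numerator and denominator.

# Per-compound assayed cells restricted to wild-type human kinases.
compound_cells <- function(matrix, compound) {
  panel <- poc_panel(matrix)
  keep <- panel$kinase[panel$is_wild_type & panel$is_human]
  rows <- matrix[matrix$compound_id == compound & matrix$kinase %in% keep, ]
  if (nrow(rows) == 0 && !compound %in% matrix$compound_id) {
    abort(sprintf("compound '%s' absent from matrix", compound))
  }
  n_missing <- sum(is.na(rows$poc))
  rows <- rows[!is.na(rows$poc), ]
  if (nrow(rows) == 0) {
    abort(sprintf("compound '%s' has no non-missing assay cells", compound))
  }
  if (n_missing > 0) {
    warn(sprintf("compound '%s': %d missing cell(s) excluded from the S10 denominator",
                 compound, n_missing))
  }
  rows
}

#' Activity profile of a compound
#'
#' Kinases whose percent-of-control is strictly below `cutoff` for the
#' given compound, ordered by ascending PoC and then alphabetically.
#' At the conventional 10% cutoff this is the set of kinases inhibited by
#' at least 90% at the screening concentration.
#'
#' @param matrix a [poc_matrix()].
#' @param compound compound id present in the matrix.
#' @param cutoff PoC threshold in percent (default 10); strict `<`.
#' @return character vector of kinase symbols.
#' @export
active_profile <- function(matrix, compound, cutoff = 10) {
  rows <- compound_cells(matrix, compound)
  hit <- rows[rows$poc < cutoff, ]
  hit$kinase[order(hit$poc, hit$kinase)]
}

#' Compute the S10 selectivity index
#'
#' For each compound, S10 = (number of assayed kinases with PoC < `cutoff`)
#' / (number of assayed kinases). Smaller values mean narrower kinome
#' activity. Missing cells and non-wild-type or non-human assays are
#' excluded from both counts. The screening concentration travels with the
#' matrix's panel.
#'
#' @inheritParams active_profile
#' @param compounds compound ids to score; default all compounds in the
#'   matrix.
#' @return a tibble with one row per compound: `compound_id`, `s10`,
#'   `n_active`, `n_assayed`, `cutoff`, `concentration`, and
#'   `active_kinases` (list column, ordered as [active_profile()]).
#' @examples
#' panel <- kinase_panel(tibble::tibble(
#'   kinase = c("AAK1", "ABL1", "AKT1"), family = c("Other", "TK", "AGC"),
#'   is_wild_type = TRUE, is_human = TRUE))
#' m <- poc_matrix(tibble::tibble(
#'   compound_id = "GW1", AAK1 = 5, ABL1 = 95, AKT1 = 80), panel)
#' compute_s10(m)
#' @export
compute_s10 <- function(matrix, compounds = NULL, cutoff = 10) {
  check_positive_scalar(cutoff, "cutoff")
  compounds <- compounds %||% unique(matrix$compound_id)
  conc <- attr(poc_panel(matrix), "concentration") %||% NA_real_
  rows <- map(compounds, function(cmp) {
    cells <- compound_cells(matrix, cmp)
    act <- cells[cells$poc < cutoff, ]
    tibble(
      compound_id = cmp,
      s10 = nrow(act) / nrow(cells),
      n_active = nrow(act),
      n_assayed = nrow(cells),
      cutoff = cutoff,
      concentration = conc,
      active_kinases = list(act$kinase[order(act$poc, act$kinase)])
    )
  })
  dplyr::bind_rows(rows)
}

#' Kinases to submit for K_D follow-up
#'
#' The follow-up set is all kinases with PoC strictly below
#' `followup_cutoff` for the compound. The default cutoff is 20; a stricter
#' 10 (the activity-profile cutoff) is also in common use — both are
#' supported via the argument.
#'
#' @inheritParams active_profile
#' @param followup_cutoff PoC threshold in percent (default 20); strict `<`.
#' @return character vector of kinase symbols, ordered by ascending PoC
#'   then symbol.
#' @export
kd_followup_set <- function(matrix, compound, followup_cutoff = 20) {
  active_profile(matrix, compound, cutoff = followup_cutoff)
}

#' Decide chemogenomic-set inclusion
#'
#' A compound qualifies when it is both potent and narrow-spectrum: at
#' least one follow-up K_D strictly below `kd_max_nM` on some kinase, and
#' S10 strictly below `s10_max`. Boundary values (K_D exactly 100 nM, S10
#' exactly 0.025) fail. Any kinase with a qualifying K_D counts — deliberate
#' use of a compound's off-target activity is part of the chemogenomic-set
#' design.
#'
#' @param s10_result tibble from [compute_s10()] (one or more rows).
#' @param kd K_D table (`compound`, `kinase`, `kd_nM`), e.g. from
#'   [read_kd_table()].
#' @param kd_max_nM potency threshold in nM (default 100); strict `<`.
#' @param s10_max selectivity threshold (default 0.025); strict `<`.
#' @return tibble with one row per input compound: `compound_id`, `passed`,
#'   `s10`, `n_qualifying`, `qualifying_kinases` (list column), plus the
#'   thresholds used.
#' @export
decide_inclusion <- function(s10_result, kd, kd_max_nM = 100, s10_max = 0.025) {
  check_columns(s10_result, c("compound_id", "s10"), "`s10_result`")
  check_columns(kd, c("compound", "kinase", "kd_nM"), "`kd`")
  check_positive_scalar(kd_max_nM, "kd_max_nM")
  check_positive_scalar(s10_max, "s10_max")
  qual <- kd[kd$kd_nM < kd_max_nM, ]
  out <- s10_result |>
    dplyr::transmute(
      .data$compound_id,
      s10 = .data$s10,
      qualifying_kinases = map(.data$compound_id, function(cmp) {
        sort(unique(qual$kinase[qual$compound == cmp]))
      })
    ) |>
    dplyr::mutate(
      n_qualifying = lengths(.data$qualifying_kinases),
      passed = .data$n_qualifying > 0 & .data$s10 < s10_max,
      kd_max_nM = kd_max_nM,
      s10_max = s10_max
    )
  out[, c("compound_id", "passed", "s10", "n_qualifying",
          "qualifying_kinases", "kd_max_nM", "s10_max")]
}

#' Write a selectivity score table
#'
#' TSV with columns `compound`, `s10`, `n_active`, `n_assayed`,
#' `active_kinases` (semicolon-joined).
#'
#' @param s10_result tibble from [compute_s10()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_s10_table <- function(s10_result, path) {
  out <- tibble(
    compound = s10_result$compound_id,
    s10 = s10_result$s10,
    n_active = s10_result$n_active,
    n_assayed = s10_result$n_assayed,
    active_kinases = map_chr(s10_result$active_kinases, paste, collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
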