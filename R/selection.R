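# Greedy chemogenomic-set assembly.
#
# The curation goal is to cover as much of the kinome as possible with
# potent, narrow-spectrum inhibitors, ideally two distinct chemotypes per
# kinase, preferring under-represented chemotypes among otherwise
# equivalent compounds. This module commits that expert triage to a
# deterministic, auditable greedy algorithm.

#' Selection configuration
#'
#' @param kd_max_nM potency threshold in nM for a qualifying kinase
#'   (default 100, strict `<`).
#' @param s10_max selectivity threshold (default 0.025, strict `<`).
#' @param depth_target desired number of distinct chemotypes per kinase
#'   (default 2).
#' @param publication_weights optional named numeric vector in `[0, 1]`
#'   down-weighting well-studied kinases in the greedy gain; unnamed
#'   kinases default to weight 1.
#' @return a `selection_config` list.
#' @export
selection_config <- function(kd_max_nM = 100, s10_max = 0.025,
                             depth_target = 2, publication_weights = NULL) {
  check_positive_scalar(kd_max_nM, "kd_max_nM")
  check_positive_scalar(s10_max, "s10_max")
  if (depth_target < 1) abort("`depth_target` must be >= 1")
  if (!is.null(publication_weights)) {
    if (is.null(names(publication_weights)) ||
        any(publication_weights < 0) || any(publication_weights > 1)) {
      abort("`publication_weights` must be a named vector with values in [0, 1]")
    }
  }
  structure(
    list(kd_max_nM = kd_max_nM, s10_max = s10_max,
         depth_target = as.integer(depth_target),
         publication_weights = publication_weights),
    class = "selection_config"
  )
}

#' Filter compounds to set-selection candidates
#'
#' Scores every compound in the matrix, applies the inclusion decision
#' (K_D and S10 thresholds, see [decide_inclusion()]), and returns the
#' passing compounds with their qualifying kinase sets — the pool the
#' greedy assembler draws from.
#'
#' @param matrix a [poc_matrix()].
#' @param kd K_D table (`compound`, `kinase`, `kd_nM`).
#' @param config a [selection_config()].
#' @param cutoff PoC cutoff for S10 (default 10).
#' @return tibble of candidates: `compound_id`, `s10`, `qualifying_kinases`
#'   (list column), `n_qualifying`.
#' @export
filter_candidates <- function(matrix, kd, config = selection_config(),
                              cutoff = 10) {
  s10 <- compute_s10(matrix, cutoff = cutoff)
  dec <- decide_inclusion(s10, kd, kd_max_nM = config$kd_max_nM,
                          s10_max = config$s10_max)
  dec |>
    dplyr::filter(.data$passed) |>
    dplyr::select("compound_id", "s10", "qualifying_kinases", "n_qualifying")
}

#' Assemble a chemogenomic set by greedy kinome-coverage maximization
#'
#' Iteratively adds the candidate with the largest marginal coverage gain.
#' A candidate's gain is the weighted number of its qualifying kinases for
#' which its chemotype bin is new *and* that are still below the chemotype
#' depth target; kinases already at the target, or already covered by the
#' same bin, contribute nothing. Ties are broken by (1) fewer exemplars of
#' the candidate's chemotype already selected, (2) lower S10, (3)
#' lexicographically smaller compound id. Assembly stops when no candidate
#' has positive gain.
#'
#' Once a compound is selected, *all* of its qualifying kinases gain an
#' inhibitor (and its bin, if new) in the depth table — kinases beyond the
#' depth target can accumulate depth incidentally, they just never justify
#' an addition.
#'
#' @param candidates tibble from [filter_candidates()] (columns
#'   `compound_id`, `s10`, `qualifying_kinases`).
#' @param assignments chemotype assignments from [assign_chemotypes()]
#'   covering every candidate (columns `id`, `bin`).
#' @param config a [selection_config()].
#' @return an object of class `kinoset_set`: list with `compounds` (tibble
#'   in selection order: `compound_id`, `bin`, `s10`, `gain`, `step`),
#'   `depth` (tibble `kinase`, `n_inhibitors`, `n_chemotypes`, `bins`
#'   list column), `audit` (one row per greedy step with candidate scores
#'   and the tie-break level applied) and `config`.
#' @export
greedy_assemble <- function(candidates, assignments,
                            config = selection_config()) {
  check_columns(candidates, c("compound_id", "s10", "qualifying_kinases"),
                "`candidates`")
  check_columns(assignments, c("id", "bin"), "`assignments`")
  missing_bin <- setdiff(candidates$compound_id, assignments$id)
  if (length(missing_bin)) {
    abort(sprintf("candidate(s) without a chemotype assignment: %s",
                  paste(missing_bin, collapse = ", ")))
  }
  bin_of <- setNames(assignments$bin, assignments$id)
  ids <- candidates$compound_id
  s10 <- setNames(candidates$s10, ids)
  qual <- setNames(candidates$qualifying_kinases, ids)
  depth_target <- config$depth_target
  wts <- config$publication_weights
  weight_of <- function(k) {
    if (is.null(wts)) 1 else unname(wts[k] %|NA|% 1)
  }

  kin_bins <- list()        # kinase -> character vector of distinct bins
  kin_inhib <- integer()    # kinase -> inhibitor count
  bin_count <- integer()    # bin -> exemplars selected
  remaining <- ids
  selected <- character()
  sel_rows <- list()
  audit <- list()
  step <- 0L

  gain_of <- function(cmp) {
    b <- bin_of[[cmp]]
    ks <- qual[[cmp]]
    if (!length(ks)) return(0)
    sum(map_dbl(ks, function(k) {
      bins_k <- kin_bins[[k]] %||% character()
      if (length(bins_k) >= depth_target || b %in% bins_k) return(0)
      weight_of(k)
    }))
  }

  while (length(remaining)) {
    gains <- map_dbl(remaining, gain_of)
    if (max(gains) <= 0) break
    top <- remaining[gains == max(gains)]
    tiebreak <- "none"
    if (length(top) > 1) {
      tiebreak <- "chemotype_exemplars"
      ex <- map_dbl(top, function(cmp) {
        unname(bin_count[bin_of[[cmp]]] %|NA|% 0L)
      })
      top <- top[ex == min(ex)]
      if (length(top) > 1) {
        tiebreak <- "s10"
        top <- top[s10[top] == min(s10[top])]
        if (length(top) > 1) {
          tiebreak <- "id"
          top <- sort(top)[1]
        }
      }
    }
    pick <- top[1]
    step <- step + 1L
    g <- gains[remaining == pick][1]
    b <- bin_of[[pick]]
    for (k in qual[[pick]]) {
      kin_inhib[k] <- (kin_inhib[k] %|NA|% 0L) + 1L
      kin_bins[[k]] <- union(kin_bins[[k]] %||% character(), b)
    }
    bin_count[b] <- (bin_count[b] %|NA|% 0L) + 1L
    sel_rows[[step]] <- tibble(compound_id = pick, bin = b,
                               s10 = unname(s10[pick]), gain = g, step = step)
    audit[[step]] <- tibble(
      step = step, selected = pick, gain = g, tiebreak = tiebreak,
      n_candidates = length(remaining),
      scores = list(tibble(compound_id = remaining, gain = gains))
    )
    remaining <- setdiff(remaining, pick)
    selected <- c(selected, pick)
  }

  depth <- if (length(kin_inhib)) {
    tibble(
      kinase = names(kin_inhib),
      n_inhibitors = unname(kin_inhib),
      n_chemotypes = map_int(names(kin_inhib), ~ length(kin_bins[[.x]])),
      bins = map(names(kin_inhib), ~ sort(kin_bins[[.x]]))
    ) |> dplyr::arrange(.data$kinase)
  } else {
    tibble(kinase = character(), n_inhibitors = integer(),
           n_chemotypes = integer(), bins = list())
  }

  structure(
    list(
      compounds = if (length(sel_rows)) dplyr::bind_rows(sel_rows) else
        tibble(compound_id = character(), bin = character(),
               s10 = double(), gain = double(), step = integer()),
      depth = depth,
      audit = dplyr::bind_rows(audit),
      config = config
    ),
    class = "kinoset_set"
  )
}

# coalesce for indexed lookups that return NA on absent names
`%|NA|%` <- function(x, y) {
  if (length(x) == 0 || is.na(x)) y else x
}

#' @export
print.kinoset_set <- function(x, ...) {
  cat(sprintf(
    "<kinoset_set> %d compound(s) covering %d kinase(s); %d kinase(s) at >= %d chemotypes\n",
    nrow(x$compounds), nrow(x$depth),
    sum(x$depth$n_chemotypes >= x$config$depth_target),
    x$config$depth_target
  ))
  print(x$compounds, ...)
  invisible(x)
}

#' Write a selected set and its audit log
#'
#' The set TSV has columns `compound`, `chemotype`, `s10`,
#' `qualifying_kinases` is not stored here (it lives in the candidates);
#' the audit log is one JSON record per greedy step.
#'
#' @param set a `kinoset_set`.
#' @param path output TSV path for the set.
#' @param audit_path optional path for a JSON-lines audit log.
#' @return `path`, invisibly.
#' @export
write_selected_set <- function(set, path, audit_path = NULL) {
  readr::write_tsv(
    tibble(compound = set$compounds$compound_id,
           chemotype = set$compounds$bin,
           s10 = set$compounds$s10,
           step = set$compounds$step),
    path, progress = FALSE
  )
  if (!is.null(audit_path)) {
    lines <- map_chr(seq_len(nrow(set$audit)), function(i) {
      row <- set$audit[i, ]
      jsonlite::toJSON(list(
        step = row$step, selected = row$selected, gain = row$gain,
        tiebreak = row$tiebreak,
        scores = row$scores[[1]]
      ), auto_unbox = TRUE, digits = NA)
    })
    writeLines(lines, audit_path)
  }
  invisible(path)
}
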