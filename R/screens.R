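# Phenotypic-screen annotation: normalized growth-rate (GR) inhibition,
# cytotoxicity tiers with per-kinase aggregation, and autophagic-flux hit
# calling from GFP/RFP reporter time series.

#' Compute normalized growth-rate (GR) inhibition values
#'
#' GR corrects endpoint cell counts for variable division times:
#' \deqn{GR = 2^{\log_2(x/x_0) / \log_2(x_{ctrl}/x_0)} - 1}
#' where `x0` is the live-cell count at treatment time, `x` the treated
#' endpoint count, and `x_ctrl` the vehicle-control endpoint count on the
#' same plate. GR = 1 for vehicle-like growth, 0 for complete growth
#' arrest, and negative values indicate net cell loss. GR is invariant
#' under a common rescaling of all three counts.
#'
#' A line whose control did not grow (`x_ctrl == x0`) makes GR undefined
#' and is a hard error naming the line; such lines are excluded upstream.
#'
#' @param records tibble with columns `cell_line`, `compound_id`, `x0`,
#'   `x`, `x_ctrl` (all counts > 0).
#' @return the input tibble with a `gr` column appended.
#' @export
compute_gr <- function(records) {
  check_columns(records, c("cell_line", "compound_id", "x0", "x", "x_ctrl"),
                "`records`")
  if (any(records$x0 <= 0 | records$x <= 0 | records$x_ctrl <= 0)) {
    abort("all cell counts must be positive")
  }
  flat <- records$x_ctrl == records$x0
  if (any(flat)) {
    abort(sprintf(
      "control did not grow (x_ctrl == x0) for cell line(s): %s; exclude these lines",
      paste(unique(records$cell_line[flat]), collapse = ", ")
    ))
  }
  records |>
    dplyr::mutate(gr = 2^(log2(.data$x / .data$x0) /
                            log2(.data$x_ctrl / .data$x0)) - 1) |>
    as_tibble()
}

#' Classify a compound's growth response across cell lines
#'
#' Three classes per compound from its per-line GR values:
#' * `inactive` — every line within `inactive_band` of vehicle
#'   (all GR >= 1 - inactive_band);
#' * `broad` — at least `broad_fraction` of lines show a decrease of more
#'   than `decrease` (GR <= 1 - decrease);
#' * `line_dependent` — some but not enough lines show that decrease.
#' Compounds with no line at the decrease threshold fall back to
#' `inactive`.
#'
#' @param gr tibble with columns `compound_id`, `cell_line`, `gr` (e.g.
#'   from [compute_gr()]); at least two lines per compound.
#' @param inactive_band half-width of the vehicle-like band (default 0.1,
#'   i.e. within 10% of control).
#' @param decrease GR decrease defining an affected line (default 0.3).
#' @param broad_fraction fraction of affected lines required for the broad
#'   class (default 0.75).
#' @return tibble with one row per compound: `compound_id`, `response`,
#'   `n_lines`, `n_affected`.
#' @export
classify_growth_response <- function(gr, inactive_band = 0.1, decrease = 0.3,
                                     broad_fraction = 0.75) {
  check_columns(gr, c("compound_id", "cell_line", "gr"), "`gr`")
  if (nrow(gr) == 0) abort("empty GR input")
  out <- gr |>
    dplyr::group_by(compound_id = .data$compound_id) |>
    dplyr::summarise(
      n_lines = dplyr::n(),
      n_affected = sum(.data$gr <= 1 - decrease),
      all_vehicle_like = all(.data$gr >= 1 - inactive_band),
      .groups = "drop"
    )
  if (any(out$n_lines < 2)) {
    abort("each compound needs GR values for at least two cell lines")
  }
  out |>
    dplyr::mutate(response = dplyr::case_when(
      .data$all_vehicle_like ~ "inactive",
      .data$n_affected / .data$n_lines >= broad_fraction ~ "broad",
      .data$n_affected > 0 ~ "line_dependent",
      TRUE ~ "inactive"
    )) |>
    dplyr::select("compound_id", "response", "n_lines", "n_affected")
}

#' Classify acute cytotoxicity into tiers
#'
#' Tiers the normalized healthy cell fraction (relative to vehicle) into
#' `nontoxic` (>= 0.8), `reduced` (< 0.8), `severe` (< 0.5) and `extreme`
#' (< 1/3, i.e. a decrease of more than 67%). Tiers are nested and the
#' most severe applicable tier is reported; boundaries are inclusive on
#' the healthier side, so exactly 0.8 is nontoxic and exactly 0.5 is
#' reduced.
#'
#' @param records tibble with a `healthy_fraction` column (>= 0); other
#'   columns (e.g. `compound_id`, `pct_apoptotic`, `pct_necrotic`) pass
#'   through.
#' @return the input tibble with a `tier` factor column appended
#'   (levels nontoxic < reduced < severe < extreme).
#' @export
classify_toxicity <- function(records) {
  check_columns(records, "healthy_fraction", "`records`")
  if (any(records$healthy_fraction < 0, na.rm = TRUE)) {
    abort("`healthy_fraction` must be >= 0")
  }
  records |>
    dplyr::mutate(tier = factor(
      dplyr::case_when(
        .data$healthy_fraction < 1 / 3 ~ "extreme",
        .data$healthy_fraction < 0.5 ~ "severe",
        .data$healthy_fraction < 0.8 ~ "reduced",
        TRUE ~ "nontoxic"
      ),
      levels = c("nontoxic", "reduced", "severe", "extreme"), ordered = TRUE
    )) |>
    as_tibble()
}

#' Aggregate toxicity per target kinase
#'
#' Restricts to kinases covered by at least `min_chemotypes` distinct
#' chemotypes (others are excluded with a warning), averages the
#' normalized healthy fraction over each kinase's inhibitors, and flags
#' kinases whose inhibitors sit significantly below the vehicle replicate
#' distribution. The flag uses a one-sided Welch two-sample t-test
#' (inhibitors < vehicle) with Benjamini-Hochberg correction across
#' kinases — a documented default, configurable via `alpha`.
#'
#' @param kinase_map tibble mapping compounds to covered kinases and
#'   chemotypes: columns `compound_id`, `kinase`, `bin`.
#' @param toxicity tibble with columns `compound_id`, `healthy_fraction`
#'   (one row per compound or per replicate).
#' @param vehicle numeric vector of vehicle-control healthy fractions
#'   (replicates).
#' @param min_chemotypes minimum distinct chemotypes per kinase (default 2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return tibble with one row per retained kinase: `kinase`,
#'   `n_inhibitors`, `n_chemotypes`, `mean_healthy`, `p_value`, `p_adj`,
#'   `flagged`.
#' @export
kinase_toxicity_aggregate <- function(kinase_map, toxicity, vehicle,
                                      min_chemotypes = 2, alpha = 0.05) {
  check_columns(kinase_map, c("compound_id", "kinase", "bin"), "`kinase_map`")
  check_columns(toxicity, c("compound_id", "healthy_fraction"), "`toxicity`")
  no_tox <- setdiff(kinase_map$compound_id, toxicity$compound_id)
  if (length(no_tox)) {
    abort(sprintf("no toxicity record for compound(s): %s",
                  paste(no_tox, collapse = ", ")))
  }
  depth <- kinase_map |>
    dplyr::group_by(kinase = .data$kinase) |>
    dplyr::summarise(n_inhibitors = dplyr::n_distinct(.data$compound_id),
                     n_chemotypes = dplyr::n_distinct(.data$bin),
                     .groups = "drop")
  dropped <- depth$kinase[depth$n_chemotypes < min_chemotypes]
  if (length(dropped)) {
    warn(sprintf("excluding %d kinase(s) with < %d distinct chemotypes: %s",
                 length(dropped), min_chemotypes,
                 paste(head(dropped, 10), collapse = ", ")))
  }
  keep <- depth[depth$n_chemotypes >= min_chemotypes, ]
  if (nrow(keep) == 0) {
    return(tibble(kinase = character(), n_inhibitors = integer(),
                  n_chemotypes = integer(), mean_healthy = double(),
                  p_value = double(), p_adj = double(), flagged = logical()))
  }
  vals <- map(keep$kinase, function(k) {
    cmps <- unique(kinase_map$compound_id[kinase_map$kinase == k])
    toxicity$healthy_fraction[toxicity$compound_id %in% cmps]
  })
  p <- map_dbl(vals, function(v) {
    if (length(v) < 2 || length(vehicle) < 2 ||
        (stats::sd(v) == 0 && stats::sd(vehicle) == 0)) return(NA_real_)
    stats::t.test(v, vehicle, alternative = "less")$p.value
  })
  keep |>
    dplyr::mutate(
      mean_healthy = map_dbl(vals, mean),
      p_value = p,
      p_adj = p.adjust(p, method = "BH"),
      flagged = !is.na(.data$p_adj) & .data$p_adj < alpha
    )
}

#' Normalize autophagic-flux series to the control span
#'
#' Expresses a compound's GFP/RFP reporter ratio at each time point as a
#' percentage of the span between the vehicle series (0%) and the
#' positive-control flux-inducer series (100%) on the same time grid:
#' \deqn{pct(t) = 100 (r_{cmpd}(t) - r_{veh}(t)) / (r_{ctrl}(t) - r_{veh}(t))}
#' Note the GFP reporter is degraded when flux runs, so an *induced* flux
#' typically shows as a ratio drop toward the positive control.
#'
#' @param flux long tibble with columns `compound_id`, `time_h`,
#'   `gfp_rfp_ratio`, `role` (one of `compound`, `vehicle`,
#'   `positive_control`); vehicle and positive control must share the
#'   compound series' time grid and differ at every time point.
#' @return tibble `compound_id`, `time_h`, `pct_flux` for the compound
#'   rows.
#' @export
autophagy_normalize <- function(flux) {
  check_columns(flux, c("compound_id", "time_h", "gfp_rfp_ratio", "role"),
                "`flux`")
  veh <- flux[flux$role == "vehicle", ]
  ctl <- flux[flux$role == "positive_control", ]
  cmp <- flux[flux$role == "compound", ]
  if (!nrow(veh) || !nrow(ctl)) {
    abort("`flux` must contain vehicle and positive_control series")
  }
  grid <- sort(unique(cmp$time_h))
  veh <- veh |> dplyr::group_by(.data$time_h) |>
    dplyr::summarise(veh = mean(.data$gfp_rfp_ratio), .groups = "drop")
  ctl <- ctl |> dplyr::group_by(.data$time_h) |>
    dplyr::summarise(ctl = mean(.data$gfp_rfp_ratio), .groups = "drop")
  if (!all(grid %in% veh$time_h) || !all(grid %in% ctl$time_h)) {
    abort("vehicle/positive_control series do not cover the compound time grid")
  }
  ref <- dplyr::left_join(veh, ctl, by = "time_h")
  degen <- ref$time_h[ref$ctl == ref$veh]
  if (length(degen)) {
    abort(sprintf("degenerate normalization span (control == vehicle) at t = %s h",
                  paste(degen, collapse = ", ")))
  }
  cmp |>
    dplyr::inner_join(ref, by = "time_h") |>
    dplyr::arrange(.data$compound_id, .data$time_h) |>
    dplyr::transmute(
      .data$compound_id, .data$time_h,
      pct_flux = 100 * (.data$gfp_rfp_ratio - .data$veh) /
        (.data$ctl - .data$veh)
    )
}

# First run of >= min_run consecutive TRUEs; returns c(start, length) or NULL.
first_run <- function(flag, min_run) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values & r$lengths >= min_run)
  if (!length(i)) return(NULL)
  c(starts[i[1]], r$lengths[i[1]])
}

#' Call autophagic-flux hits from normalized series
#'
#' A compound is a hit when its percent-flux magnitude exceeds `threshold`
#' (strict `>`) at `min_run` or more consecutive time points. The first
#' qualifying run is reported; its sign gives the direction (`induced`
#' when the run is positive toward the flux-inducer control, `reduced`
#' when negative).
#'
#' @param pct tibble from [autophagy_normalize()] (`compound_id`, `time_h`,
#'   `pct_flux`); every compound needs at least `min_run` time points.
#' @param threshold percent aberration (default 20, strict).
#' @param min_run minimum consecutive time points (default 5).
#' @return tibble with one row per compound: `compound_id`, `is_hit`,
#'   `direction` (NA for non-hits), `run_start` (index into the ordered
#'   series), `run_length`.
#' @export
autophagy_hit_call <- function(pct, threshold = 20, min_run = 5) {
  check_columns(pct, c("compound_id", "time_h", "pct_flux"), "`pct`")
  check_positive_scalar(threshold, "threshold")
  pct |>
    dplyr::arrange(.data$compound_id, .data$time_h) |>
    dplyr::group_by(compound_id = .data$compound_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_run) {
        abort(sprintf("series for '%s' has fewer than %d time points",
                      key$compound_id, min_run))
      }
      run <- first_run(abs(df$pct_flux) > threshold, min_run)
      if (is.null(run)) {
        tibble(is_hit = FALSE, direction = NA_character_,
               run_start = NA_integer_, run_length = NA_integer_)
      } else {
        seg <- df$pct_flux[run[1]:(run[1] + run[2] - 1)]
        tibble(
          is_hit = TRUE,
          direction = if (mean(seg) > 0) "induced" else "reduced",
          run_start = as.integer(run[1]),
          run_length = as.integer(run[2])
        )
      }
    }) |>
    dplyr::ungroup()
}

#' Categorize autophagy hits
#'
#' Places each hit into one of six categories from the direction of the
#' flux change crossed with the cell state: proliferation reduced,
#' proliferation unchanged with abnormal appearance, or proliferation
#' unchanged with normal appearance. This 2 x 3 scheme is this package's
#' documented convention for summarizing flux screens; `increased`
#' proliferation is treated as unchanged on the proliferation axis.
#'
#' | category | flux | cell state |
#' |---|---|---|
#' | 1 | induced | unchanged proliferation, normal appearance |
#' | 2 | reduced | unchanged proliferation, normal appearance |
#' | 3 | induced | unchanged proliferation, abnormal appearance |
#' | 4 | reduced | unchanged proliferation, abnormal appearance |
#' | 5 | induced | reduced proliferation |
#' | 6 | reduced | reduced proliferation |
#'
#' @param hits tibble from [autophagy_hit_call()]; non-hit rows are an
#'   error.
#' @param proliferation character vector (per hit) in
#'   `c("reduced", "unchanged", "increased")`.
#' @param appearance character vector (per hit) in
#'   `c("normal", "abnormal")`.
#' @return `hits` with a `category` integer column appended.
#' @export
autophagy_categorize <- function(hits, proliferation, appearance) {
  check_columns(hits, c("compound_id", "is_hit", "direction"), "`hits`")
  if (any(!hits$is_hit)) {
    abort(sprintf("non-hit compound(s) cannot be categorized: %s",
                  paste(hits$compound_id[!hits$is_hit], collapse = ", ")))
  }
  proliferation <- rlang::arg_match(proliferation,
                                    c("reduced", "unchanged", "increased"),
                                    multiple = TRUE)
  appearance <- rlang::arg_match(appearance, c("normal", "abnormal"),
                                 multiple = TRUE)
  stopifnot(length(proliferation) == nrow(hits),
            length(appearance) == nrow(hits))
  state <- ifelse(proliferation == "reduced", "prolif_reduced",
                  ifelse(appearance == "abnormal", "unchanged_abnormal",
                         "unchanged_normal"))
  induced <- hits$direction == "induced"
  category <- dplyr::case_when(
    state == "unchanged_normal" & induced ~ 1L,
    state == "unchanged_normal" & !induced ~ 2L,
    state == "unchanged_abnormal" & induced ~ 3L,
    state == "unchanged_abnormal" & !induced ~ 4L,
    state == "prolif_reduced" & induced ~ 5L,
    state == "prolif_reduced" & !induced ~ 6L
  )
  dplyr::mutate(hits, category = category)
}
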