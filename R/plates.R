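# Plate logistics: assay-budget arithmetic and deterministic 384-well
# plate-map generation.

#' Number of assays supported by a compound aliquot
#'
#' Nanomoles available in the stock aliquot divided by nanomoles consumed
#' per assay well, floored — partial assays do not count. A 1 uL aliquot of
#' a 10 mM stock supports 100 assays at 1 uM final concentration in a
#' 100 uL working volume (96-well format) and 200 assays in 50 uL
#' (384-well format).
#'
#' @param stock_vol_uL stock aliquot volume in microliters.
#' @param stock_mM stock concentration in millimolar.
#' @param assay_uM final assay concentration in micromolar.
#' @param well_vol_uL working volume per well in microliters.
#' @return integer number of assays.
#' @examples
#' assay_budget(1, 10, 1, 100) # 100
#' assay_budget(1, 10, 1, 50)  # 200
#' @export
assay_budget <- function(stock_vol_uL, stock_mM, assay_uM, well_vol_uL) {
  check_positive_scalar(stock_vol_uL, "stock_vol_uL")
  check_positive_scalar(stock_mM, "stock_mM")
  check_positive_scalar(assay_uM, "assay_uM")
  check_positive_scalar(well_vol_uL, "well_vol_uL")
  # nanomoles in stock: uL * mM = nmol; per well: uM * uL * 1e-3 = nmol
  as.integer(floor((stock_vol_uL * stock_mM) /
                     (assay_uM * well_vol_uL * 1e-3)))
}

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

# Well coordinates of a 384-well plate in the requested fill order.
well_order <- function(fill_order) {
  if (fill_order == "row-major") {
    paste0(rep(PLATE_ROWS, each = length(PLATE_COLS)), PLATE_COLS)
  } else {
    paste0(rep(PLATE_ROWS, times = length(PLATE_COLS)),
           rep(PLATE_COLS, each = length(PLATE_ROWS)))
  }
}

#' Build a deterministic 384-well plate map
#'
#' Controls are placed first (by default into column 1, top down), then
#' compounds fill the remaining wells in the requested order. The same
#' inputs always produce the same layout, and writing then reading the CSV
#' reproduces the map exactly.
#'
#' @param compounds ordered character vector of compound ids.
#' @param controls named character vector of control labels; names are well
#'   coordinates (e.g. `c(A1 = "DMSO")`), or an unnamed vector to use the
#'   default column-1 positions.
#' @param fill_order `"row-major"` (A1, A2, ...) or `"column-major"`
#'   (A1, B1, ...).
#' @param plate_id plate identifier (default "P1").
#' @param volume_uL per-well volume (default 1).
#' @param conc_mM per-well concentration in mM (default 10).
#' @return tibble with columns `plate`, `well`, `content`, `role`
#'   (`compound` or `control`), `volume_uL`, `conc_mM`, in plate fill
#'   order.
#' @export
build_platemap <- function(compounds, controls = character(),
                           fill_order = c("row-major", "column-major"),
                           plate_id = "P1", volume_uL = 1, conc_mM = 10) {
  fill_order <- match.arg(fill_order)
  if (any(duplicated(compounds))) abort("duplicate compound id(s)")
  wells <- well_order(fill_order)
  if (length(controls) && is.null(names(controls))) {
    names(controls) <- paste0(PLATE_ROWS, 1)[seq_along(controls)]
  }
  bad <- setdiff(names(controls), wells)
  if (length(bad)) {
    abort(sprintf("invalid control well(s): %s", paste(bad, collapse = ", ")))
  }
  free <- setdiff(wells, names(controls))
  if (length(compounds) > length(free)) {
    need <- ceiling((length(compounds) + length(controls)) / 384)
    abort(sprintf(
      "%d compounds + %d controls exceed one 384-well plate; %d plates required",
      length(compounds), length(controls), need
    ))
  }
  rows <- dplyr::bind_rows(
    tibble(well = names(controls), content = unname(controls),
           role = "control"),
    tibble(well = free[seq_along(compounds)], content = compounds,
           role = "compound")
  )
  rows <- rows[order(match(rows$well, wells)), ]
  tibble(plate = plate_id, well = rows$well, content = rows$content,
         role = rows$role, volume_uL = volume_uL, conc_mM = conc_mM)
}

#' Write a plate map CSV
#' @param platemap tibble from [build_platemap()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_platemap <- function(platemap, path) {
  readr::write_csv(platemap, path, progress = FALSE)
  invisible(path)
}

#' Read a plate map CSV
#' @param path CSV written by [write_platemap()].
#' @return plate map tibble.
#' @export
read_platemap <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("plate", "well", "content", "role", "volume_uL",
                      "conc_mM"), "plate map")
  if (any(duplicated(df[, c("plate", "well")]))) {
    abort("well coordinate assigned twice")
  }
  ok <- grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", df$well)
  if (!all(ok)) {
    abort(sprintf("invalid well coordinate(s): %s",
                  paste(df$well[!ok], collapse = ", ")))
  }
  as_tibble(df)
}
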