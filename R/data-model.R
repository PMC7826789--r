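# Domain containers and validated readers/writers: compounds, kinase
# panels, percent-of-control (PoC) matrices, K_D follow-up tables.

#' Read a compound list (SMILES or SDF)
#'
#' Compounds are the inhibitors submitted for kinome profiling. Two formats
#' are accepted: a whitespace/tab-separated SMILES file with one
#' `SMILES<TAB>id` record per line, or an SDF with the compound identifier
#' in a named data field. Every structure is validated against the Open
#' Babel parser; failures are hard errors that name the offending record.
#'
#' @param path file path (`.smi`/`.smiles` text or `.sdf`).
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @param id_field SDF data field holding the compound id (default `"ID"`;
#'   falls back to the molecule title when the field is absent).
#' @param source optional provenance string recorded on every compound.
#' @param screen_panel optional panel identifier recorded on every compound.
#' @return a tibble with columns `id`, `smiles`, `source`, `screen_panel`.
#' @seealso [write_compounds()], [read_poc_matrix()]
#' @export
read_compounds <- function(path, format = c("auto", "smiles", "sdf"),
                           id_field = "ID", source = NA_character_,
                           screen_panel = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(tibble(id = character(), smiles = character(),
                    source = character(), screen_panel = character()))
    }
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) < 2)
    if (length(bad)) {
      abort(sprintf("line(s) %s lack an id field (expected 'SMILES<TAB>id')",
                    paste(bad, collapse = ", ")))
    }
    smiles <- map_chr(parts, 1)
    ids <- map_chr(parts, 2)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdf)
    if (!all(valid)) {
      abort(sprintf("unparseable structure at SDF record(s) %s",
                    paste(which(!valid), collapse = ", ")))
    }
    blocks <- ChemmineR::datablock(sdf)
    ids <- map_chr(seq_along(sdf), function(i) {
      db <- blocks[[i]]
      if (length(db) && id_field %in% names(db)) db[[id_field]]
      else ChemmineR::sdfid(sdf[i])
    })
    smiles <- as.character(ChemmineR::sdf2smiles(sdf))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    occ <- which(ids %in% dup)
    abort(sprintf("duplicate compound id(s) %s at record(s) %s",
                  paste(unique(dup), collapse = ", "),
                  paste(occ, collapse = ", ")))
  }
  ok <- smiles_is_valid(smiles)
  if (!all(ok)) {
    abort(sprintf("unparseable structure at record(s) %s (id: %s)",
                  paste(which(!ok), collapse = ", "),
                  paste(ids[!ok], collapse = ", ")))
  }
  tibble(id = ids, smiles = smiles, source = source,
         screen_panel = screen_panel)
}

#' Write a compound list as a SMILES file
#'
#' Emits `SMILES<TAB>id` lines, the format [read_compounds()] reads back;
#' write-then-read is the identity on `id` and `smiles`.
#'
#' @param compounds tibble with columns `id` and `smiles`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  check_columns(compounds, c("id", "smiles"), "`compounds`")
  writeLines(paste(compounds$smiles, compounds$id, sep = "\t"), path)
  invisible(path)
}

#' Read a kinase assay panel definition
#'
#' A panel lists the kinase assays a profiling matrix was screened against:
#' gene symbol, kinome family, and flags for wild-type and human assays.
#' Families must come from the ten-family kinome vocabulary (AGC, Atypical,
#' CAMK, CK1, CMGC, Lipid, Other, STE, TK, TKL).
#'
#' @param path TSV with columns `kinase`, `family`, `is_wild_type`,
#'   `is_human` (flags as 0/1 or TRUE/FALSE).
#' @param concentration screening concentration in micromolar attached to
#'   the panel (default 1).
#' @param name panel name (default: file base name).
#' @return a tibble with the four columns above plus attributes
#'   `concentration` and `name`.
#' @export
read_panel <- function(path, concentration = 1, name = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("kinase", "family", "is_wild_type", "is_human"),
                "panel file")
  panel <- tibble(
    kinase = as.character(df$kinase),
    family = as.character(df$family),
    is_wild_type = as.logical(df$is_wild_type),
    is_human = as.logical(df$is_human)
  )
  kinase_panel(panel, concentration = concentration,
               name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct and validate a kinase panel
#'
#' @param panel data frame with columns `kinase`, `family`, `is_wild_type`,
#'   `is_human`.
#' @param concentration screening concentration in micromolar (> 0).
#' @param name panel name.
#' @return validated panel tibble with `concentration` and `name` attributes.
#' @export
kinase_panel <- function(panel, concentration = 1, name = "panel") {
  check_columns(panel, c("kinase", "family", "is_wild_type", "is_human"),
                "`panel`")
  check_positive_scalar(concentration, "concentration")
  if (nrow(panel) == 0) abort("a panel must contain at least one assay")
  dup <- unique(panel$kinase[duplicated(panel$kinase)])
  if (length(dup)) {
    abort(sprintf("duplicate kinase symbol(s) in panel: %s",
                  paste(dup, collapse = ", ")))
  }
  bad_fam <- setdiff(unique(panel$family), KINASE_FAMILIES)
  if (length(bad_fam)) {
    abort(sprintf("unknown kinase family(ies): %s (expected one of %s)",
                  paste(bad_fam, collapse = ", "),
                  paste(KINASE_FAMILIES, collapse = ", ")))
  }
  out <- as_tibble(panel)
  attr(out, "concentration") <- concentration
  attr(out, "name") <- name
  out
}

#' Read a percent-of-control profiling matrix
#'
#' The matrix holds percent-of-control (PoC) values from a broad kinase
#' binding panel screened at a single concentration: 0 means complete
#' inhibition, 100 no effect, and values above 100 occur. The CSV is wide:
#' first column `compound_id`, one column per kinase gene symbol. Empty
#' cells are preserved as missing (`NA`), never coerced to zero; missing
#' cells shrink the denominator of downstream selectivity indices.
#'
#' @param path CSV path.
#' @param panel panel tibble from [read_panel()] or [kinase_panel()]; every
#'   matrix column must name a kinase present in the panel.
#' @return a long tibble of class `poc_matrix` with columns `compound_id`,
#'   `kinase`, `poc` (NA = not assayed), carrying the panel as an attribute.
#' @export
read_poc_matrix <- function(path, panel) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          na = c("", "NA"))
  check_columns(wide, "compound_id", "PoC matrix")
  poc_matrix(wide, panel)
}

#' Construct and validate a PoC matrix
#'
#' Accepts either a wide data frame (`compound_id` plus one column per
#' kinase) or a long one (`compound_id`, `kinase`, `poc`).
#'
#' @inheritParams read_poc_matrix
#' @param x wide or long data frame of PoC values.
#' @return long `poc_matrix` tibble (see [read_poc_matrix()]).
#' @export
poc_matrix <- function(x, panel) {
  if (is.null(attr(panel, "concentration"))) {
    panel <- kinase_panel(panel)
  }
  if (all(c("compound_id", "kinase", "poc") %in% names(x))) {
    long <- as_tibble(x)[, c("compound_id", "kinase", "poc")]
  } else {
    check_columns(x, "compound_id", "`x`")
    long <- tidyr::pivot_longer(as_tibble(x), -"compound_id",
                                names_to = "kinase", values_to = "poc")
  }
  long$compound_id <- as.character(long$compound_id)
  long$kinase <- as.character(long$kinase)
  long$poc <- as.numeric(long$poc)
  unknown <- setdiff(unique(long$kinase), panel$kinase)
  if (length(unknown)) {
    abort(sprintf("matrix column(s) name kinase(s) absent from the panel: %s",
                  paste(unknown, collapse = ", ")))
  }
  neg <- long$poc < 0 & !is.na(long$poc)
  if (any(neg)) {
    abort(sprintf("negative PoC value(s) for %s",
                  paste(unique(long$compound_id[neg]), collapse = ", ")))
  }
  dup <- duplicated(long[, c("compound_id", "kinase")])
  if (any(dup)) abort("duplicate (compound, kinase) cell(s) in matrix")
  out <- long
  attr(out, "panel") <- panel
  class(out) <- c("poc_matrix", class(tibble()))
  out
}

#' @export
print.poc_matrix <- function(x, ...) {
  panel <- attr(x, "panel")
  cat(sprintf(
    "<poc_matrix> %d compound(s) x %d kinase column(s); panel '%s' (%d assays, %g uM); %d missing cell(s)\n",
    dplyr::n_distinct(x$compound_id), dplyr::n_distinct(x$kinase),
    attr(panel, "name") %||% "panel", nrow(panel),
    attr(panel, "concentration") %||% NA_real_, sum(is.na(x$poc))
  ))
  NextMethod()
}

# Panel accessor (also works on anything carrying a "panel" attribute).
#' Extract the assay panel attached to a PoC matrix
#' @param x a `poc_matrix`.
#' @return the panel tibble.
#' @export
poc_panel <- function(x) {
  p <- attr(x, "panel")
  if (is.null(p)) abort("`x` carries no panel attribute; is it a poc_matrix?")
  p
}

#' Write a PoC matrix as wide CSV
#'
#' Missing cells are written as empty strings so that a read-back through
#' [read_poc_matrix()] reproduces the matrix exactly.
#'
#' @param x `poc_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_poc_matrix <- function(x, path) {
  wide <- tidyr::pivot_wider(as_tibble(x), names_from = "kinase",
                             values_from = "poc")
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Read a K_D follow-up table
#'
#' Dissociation constants from full dose-response follow-up on the kinases
#' flagged by the primary screen. Values are in nanomolar and must be
#' strictly positive.
#'
#' @param path TSV with columns `compound`, `kinase`, `kd_nM`.
#' @return tibble with those three columns (`kd_nM` numeric).
#' @export
read_kd_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, c("compound", "kinase", "kd_nM"), "K_D table")
  kd <- suppressWarnings(as.numeric(df$kd_nM))
  bad <- which(is.na(kd) | kd <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive or non-numeric kd_nM at row(s) %s",
                  paste(bad, collapse = ", ")))
  }
  tibble(compound = as.character(df$compound),
         kinase = as.character(df$kinase), kd_nM = kd)
}

#' Write a K_D table
#' @param kd tibble with columns `compound`, `kinase`, `kd_nM`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_kd_table <- function(kd, path) {
  check_columns(kd, c("compound", "kinase", "kd_nM"), "`kd`")
  readr::write_tsv(kd, path, progress = FALSE)
  invisible(path)
}

#' Write a panel definition
#' @param panel panel tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  check_columns(panel, c("kinase", "family", "is_wild_type", "is_human"),
                "`panel`")
  out <- as_tibble(panel)
  out$is_wild_type <- as.integer(out$is_wild_type)
  out$is_human <- as.integer(out$is_human)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
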