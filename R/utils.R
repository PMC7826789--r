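# Shared internal helpers: rounding, SMILES validation, input checks.

#' Round half-up
#'
#' Rounds to `digits` decimal places with halves always rounded away from
#' zero toward the next integer (so 37.5 -> 38), unlike base [round()]'s
#' round-half-even. Coverage percentages in the reporting functions use this
#' convention because it reproduces the usual hand-rounded tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(c(37.5, 66.67, 0.5, 2.5))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Parse a vector of SMILES into an SDFset, erroring with the offending
# record index. Open Babel (via ChemmineOB) is the parsing engine.
# Returns the SDFset invisibly; used both for validation and matching.
parse_smiles <- function(smiles, ids = NULL) {
  ids <- ids %||% paste0("mol", seq_along(smiles))
  stopifnot(length(smiles) == length(ids))
  ok <- smiles_is_valid(smiles)
  if (!all(ok)) {
    bad <- which(!ok)
    abort(sprintf(
      "unparseable structure at record(s) %s (id: %s; smiles: %s)",
      paste(bad, collapse = ", "),
      paste(ids[bad], collapse = ", "),
      paste(smiles[bad], collapse = ", ")
    ))
  }
  suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids)))
}

#' Validate SMILES strings
#'
#' Checks each string against the Open Babel parser without raising an
#' error. Used by the readers to report parse failures by record index.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string parses to a molecule.
#' @export
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    tryCatch(
      {
        suppressWarnings(ChemmineR::smiles2sdf(c(x = s)))
        TRUE
      },
      error = function(e) FALSE
    )
  }, logical(1), USE.NAMES = FALSE)
}

# Stop unless `df` has all of `cols`; `what` names the input in the message.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}
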