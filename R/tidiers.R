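# broom-style tidiers for the assembled-set object.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an assembled chemogenomic set
#'
#' One row per selected compound, in selection order, with its chemotype,
#' S10, marginal coverage gain and greedy step.
#'
#' @param x a `kinoset_set` from [greedy_assemble()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.kinoset_set <- function(x, ...) {
  x$compounds
}

#' One-row summary of an assembled chemogenomic set
#'
#' @param x a `kinoset_set` from [greedy_assemble()].
#' @param ... unused.
#' @return a one-row tibble: `n_compounds`, `n_kinases_covered`,
#'   `n_kinases_multi` (>= 2 distinct chemotypes), `n_kinases_single`,
#'   `n_chemotypes`, `depth_target`.
#' @export
glance.kinoset_set <- function(x, ...) {
  red <- redundancy_report(x$depth)
  tibble(
    n_compounds = nrow(x$compounds),
    n_kinases_covered = nrow(x$depth),
    n_kinases_multi = red$n_kinases_multi,
    n_kinases_single = red$n_kinases_single,
    n_chemotypes = dplyr::n_distinct(x$compounds$bin),
    depth_target = x$config$depth_target
  )
}
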