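#' Zero-out attribution: prescribed-fire concentration delta
#'
#' The PF-attributable field is the pointwise difference between the
#' baseline (all emissions) and the zero-out (no PF emissions) runs:
#' `delta(x, t) = C_all(x, t) - C_no_pf(x, t)`.  No clamping is applied -
#' under nonlinear chemistry real models can produce locally negative
#' deltas, and clamping would silently destroy mass consistency.  A
#' flooring option exists at the aggregation stage instead.
#'
#' @param pair A [scenario_pair()].
#' @param species Which species' delta to compute.
#' @return A `pf_field` with scenario `"delta_pf"`.
#' @export
pf_delta <- function(pair, species = "PM25_TOT") {
  stopifnot(inherits(pair, "pf_scenario_pair"))
  species <- match.arg(species, PF_SPECIES)
  a <- pair$all_emissions[[species]]
  b <- pair$no_pf[[species]]
  if (is.null(a) || is.null(b))
    stop(sprintf("species %s not present in both scenario members", species))
  stop_if_misaligned(a, b, "scenario members")
  field_series(a$grid, a$dates, species, "delta_pf", a$values - b$values)
}

#' PF deltas for every species in a pair
#' @param pair A [scenario_pair()].
#' @return Named list of `delta_pf` fields.
#' @export
pf_delta_all <- function(pair) {
  stats::setNames(lapply(names(pair$all_emissions), function(s) pf_delta(pair, s)),
                  names(pair$all_emissions))
}
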