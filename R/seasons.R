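#' Burning-season definition
#'
#' Maps each calendar month to one of the three southeastern-US burning
#' seasons: JFMA (January-April, the extensive burning season), MJJAS
#' (May-September, least active), OND (October-December, moderate).
#'
#' @param mapping Character vector of length 12 (months Jan..Dec) of season
#'   labels.  Every month must be mapped exactly once.
#' @return A `pf_seasons` object (named character vector).
#' @export
season_definition <- function(mapping = c(rep("JFMA", 4), rep("MJJAS", 5), rep("OND", 3))) {
  if (length(mapping) != 12L || anyNA(mapping))
    stop("season mapping must assign all 12 months")
  structure(stats::setNames(as.character(mapping), month.abb), class = "pf_seasons")
}

#' Season label of each date
#' @param dates Date vector.
#' @param seasons A [season_definition()].
#' @return Character vector of season labels.
#' @export
season_of <- function(dates, seasons = season_definition()) {
  unname(unclass(seasons)[as.integer(format(as.Date(dates), "%m"))])
}
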