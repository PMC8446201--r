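#' Reference (co)variance components for Holstein reproductive traits
#'
#' Published single-trait estimates for the correlated service-sire/dam
#' model on five female reproductive traits in Chinese Holstein cattle:
#' conception rate (CR), 56-day non-return rate (NRR56), calving ease (CE),
#' stillbirth (SB) and gestation length (GL, days). The seven parameters
#' per trait are, in order: service-sire additive variance, sire-dam
#' additive covariance, dam additive variance, service-sire and dam
#' permanent-environment variances, herd-year-month variance and residual
#' variance. These serve as default simulation truth and as inputs to the
#' worked examples of the derived-parameter formulas.
#'
#' @param trait Optional trait name (`"CR"`, `"NRR56"`, `"CE"`, `"SB"`,
#'   `"GL"`); if given, a named numeric vector for that trait is returned,
#'   otherwise the full table.
#' @return A data frame (parameter x trait) or a named numeric vector.
#' @export
reference_components <- function(trait = NULL) {
  path <- system.file("extdata", "reference_components.csv", package = "gesskit",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(trait)) return(tab)
  trait <- match.arg(trait, c("CR", "NRR56", "CE", "SB", "GL"))
  stats::setNames(tab[[trait]], tab$parameter)
}

#' Bundle a 7-parameter vector into a variance-component object
#'
#' Convenience constructor for [varcomp()] from a named vector in the
#' order used by [reference_components()].
#' @param x Named numeric vector with elements `sigma2_ss`, `sigma_ssd`,
#'   `sigma2_d`, `sigma2_pess`, `sigma2_ped`, `sigma2_hym`, `sigma2_e`.
#' @return A `gess_varcomp` object.
#' @export
as_varcomp <- function(x) {
  varcomp(sigma2_ss = x[["sigma2_ss"]], sigma_ssd = x[["sigma_ssd"]],
          sigma2_d = x[["sigma2_d"]], sigma2_pess = x[["sigma2_pess"]],
          sigma2_ped = x[["sigma2_ped"]], sigma2_hym = x[["sigma2_hym"]],
          sigma2_e = x[["sigma2_e"]])
}
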