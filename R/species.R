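#' THM species labels
#'
#' The four regulated trihalomethanes, in the fixed order used throughout
#' the package: trichloromethane (TCM, chloroform), bromodichloromethane
#' (BDCM), dibromochloromethane (DBCM) and tribromomethane (TBM,
#' bromoform).
#'
#' @return Character vector of species codes.
#' @export
thm_species <- function() c("tcm", "bdcm", "dbcm", "tbm")

#' Default per-species physical and toxicological constants
#'
#' Transport and dose-response constants for the four THM species:
#' \describe{
#'   \item{henry}{dimensionless Henry's constant at 40 degC (water-air
#'     partitioning during a hot shower; held fixed, not adjusted for the
#'     sampled water temperature).}
#'   \item{kola}{overall mass-transfer coefficient times interfacial area
#'     for a shower, KoLA, in L/min.}
#'   \item{csf_oral}{oral cancer slope factor, (mg/kg/day)^-1, applied to
#'     both the ingestion and the dermal route (no dermal-specific slope
#'     factors exist).}
#'   \item{iur}{inhalation unit risk, (ug/m^3)^-1.}
#' }
#'
#' @return data.frame with one row per species and columns
#'   \code{species}, \code{henry}, \code{kola}, \code{csf_oral},
#'   \code{iur}.
#' @examples
#' default_species_constants()
#' @export
default_species_constants <- function() {
  data.frame(
    species  = thm_species(),
    henry    = c(0.25, 0.124, 0.0526, 0.0501),
    kola     = c(7.4, 5.9, 4.6, 3.7),
    csf_oral = c(0.0061, 0.062, 0.084, 0.0079),
    iur      = c(2.3e-5, 3.7e-5, 2.4e-5, 1.1e-6),
    stringsAsFactors = FALSE
  )
}
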