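#' Body surface area
#'
#' Population-specific rational form \code{SA = (4 BW + 7) / (BW + 90)}
#' (m^2), appropriate for adult South-Asian body habitus; monotone in body
#' weight with supremum 4 m^2.
#'
#' @param bw body weight, kg, \code{> 0}.
#' @return Skin surface area, m^2.
#' @examples
#' surface_area(65)   # 1.7226
#' @export
surface_area <- function(bw) {
  if (any(bw <= 0)) stop("bw must be > 0", call. = FALSE)
  (4 * bw + 7) / (bw + 90)
}

#' THM formation rate in chlorinated water
#'
#' Residual chlorine keeps forming THM while water is stored or heated;
#' the first-order formation rate grows exponentially with temperature:
#' \code{k(T) = 0.0011 exp(0.0407 T)} per minute, \code{T} in degC.
#'
#' @param temp water temperature, degC (guarded to \code{[0, 100]}).
#' @return Formation rate, min^-1.
#' @examples
#' formation_rate(40)   # 0.0056
#' @export
formation_rate <- function(temp) {
  if (any(temp < 0 | temp > 100))
    stop("temp must lie in [0, 100] degC", call. = FALSE)
  0.0011 * exp(0.0407 * temp)
}

#' Heated-water THM concentration
#'
#' During a shower of duration \code{t} the water is heated, and extra THM
#' forms relative to the cold tap: \code{Chw = Cw exp((kh - kc) t)} with
#' \code{kh}, \code{kc} the formation rates at the hot and cold
#' temperatures. The dermal and inhalation routes use \code{Chw}; the
#' ingestion route keeps the cold-water \code{Cw} (drinking water is not
#' heated).
#'
#' @param cw cold-water concentration, ug/L.
#' @param t shower duration, min, \code{>= 0}.
#' @param temp_hot,temp_cold hot and cold water temperatures, degC.
#' @return Heated-water concentration, ug/L; \code{>= cw} whenever
#'   \code{temp_hot >= temp_cold}.
#' @examples
#' heated_concentration(10, 10, 40, 15)   # 10.364
#' @export
heated_concentration <- function(cw, t, temp_hot, temp_cold) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  cw * exp((formation_rate(temp_hot) - formation_rate(temp_cold)) * t)
}

#' Chronic daily intake via ingestion
#'
#' \code{CDI = Cw IR EF ED CF / (BW AT)} with \code{CF = 0.001} converting
#' ug to mg.
#'
#' @param cw water concentration, ug/L.
#' @param ir ingestion rate, L/day.
#' @param ef exposure frequency, days/yr.
#' @param ed exposure duration, yr.
#' @param bw body weight, kg, \code{> 0}.
#' @param at averaging time, days, \code{> 0}.
#' @return Chronic daily intake, mg kg^-1 day^-1.
#' @examples
#' cdi_ingestion(30.22, 2, 350, 72, 55, 26280)
#' @export
cdi_ingestion <- function(cw, ir, ef, ed, bw, at) {
  if (any(bw <= 0) || any(at <= 0))
    stop("bw and at must be > 0", call. = FALSE)
  cw * ir * ef * ed * 0.001 / (bw * at)
}

#' Chronic daily intake via dermal absorption
#'
#' \code{CDI = Chw SA Pd t F EF ED / (BW AT)}. The implicit L-to-m^3
#' (x1000) and ug-to-mg (x0.001) conversions cancel, so the product
#' applied to a ug/L concentration with SA in m^2 and Pd in m/min yields
#' mg kg^-1 day^-1 directly.
#'
#' @param chw heated-water concentration, ug/L.
#' @param sa skin surface area, m^2.
#' @param pd skin permeability, m/min.
#' @param t shower duration, min/event.
#' @param f showering frequency, events/day.
#' @param ef exposure frequency, days/yr.
#' @param ed exposure duration, yr.
#' @param bw body weight, kg, \code{> 0}.
#' @param at averaging time, days, \code{> 0}.
#' @return Chronic daily intake, mg kg^-1 day^-1.
#' @export
cdi_dermal <- function(chw, sa, pd, t, f, ef, ed, bw, at) {
  if (any(bw <= 0) || any(at <= 0))
    stop("bw and at must be > 0", call. = FALSE)
  chw * sa * pd * t * f * ef * ed / (bw * at)
}

#' Daily exposure time in the shower
#'
#' \code{ET = t F / 60} hours/day: duration per event times events per
#' day, converted from minutes.
#'
#' @param t shower duration, min/event, \code{>= 0}.
#' @param f showering frequency, events/day, \code{>= 0}.
#' @return Exposure time, h/day.
#' @examples
#' exposure_time(10, 0.74)   # 0.1233
#' @export
exposure_time <- function(t, f) {
  if (any(t < 0) || any(f < 0)) stop("t and f must be >= 0", call. = FALSE)
  t * f / 60
}

#' Inhalation exposure concentration
#'
#' Time-weighted air concentration over the averaging time:
#' \code{EC = Cair ET EF ED / AT} with the averaging time in hours.
#'
#' @param cair shower-air concentration, ug/m^3.
#' @param et exposure time, h/day.
#' @param ef exposure frequency, days/yr.
#' @param ed exposure duration, yr.
#' @param at_hours averaging time, hours, \code{> 0} (days x 24).
#' @return Exposure concentration, ug/m^3.
#' @examples
#' exposure_concentration(100, 0.1233, 330, 72, 630720)
#' @export
exposure_concentration <- function(cair, et, ef, ed, at_hours) {
  if (any(at_hours <= 0)) stop("at_hours must be > 0", call. = FALSE)
  cair * et * ef * ed / at_hours
}

#' Cancer risk conversions
#'
#' Linear low-dose extrapolation: \code{CR = CDI x CSF} for the oral
#' (ingestion and dermal) routes, and \code{CR = EC x IUR} for
#' inhalation. The oral slope factor is applied to the dermal dose because
#' no dermal-specific slope factors exist.
#'
#' @param cdi chronic daily intake, mg kg^-1 day^-1, \code{>= 0}.
#' @param csf oral cancer slope factor, (mg kg^-1 day^-1)^-1, \code{>= 0}.
#' @return Dimensionless incremental lifetime cancer risk.
#' @examples
#' cancer_risk_oral(3.55e-4, 0.084)
#' cancer_risk_inhalation(0.1, 2.3e-5)
#' @export
cancer_risk_oral <- function(cdi, csf) {
  if (any(cdi < 0) || any(csf < 0))
    stop("cdi and csf must be >= 0", call. = FALSE)
  cdi * csf
}

#' @rdname cancer_risk_oral
#' @param ec exposure concentration, ug/m^3, \code{>= 0}.
#' @param iur inhalation unit risk, (ug/m^3)^-1, \code{>= 0}.
#' @export
cancer_risk_inhalation <- function(ec, iur) {
  if (any(ec < 0) || any(iur < 0))
    stop("ec and iur must be >= 0", call. = FALSE)
  ec * iur
}

#' Total cancer risk across species and routes
#'
#' Sums a complete species-by-route risk grid. Route totals, species
#' totals and the grand total are exact sums, and the grand total equals
#' both the sum of route totals and the sum of species totals (a
#' conservation check callers can rely on).
#'
#' @param risks numeric matrix or data.frame, rows = species, columns =
#'   routes, no missing cells.
#' @return list with \code{by_route}, \code{by_species}, \code{grand}.
#' @examples
#' m <- matrix(1e-6 * c(1, 2, 3, 4, 5, 6), 2,
#'             dimnames = list(c("tcm", "bdcm"), c("ing", "der", "inh")))
#' total_risk(m)
#' @export
total_risk <- function(risks) {
  m <- as.matrix(risks)
  if (any(is.na(m)))
    stop("risk grid has missing cells", call. = FALSE)
  list(by_route = colSums(m), by_species = rowSums(m), grand = sum(m))
}
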