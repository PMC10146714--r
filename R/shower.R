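#' Shower scenario
#'
#' Geometry and operating conditions of one shower stall, validated once
#' and passed to [event_series()].
#'
#' @param vs stall (bathroom) volume, L, \code{> 0}.
#' @param qw water flow, L/min, \code{> 0}.
#' @param qg ventilation air flow, L/min, \code{>= 0}.
#' @param t shower duration, min, \code{> 0}.
#' @param n_events number of back-to-back showering events, \code{>= 1}.
#' @return list of class \code{"shower_scenario"}.
#' @export
shower_scenario <- function(vs, qw, qg, t, n_events = 1L) {
  if (any(vs <= 0)) stop("vs must be > 0", call. = FALSE)
  if (any(qw <= 0)) stop("qw must be > 0", call. = FALSE)
  if (any(qg < 0)) stop("qg must be >= 0", call. = FALSE)
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  structure(list(vs = vs, qw = qw, qg = qg, t = t,
                 n_events = as.integer(n_events)),
            class = "shower_scenario")
}

#' Dimensionless mass-transfer coefficient
#'
#' N = KoLA / Qw, the overall mass-transfer coefficient non-dimensionalized
#' by the water flow; \code{1 - exp(-N)} is the fraction of a THM's
#' equilibrium transfer achieved during the water's transit through the
#' shower.
#'
#' @param kola overall mass-transfer coefficient KoLA, L/min, \code{>= 0}.
#' @param qw water flow, L/min, \code{> 0}.
#' @return Dimensionless N.
#' @examples
#' dimensionless_N(7.4, 4)   # 1.85
#' @export
dimensionless_N <- function(kola, qw) {
  if (any(qw <= 0)) stop("qw must be > 0", call. = FALSE)
  if (any(kola < 0)) stop("kola must be >= 0", call. = FALSE)
  kola / qw
}

#' Volatilization source and loss coefficients
#'
#' Coefficients of the single-compartment stall-air mass balance
#' \code{dC/dt = a - b C} (concentrations in ug/L, time in min):
#' \deqn{b = \{(Q_w/H)(1 - e^{-N}) + Q_g\} / V_s}
#' \deqn{a = Q_w C_w (1 - e^{-N}) / V_s}
#' where the source term \code{a} is volatilization from the falling water
#' and the loss term \code{b} combines re-dissolution (limited by the
#' Henry partitioning) and ventilation flushing.
#'
#' @param vs stall volume, L.
#' @param qw water flow, L/min.
#' @param qg ventilation flow, L/min.
#' @param henry dimensionless Henry's constant, \code{> 0}.
#' @param kola overall mass-transfer coefficient, L/min.
#' @param cw THM concentration in the shower water, ug/L, \code{>= 0}.
#' @return list with components \code{a} (ug L^-1 min^-1) and \code{b}
#'   (min^-1); vectorized over all arguments.
#' @examples
#' volatilization_coefficients(3500, 4, 50, 0.25, 7.4, 10)
#' @export
volatilization_coefficients <- function(vs, qw, qg, henry, kola, cw) {
  if (any(henry <= 0)) stop("henry must be > 0", call. = FALSE)
  if (any(cw < 0)) stop("cw must be >= 0", call. = FALSE)
  if (any(vs <= 0)) stop("vs must be > 0", call. = FALSE)
  if (any(qg < 0)) stop("qg must be >= 0", call. = FALSE)
  frac <- 1 - exp(-dimensionless_N(kola, qw))
  list(a = qw * cw * frac / vs,
       b = ((qw / henry) * frac + qg) / vs)
}

#' End-of-event stall air concentration
#'
#' Solution at time \code{t} of \code{dC/dt = a - b C} with \code{C(0) =
#' 0}: \code{Ct = (1 - exp(-b t)) a / b}. For \code{b = 0} (no
#' re-dissolution, no ventilation) the limiting pure-accumulation form
#' \code{a t} is returned.
#'
#' @param a source coefficient, ug L^-1 min^-1.
#' @param b loss coefficient, min^-1, \code{>= 0}.
#' @param t event duration, min, \code{>= 0}.
#' @return Air concentration at the end of the event, ug/L.
#' @examples
#' end_of_event_concentration(0.009631, 0.018138, 10)
#' @export
end_of_event_concentration <- function(a, b, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(b < 0)) stop("b must be >= 0", call. = FALSE)
  # -expm1 avoids cancellation in 1 - exp(-bt) when bt is tiny
  ifelse(b == 0, a * t, -expm1(-b * t) * a / b)
}

#' Successive-shower accumulation factor
#'
#' Under back-to-back showering with no inter-event gap, the air a bather
#' is exposed to at event \code{n} averages the carried-over concentration
#' with the end-of-event concentration: \code{Cair(n) = (Cair(n-1) + Ct) /
#' 2}, \code{Cair(0) = 0}. The closed form is the saturating geometric
#' factor \code{(2^n - 1) / 2^n}, so the second event is exactly 1.5x the
#' first, the third 1.75x, and the limit is 2x.
#'
#' @param n event index (1 = first shower against clean air), \code{>= 1};
#'   vectorized.
#' @return \code{accumulation_factor}: the factor in (0, 1];
#'   \code{successive_air_concentration}: \code{factor * ct}.
#' @examples
#' accumulation_factor(1:5)           # 1/2, 3/4, 7/8, 15/16, 31/32
#' successive_air_concentration(2, 0.1)
#' @export
accumulation_factor <- function(n) {
  if (any(n < 1)) stop("event index n must be >= 1", call. = FALSE)
  (2^n - 1) / 2^n
}

#' @rdname accumulation_factor
#' @param ct end-of-event concentration, ug/L, \code{>= 0}.
#' @export
successive_air_concentration <- function(n, ct) {
  if (any(ct < 0)) stop("ct must be >= 0", call. = FALSE)
  accumulation_factor(n) * ct
}

#' Per-event stall air concentrations for a scenario
#'
#' Runs the volatilization model for every species and every back-to-back
#' event of a scenario. Two accumulation modes:
#' \describe{
#'   \item{\code{"averaging"}}{(default) the geometric averaging rule of
#'     [successive_air_concentration()]: each event's end concentration is
#'     the clean-stall \code{Ct}, and exposure concentrations saturate at
#'     \code{2 Cair(1)}.}
#'   \item{\code{"ode"}}{comparison mode: each event re-solves the mass
#'     balance from the previous event's exposure concentration as the
#'     initial condition, \code{C(t) = a/b + (C0 - a/b) exp(-b t)}, with
#'     the exposure concentration still the (C0 + Ct)/2 event average.
#'     This is the physically literal alternative, not the rule used by
#'     the headline results.}
#' }
#'
#' @param scenario a [shower_scenario()].
#' @param species species constants (see [default_species_constants()]).
#' @param cw named vector of per-species water concentrations, ug/L
#'   (tcm, bdcm, dbcm, tbm).
#' @param mode accumulation mode, see Details.
#' @return data.frame with columns \code{event}, \code{species},
#'   \code{c0}, \code{ct}, \code{cair} (ug/L) and \code{cair_ugm3}
#'   (= cair x 1000).
#' @examples
#' sc <- shower_scenario(vs = 3500, qw = 4, qg = 50, t = 10, n_events = 3)
#' cw <- c(tcm = 4.9, bdcm = 8.6, dbcm = 11.0, tbm = 3.3)
#' event_series(sc, default_species_constants(), cw)
#' @export
event_series <- function(scenario, species = default_species_constants(),
                         cw, mode = c("averaging", "ode")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "shower_scenario"))
  if (!all(thm_species() %in% names(cw)))
    stop("cw must be named with all of: ",
         paste(thm_species(), collapse = ", "), call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(species))) {
    sp <- species$species[i]
    ab <- volatilization_coefficients(scenario$vs, scenario$qw,
                                      scenario$qg, species$henry[i],
                                      species$kola[i], cw[[sp]])
    c0 <- 0
    for (n in seq_len(scenario$n_events)) {
      if (mode == "averaging") {
        ct <- end_of_event_concentration(ab$a, ab$b, scenario$t)
        cair <- successive_air_concentration(n, ct)
      } else {
        sat <- ifelse(ab$b == 0, Inf, ab$a / ab$b)
        ct <- ifelse(ab$b == 0, c0 + ab$a * scenario$t,
                     sat + (c0 - sat) * exp(-ab$b * scenario$t))
        cair <- (c0 + ct) / 2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        event = n, species = sp, c0 = c0, ct = ct, cair = cair,
        stringsAsFactors = FALSE)
      c0 <- cair
    }
  }
  out <- do.call(rbind, rows)
  out$cair_ugm3 <- ug_per_L_to_ug_per_m3(out$cair)
  rownames(out) <- NULL
  out[order(out$event, match(out$species, thm_species())), ]
}

# the single place where stall-air ug/L becomes ug/m^3 (1 m^3 = 1000 L)
ug_per_L_to_ug_per_m3 <- function(x) x * 1000
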