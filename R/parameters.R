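#' Default exposure-factor parameter table
#'
#' The full set of uncertain exposure factors used by the Monte Carlo
#' engine, each as a triangular (min, mode, max) specification in its
#' working units. The defaults describe an adult Indian campus population
#' served by a chlorinated surface-water supply:
#'
#' \describe{
#'   \item{ir}{drinking-water ingestion rate, L/day, T(1, 2, 3).}
#'   \item{pd}{skin permeability to THM, m/min, T(2.67e-5, 3e-5, 3.5e-5).}
#'   \item{t}{shower duration, min/event, T(5, 10, 15).}
#'   \item{vs}{shower stall volume, L, T(2000, 3500, 5000).}
#'   \item{qw}{shower water flow, L/min, T(3, 4, 5).}
#'   \item{qg}{stall ventilation air flow, L/min, T(40, 50, 60).}
#'   \item{r}{breathing rate, m^3/min, T(0.012, 0.014, 0.016); carried for
#'     completeness but unused by the exposure-concentration method, which
#'     works in air concentration rather than inhaled volume.}
#'   \item{f}{showering frequency, events/day, T(0.72, 0.74, 0.76).}
#'   \item{ef_ing, ef_derm, ef_inh}{route-specific exposure frequency,
#'     days/yr: T(330, 350, 365), T(300, 330, 365), T(300, 330, 360).}
#'   \item{ed}{exposure duration, yr; female T(67, 72, 77), male
#'     T(65, 70, 75).}
#'   \item{bw}{body weight, kg; female T(50, 55, 60), male T(60, 65, 70).}
#'   \item{at}{averaging time, days; female T(24455, 26280, 28105), male
#'     T(23725, 25550, 27375). Sampled from its own spec by default; see
#'     \code{couple_at_to_ed} in [draw_parameters()].}
#'   \item{t_cold, t_hot}{cold and hot water temperature, degC,
#'     T(10, 15, 20) and T(35, 40, 45).}
#' }
#'
#' @return A named list of class \code{"thm_parameters"}; gender-specific
#'   entries (\code{ed}, \code{bw}, \code{at}) are two-element lists with
#'   \code{female} and \code{male} specs.
#' @seealso [draw_parameters()], [read_parameter_config()]
#' @export
default_parameters <- function() {
  ts <- function(v, name) triangular_spec(v, name = name)
  structure(list(
    ir      = ts(c(1, 2, 3), "ir"),
    pd      = ts(c(2.67e-5, 3.0e-5, 3.5e-5), "pd"),
    t       = ts(c(5, 10, 15), "t"),
    vs      = ts(c(2000, 3500, 5000), "vs"),
    qw      = ts(c(3, 4, 5), "qw"),
    qg      = ts(c(40, 50, 60), "qg"),
    r       = ts(c(0.012, 0.014, 0.016), "r"),
    f       = ts(c(0.72, 0.74, 0.76), "f"),
    ef_ing  = ts(c(330, 350, 365), "ef_ing"),
    ef_derm = ts(c(300, 330, 365), "ef_derm"),
    ef_inh  = ts(c(300, 330, 360), "ef_inh"),
    ed      = list(female = ts(c(67, 72, 77), "ed"),
                   male   = ts(c(65, 70, 75), "ed")),
    bw      = list(female = ts(c(50, 55, 60), "bw"),
                   male   = ts(c(60, 65, 70), "bw")),
    at      = list(female = ts(c(24455, 26280, 28105), "at"),
                   male   = ts(c(23725, 25550, 27375), "at")),
    t_cold  = ts(c(10, 15, 20), "t_cold"),
    t_hot   = ts(c(35, 40, 45), "t_hot")
  ), class = "thm_parameters")
}

parameter_names <- function() {
  c("ir", "pd", "t", "vs", "qw", "qg", "r", "f",
    "ef_ing", "ef_derm", "ef_inh", "ed", "bw", "at", "t_cold", "t_hot")
}

resolve_spec <- function(params, name, gender) {
  entry <- params[[name]]
  if (is.null(entry))
    stop("parameter table is missing '", name, "'", call. = FALSE)
  if (inherits(entry, "triangular_spec")) return(entry)
  if (is.list(entry) && !is.null(entry[[gender]])) return(entry[[gender]])
  stop("parameter '", name, "' has no spec for gender '", gender, "'",
       call. = FALSE)
}

#' Draw a table of exposure-factor values
#'
#' Samples every parameter in the table independently (no correlation
#' structure is imposed) and returns one row per Monte Carlo iteration.
#' Gender-specific specs are applied for exposure duration, body weight
#' and averaging time.
#'
#' @param params parameter table from [default_parameters()] or
#'   [read_parameter_config()].
#' @param n_iter number of iterations, \code{>= 1}.
#' @param gender \code{"female"} or \code{"male"}.
#' @param couple_at_to_ed if \code{TRUE}, the averaging time is computed
#'   per draw as \code{ed * 365} days instead of being sampled from its
#'   own spec. Default \code{FALSE}: the averaging time is listed as a
#'   separate distribution, so it is sampled as one.
#' @return data.frame with \code{n_iter} rows, one column per parameter,
#'   plus a \code{gender} column.
#' @examples
#' set.seed(42)
#' d <- draw_parameters(default_parameters(), 100, "female")
#' range(d$bw)   # within [50, 60]
#' @export
draw_parameters <- function(params, n_iter, gender = c("female", "male"),
                            couple_at_to_ed = FALSE) {
  gender <- match.arg(gender)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  cols <- lapply(parameter_names(), function(nm)
    sample_triangular(resolve_spec(params, nm, gender), n_iter))
  names(cols) <- parameter_names()
  out <- as.data.frame(cols)
  if (couple_at_to_ed) out$at <- out$ed * 365
  out$gender <- gender
  out
}

spec_to_list <- function(spec) {
  if (is_degenerate(spec)) return(spec$lower)
  c(spec$lower, spec$mode, spec$upper)
}

list_to_spec <- function(x, name) {
  if (is.list(x) && all(c("female", "male") %in% names(x)))
    return(list(female = triangular_spec(unlist(x$female), name = name),
                male   = triangular_spec(unlist(x$male), name = name)))
  triangular_spec(unlist(x), name = name)
}

#' Read / write a parameter configuration file
#'
#' The configuration is a JSON object with one entry per parameter name
#' (see [default_parameters()] for the schema): either a 3-element array
#' \code{[min, mode, max]}, a single number (point mass), or an object
#' \code{{"female": [...], "male": [...]}} for gender-specific
#' parameters. Any parameter absent from the file falls back to the
#' shipped default; an unknown name is an error.
#'
#' @param path file path.
#' @param params a parameter table (for writing).
#' @return \code{read_parameter_config}: a \code{"thm_parameters"} list.
#' @export
read_parameter_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- default_parameters()
  unknown <- setdiff(names(raw), parameter_names())
  if (length(unknown))
    stop("unknown parameter(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(raw)) params[[nm]] <- list_to_spec(raw[[nm]], nm)
  params
}

#' @rdname read_parameter_config
#' @export
write_parameter_config <- function(params, path) {
  out <- lapply(params, function(entry) {
    if (inherits(entry, "triangular_spec")) spec_to_list(entry)
    else lapply(entry, spec_to_list)
  })
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
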