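#' Full multi-pathway Monte Carlo simulation
#'
#' Runs the complete chain for both genders: synthetic (or supplied) water
#' concentrations -> heated-water adjustment -> ingestion and dermal
#' chronic daily intakes -> shower-stall volatilization -> per-event
#' inhalation exposure concentrations -> per-route cancer risks. Within an
#' iteration a single concentration draw and a single exposure-factor draw
#' feed all three routes (the routes describe the same person), and the
#' two genders are run with equal iteration counts so pooled means equal
#' the equal-weight gender average.
#'
#' @param n_iter Monte Carlo iterations per gender (default 10000).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param population \code{"private"} (single shower against clean stall
#'   air) or \code{"shared"} (back-to-back events in a communal stall).
#' @param n_events number of successive events for the shared population
#'   (default 10); forced to 1 for \code{"private"}.
#' @param params exposure-factor table, see [default_parameters()].
#' @param conc concentration model, see [default_concentration_config()].
#' @param species species constants, see [default_species_constants()].
#' @param couple_at_to_ed see [draw_parameters()].
#' @param fixed named list of parameters to pin to constants (after
#'   sampling, so the random stream stays aligned across scan settings),
#'   e.g. \code{list(t = 15)} or \code{list(qg = 300)}.
#' @param accumulation successive-shower mode, see [event_series()].
#' @param conc_table optional measured concentration table (data.frame
#'   with columns tcm/bdcm/dbcm/tbm, ug/L) used instead of the synthetic
#'   generator; rows are resampled with replacement to \code{n_iter}.
#' @return An object of class \code{"thm_run"}: per-iteration matrices
#'   (\code{cdi_ing}, \code{cr_ing}, \code{cdi_der}, \code{cr_der} of
#'   dimension iterations x species; \code{ec}, \code{cr_inh} arrays of
#'   iterations x species x events), the pooled \code{gender} vector, and
#'   the run settings. Use [risk_summary()] or \code{summary()} for
#'   distributional summaries and [tidy_draws()] for a long-format table.
#' @examples
#' run <- thm_simulate(n_iter = 200, seed = 1, population = "private")
#' summary(run)[1:4, ]
#' @export
thm_simulate <- function(n_iter = 10000, seed = NULL,
                         population = c("private", "shared"),
                         n_events = NULL,
                         params = default_parameters(),
                         conc = default_concentration_config(),
                         species = default_species_constants(),
                         couple_at_to_ed = FALSE,
                         fixed = list(),
                         accumulation = c("averaging", "ode"),
                         conc_table = NULL) {
  population <- match.arg(population)
  accumulation <- match.arg(accumulation)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  n_events <- if (population == "private") 1L
              else as.integer(if (is.null(n_events)) 10L else n_events)
  if (n_events < 1 || n_events > 50)
    stop("n_events must lie in [1, 50]", call. = FALSE)
  bad <- setdiff(names(fixed), parameter_names())
  if (length(bad))
    stop("fixed overrides for unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  genders <- c("female", "male")
  nsp <- length(thm_species())
  ntot <- 2L * n_iter
  cdi_ing <- cr_ing <- cdi_der <- cr_der <-
    matrix(NA_real_, ntot, nsp, dimnames = list(NULL, thm_species()))
  ec <- cr_inh <- array(NA_real_, c(ntot, nsp, n_events),
                        dimnames = list(NULL, thm_species(), NULL))

  for (gi in seq_along(genders)) {
    g <- genders[gi]
    idx <- (gi - 1L) * n_iter + seq_len(n_iter)
    p <- draw_parameters(params, n_iter, g, couple_at_to_ed)
    for (nm in names(fixed)) p[[nm]] <- fixed[[nm]]
    cw <- if (is.null(conc_table)) sample_concentrations(conc, n_iter)
          else conc_table[sample.int(nrow(conc_table), n_iter,
                                     replace = TRUE), , drop = FALSE]
    hf <- exp((formation_rate(p$t_hot) - formation_rate(p$t_cold)) * p$t)
    sa <- surface_area(p$bw)
    et <- exposure_time(p$t, p$f)
    for (si in seq_len(nsp)) {
      sp <- thm_species()[si]
      k <- match(sp, species$species)
      cwi <- cw[[sp]]
      chwi <- cwi * hf
      cdi_ing[idx, si] <- cdi_ingestion(cwi, p$ir, p$ef_ing, p$ed,
                                        p$bw, p$at)
      cr_ing[idx, si] <- cancer_risk_oral(cdi_ing[idx, si],
                                          species$csf_oral[k])
      cdi_der[idx, si] <- cdi_dermal(chwi, sa, p$pd, p$t, p$f,
                                     p$ef_derm, p$ed, p$bw, p$at)
      cr_der[idx, si] <- cancer_risk_oral(cdi_der[idx, si],
                                          species$csf_oral[k])
      ab <- volatilization_coefficients(p$vs, p$qw, p$qg,
                                        species$henry[k],
                                        species$kola[k], chwi)
      if (accumulation == "averaging") {
        ct <- end_of_event_concentration(ab$a, ab$b, p$t)
        for (n in seq_len(n_events)) {
          cair <- ug_per_L_to_ug_per_m3(
            successive_air_concentration(n, ct))
          ec[idx, si, n] <- exposure_concentration(cair, et, p$ef_inh,
                                                   p$ed, p$at * 24)
          cr_inh[idx, si, n] <- cancer_risk_inhalation(ec[idx, si, n],
                                                       species$iur[k])
        }
      } else {
        sat <- ifelse(ab$b == 0, Inf, ab$a / ab$b)
        c0 <- 0
        for (n in seq_len(n_events)) {
          ct <- ifelse(ab$b == 0, c0 + ab$a * p$t,
                       sat + (c0 - sat) * exp(-ab$b * p$t))
          cairL <- (c0 + ct) / 2
          cair <- ug_per_L_to_ug_per_m3(cairL)
          ec[idx, si, n] <- exposure_concentration(cair, et, p$ef_inh,
                                                   p$ed, p$at * 24)
          cr_inh[idx, si, n] <- cancer_risk_inhalation(ec[idx, si, n],
                                                       species$iur[k])
          c0 <- cairL
        }
      }
    }
  }

  structure(list(
    cdi_ing = cdi_ing, cr_ing = cr_ing,
    cdi_der = cdi_der, cr_der = cr_der,
    ec = ec, cr_inh = cr_inh,
    gender = rep(genders, each = n_iter),
    n_iter = n_iter, n_events = n_events, population = population,
    seed = seed, accumulation = accumulation
  ), class = "thm_run")
}

#' @rdname thm_simulate
#' @param ... passed to [thm_simulate()].
#' @export
run_private <- function(n_iter = 10000, seed = NULL, ...) {
  thm_simulate(n_iter = n_iter, seed = seed, population = "private", ...)
}

#' @rdname thm_simulate
#' @export
run_shared <- function(n_iter = 10000, seed = NULL, n_events = 10, ...) {
  thm_simulate(n_iter = n_iter, seed = seed, population = "shared",
               n_events = n_events, ...)
}

#' Distributional summary of a numeric draw vector
#'
#' Mean, sd, min, 10th percentile, median, 90th percentile and max.
#' Percentiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7), the convention fixed throughout the
#' package: for draws 1..100 the 10th percentile is 10.9.
#'
#' @param x numeric vector, length \code{>= 1}.
#' @return Named numeric vector.
#' @examples
#' summarize_draws(1:100)["p10"]   # 10.9
#' @export
summarize_draws <- function(x) {
  if (!length(x)) stop("no draws to summarize", call. = FALSE)
  q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
    min = min(x), p10 = q[1], median = q[2], p90 = q[3], max = max(x))
}

summary_row <- function(route, species, event, metric, x) {
  data.frame(route = route, species = species, event = event,
             metric = metric, t(summarize_draws(x)),
             stringsAsFactors = FALSE)
}

#' Summarize a simulation run
#'
#' Per-route, per-species (plus \code{species = "total"}) distributional
#' summaries of cancer risk and dose, pooled over genders. Inhalation
#' rows carry the event index; the \code{route = "total"} rows give the
#' per-event grand total (ingestion + dermal + event inhalation), with
#' ingestion and dermal identical across events by construction.
#'
#' @param run a \code{"thm_run"} object.
#' @return data.frame with columns \code{route}, \code{species},
#'   \code{event}, \code{metric} (\code{"cr"}, \code{"cdi"} or
#'   \code{"ec"}) and the statistics of [summarize_draws()].
#' @export
risk_summary <- function(run) {
  stopifnot(inherits(run, "thm_run"))
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  for (si in c(thm_species(), "total")) {
    pick <- function(m) if (si == "total") rowSums(m) else m[, si]
    add(summary_row("ingestion", si, NA_integer_, "cr", pick(run$cr_ing)))
    add(summary_row("ingestion", si, NA_integer_, "cdi", pick(run$cdi_ing)))
    add(summary_row("dermal", si, NA_integer_, "cr", pick(run$cr_der)))
    add(summary_row("dermal", si, NA_integer_, "cdi", pick(run$cdi_der)))
    for (n in seq_len(run$n_events)) {
      picka <- function(a) if (si == "total") rowSums(a[, , n])
                           else a[, si, n]
      add(summary_row("inhalation", si, n, "cr", picka(run$cr_inh)))
      add(summary_row("inhalation", si, n, "ec", picka(run$ec)))
    }
  }
  oral <- rowSums(run$cr_ing) + rowSums(run$cr_der)
  for (n in seq_len(run$n_events))
    add(summary_row("total", "total", n, "cr",
                    oral + rowSums(run$cr_inh[, , n])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.thm_run <- function(object, ...) risk_summary(object)

#' @export
print.thm_run <- function(x, ...) {
  cat(sprintf("<thm_run> %s population, %d iterations x 2 genders, %d event(s)\n",
              x$population, x$n_iter, x$n_events))
  s <- risk_summary(x)
  tot <- s[s$route == "total", c("event", "mean", "p10", "median", "p90")]
  cat("total cancer risk by event:\n")
  print(tot, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Long-format per-iteration draw table
#'
#' One row per iteration x gender x species x route (x event for
#' inhalation), with the route dose (CDI in mg kg^-1 day^-1 for oral
#' routes, EC in ug/m^3 for inhalation) and the cancer risk. Suitable for
#' writing as a tidy CSV.
#'
#' @param run a \code{"thm_run"} object.
#' @return data.frame with columns \code{iteration}, \code{gender},
#'   \code{species}, \code{route}, \code{event}, \code{dose}, \code{cr}.
#' @export
tidy_draws <- function(run) {
  stopifnot(inherits(run, "thm_run"))
  ntot <- length(run$gender)
  it <- rep(seq_len(run$n_iter), 2L)
  base <- function(route, event, dose, cr) {
    data.frame(iteration = rep(it, length(thm_species())),
               gender = rep(run$gender, length(thm_species())),
               species = rep(thm_species(), each = ntot),
               route = route, event = event,
               dose = as.vector(dose), cr = as.vector(cr),
               stringsAsFactors = FALSE)
  }
  out <- list(base("ingestion", NA_integer_, run$cdi_ing, run$cr_ing),
              base("dermal", NA_integer_, run$cdi_der, run$cr_der))
  for (n in seq_len(run$n_events))
    out[[length(out) + 1L]] <- base("inhalation", n,
                                    run$ec[, , n], run$cr_inh[, , n])
  do.call(rbind, out)
}

#' Fit an exponential or logarithmic trend
#'
#' Least squares on the linearized form: \code{ln y ~ x} for the
#' exponential model \code{y = A exp(B x)}, and \code{y ~ ln x} for the
#' logarithmic model \code{y = alpha ln(x) + beta}. The reported R^2 is
#' on the linearized scale. A constant-y input yields a zero slope and
#' R^2 = 1 (the degenerate fit is exact).
#'
#' @param x predictor values (\code{> 0} for the logarithmic form).
#' @param y response values (\code{> 0} for the exponential form); at
#'   least 3 points.
#' @param form \code{"exponential"} or \code{"logarithmic"}.
#' @return list of class \code{"thm_trend"}: \code{form}, \code{coef}
#'   (named \code{A}, \code{B} or \code{alpha}, \code{beta}),
#'   \code{r_squared}.
#' @examples
#' fit_trend(1:10, 0.0438 * log(1:10) + 0.1239, "logarithmic")
#' @export
fit_trend <- function(x, y, form = c("exponential", "logarithmic")) {
  form <- match.arg(form)
  if (length(x) < 3 || length(y) != length(x))
    stop("need at least 3 (x, y) points", call. = FALSE)
  if (form == "exponential") {
    if (any(y <= 0))
      stop("exponential form requires y > 0", call. = FALSE)
    fit <- stats::lm(log(y) ~ x)
    cf <- c(A = unname(exp(stats::coef(fit)[1])),
            B = unname(stats::coef(fit)[2]))
    resp <- log(y)
  } else {
    if (any(x <= 0))
      stop("logarithmic form requires x > 0", call. = FALSE)
    fit <- stats::lm(y ~ log(x))
    cf <- c(alpha = unname(stats::coef(fit)[2]),
            beta = unname(stats::coef(fit)[1]))
    resp <- y
  }
  sst <- sum((resp - mean(resp))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst <= .Machine$double.eps * max(1, sum(resp^2))) 1
        else 1 - ssr / sst
  structure(list(form = form, coef = cf, r_squared = r2),
            class = "thm_trend")
}

#' @export
print.thm_trend <- function(x, ...) {
  eq <- if (x$form == "exponential")
    sprintf("y = %.4g * exp(%.4g x)", x$coef["A"], x$coef["B"])
  else
    sprintf("y = %.4g ln(x) + %.4g", x$coef["alpha"], x$coef["beta"])
  cat(sprintf("<thm_trend %s> %s   (R^2 = %.4f)\n", x$form, eq,
              x$r_squared))
  invisible(x)
}

scan_core <- function(settings, fixed_name, events, n_iter, seed,
                      trend_x, ...) {
  n_events <- max(events)
  rows <- list()
  for (v in settings) {
    run <- thm_simulate(n_iter = n_iter, seed = seed,
                        population = "shared", n_events = n_events,
                        fixed = stats::setNames(list(v), fixed_name), ...)
    inh <- apply(run$cr_inh, 3, function(m) mean(rowSums(m)))
    der <- mean(rowSums(run$cr_der))
    for (n in events)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = v, event = n, cr_inhalation = inh[n],
        cr_dermal = der, stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  fits <- lapply(events, function(n) {
    g <- grid[grid$event == n, ]
    fit_trend(trend_x, g$cr_inhalation, "exponential")
  })
  names(fits) <- paste0("S", events)
  structure(list(grid = grid, fits = fits), class = "thm_scan")
}

#' Shower-duration sensitivity scan
#'
#' Reruns the shared-population simulation with the shower duration
#' pinned to each grid value (duration enters the stall-air solution, the
#' daily exposure time, the dermal dose, and the heated-water exponent)
#' and fits an exponential trend of mean inhalation cancer risk against
#' duration, per event index. The same seed is reused at every grid
#' point, so the underlying draws are identical across settings and
#' monotonicity holds per iteration.
#'
#' @param durations shower durations to scan, min (\code{> 0}).
#' @param events event indices to report/fit (default S1, S3, S5).
#' @param n_iter iterations per gender per grid point.
#' @param seed integer seed reused at each grid point.
#' @param ... further arguments to [thm_simulate()].
#' @return list of class \code{"thm_scan"}: \code{grid} (columns
#'   \code{setting} = duration, \code{event}, \code{cr_inhalation},
#'   \code{cr_dermal}) and \code{fits}, one \code{"thm_trend"} per event.
#' @export
scan_duration <- function(durations = seq(5, 25, by = 5),
                          events = c(1, 3, 5), n_iter = 10000,
                          seed = NULL, ...) {
  if (!length(durations) || any(durations <= 0))
    stop("durations must be positive and non-empty", call. = FALSE)
  scan_core(durations, "t", events, n_iter, seed, trend_x = durations,
            ...)
}

#' Ventilation sensitivity scan
#'
#' As [scan_duration()], but pins the stall ventilation rate. Grid values
#' are given in L/s (the natural reporting unit for mechanical
#' ventilation) and converted x60 to the model's L/min before entering
#' the loss coefficient. Fits an exponential decay of mean inhalation
#' cancer risk against ventilation (L/s), per event.
#'
#' @param qg_ls ventilation rates to scan, L/s (\code{>= 0}); a zero is
#'   shifted to the fit's predictor as-is (the exponential fit tolerates
#'   x = 0).
#' @inheritParams scan_duration
#' @return As [scan_duration()]; \code{grid$setting} is in L/s.
#' @export
scan_ventilation <- function(qg_ls = c(0, 5, 10, 15, 20),
                             events = c(1, 3, 5), n_iter = 10000,
                             seed = NULL, ...) {
  if (!length(qg_ls) || any(qg_ls < 0))
    stop("qg_ls must be non-negative and non-empty", call. = FALSE)
  out <- scan_core(qg_ls * 60, "qg", events, n_iter, seed,
                   trend_x = qg_ls, ...)
  out$grid$setting <- out$grid$setting / 60
  out
}

#' @export
print.thm_scan <- function(x, ...) {
  cat("<thm_scan> grid:\n")
  print(x$grid, row.names = FALSE, digits = 4)
  for (nm in names(x$fits)) {
    cat(nm, ": ")
    print(x$fits[[nm]])
  }
  invisible(x)
}
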