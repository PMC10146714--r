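test_that("dimensionless mass-transfer coefficient", {
  expect_equal(dimensionless_N(7.4, 4), 1.85)
  expect_equal(dimensionless_N(0, 5), 0)
  expect_equal(dimensionless_N(3.7, 3.7), 1)
  expect_error(dimensionless_N(7.4, 0), "qw")
})

test_that("volatilization coefficients match hand evaluation", {
  ab <- volatilization_coefficients(vs = 3500, qw = 4, qg = 50,
                                    henry = 0.25, kola = 7.4, cw = 10)
  expect_equal(ab$b, ((4 / 0.25) * (1 - exp(-1.85)) + 50) / 3500,
               tolerance = 1e-12)
  expect_equal(ab$b, 0.018138, tolerance = 1e-4)
  expect_equal(ab$a, 4 * 10 * (1 - exp(-1.85)) / 3500, tolerance = 1e-12)
  expect_equal(ab$a, 0.009631, tolerance = 1e-4)
  # no source without THM in the water
  expect_equal(volatilization_coefficients(3500, 4, 50, 0.25, 7.4, 0)$a, 0)
  expect_error(volatilization_coefficients(3500, 4, 50, 0, 7.4, 10),
               "henry")
})

test_that("end-of-event concentration solves the mass balance", {
  expect_equal(end_of_event_concentration(0.009631, 0.018138, 10),
               0.08808, tolerance = 1e-4)
  expect_equal(end_of_event_concentration(0.01, 0.02, 0), 0)
  # b = 0 limit: pure accumulation a*t
  expect_equal(end_of_event_concentration(0.01, 0, 7), 0.07)
  # steady state
  expect_equal(end_of_event_concentration(0.01, 0.02, 1e6), 0.5)
})

test_that("closed form agrees with an RK4 ODE oracle to 1e-6", {
  for (a in c(1e-3, 0.01, 0.05)) {
    for (b in c(5e-3, 0.02, 0.1)) {
      for (t in c(2, 10, 25)) {
        expect_equal(end_of_event_concentration(a, b, t),
                     rk4_linear_ode(a, b, t),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("accumulation factors follow the saturating geometric rule", {
  expect_equal(accumulation_factor(1:5),
               c(1 / 2, 3 / 4, 7 / 8, 15 / 16, 31 / 32))
  ct <- 0.08808
  expect_equal(successive_air_concentration(1, ct), ct / 2)
  expect_equal(successive_air_concentration(2, ct), 3 * ct / 4)
  expect_equal(successive_air_concentration(2, ct) /
               successive_air_concentration(1, ct), 1.5)
  expect_equal(successive_air_concentration(60, ct), ct, tolerance = 1e-12)
  expect_error(successive_air_concentration(0, ct), "n must be")
  # closed form equals the averaging recursion from a clean stall
  cair <- 0
  for (n in 1:10) {
    cair <- (cair + ct) / 2
    expect_equal(successive_air_concentration(n, ct), cair)
  }
  # bounded below twice the first event
  f <- accumulation_factor(1:50) / accumulation_factor(1)
  expect_true(all(diff(f) > 0 | f[-1] == 2))
  expect_true(all(f < 2))
  expect_equal(f[c(2, 3, 5)], c(1.5, 1.75, 1.9375))
})

test_that("event series chains carried-over air correctly", {
  sc <- shower_scenario(vs = 3500, qw = 4, qg = 50, t = 10, n_events = 4)
  cw <- c(tcm = 4.9, bdcm = 8.6, dbcm = 11.0, tbm = 3.3)
  es <- event_series(sc, default_species_constants(), cw)
  for (sp in thm_species()) {
    e <- es[es$species == sp, ]
    expect_equal(e$c0[1], 0)
    expect_equal(e$c0[-1], e$cair[-nrow(e)])
    expect_true(all(diff(e$cair) > 0))
    expect_true(all(e$cair <= e$ct))
    expect_true(all(e$c0 <= e$cair))
    expect_equal(e$cair, accumulation_factor(1:4) * e$ct[1])
  }
  # single event: exposure is half the end concentration
  es1 <- event_series(shower_scenario(3500, 4, 50, 10, 1),
                      default_species_constants(), cw)
  expect_equal(es1$cair, es1$ct / 2)
  # ODE re-initialization mode agrees at event 1, then diverges
  eso <- event_series(sc, default_species_constants(), cw, mode = "ode")
  expect_equal(eso$cair[eso$event == 1], es$cair[es$event == 1])
  expect_false(isTRUE(all.equal(eso$cair[eso$event == 3],
                                es$cair[es$event == 3])))
})

test_that("monotonicities of the stall-air model", {
  base <- function(qg = 50, t = 10, cw = 10) {
    ab <- volatilization_coefficients(3500, 4, qg, 0.124, 5.9, cw)
    list(b = ab$b, ct = end_of_event_concentration(ab$a, ab$b, t))
  }
  qgs <- c(0, 25, 50, 100, 300)
  bs <- vapply(qgs, function(q) base(qg = q)$b, numeric(1))
  cts <- vapply(qgs, function(q) base(qg = q)$ct, numeric(1))
  expect_true(all(diff(bs) > 0))    # ventilation adds loss
  expect_true(all(diff(cts) < 0))   # and flushes the stall
  ts <- c(2, 5, 10, 20)
  expect_true(all(diff(vapply(ts, function(t) base(t = t)$ct,
                              numeric(1))) > 0))
  cws <- c(1, 5, 10, 20)
  expect_true(all(diff(vapply(cws, function(cw) base(cw = cw)$ct,
                              numeric(1))) > 0))
  # no ventilation and no re-dissolution: pure accumulation a*t
  ab <- volatilization_coefficients(3500, 4, 0, 1e12, 5.9, 10)
  expect_lt(ab$b, 1e-14)
  expect_equal(end_of_event_concentration(ab$a, ab$b, 10), ab$a * 10,
               tolerance = 1e-6)
})

test_that("scenario validation", {
  expect_error(shower_scenario(0, 4, 50, 10), "vs")
  expect_error(shower_scenario(3500, 4, -1, 10), "qg")
  expect_error(shower_scenario(3500, 4, 50, 10, 0), "n_events")
})
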