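test_that("body surface area follows the rational form", {
  expect_equal(surface_area(65), 267 / 155)
  expect_equal(surface_area(55), 227 / 145)
  bw <- seq(40, 120, by = 5)
  expect_true(all(diff(surface_area(bw)) > 0))
  expect_lt(surface_area(1e9), 4)
  expect_error(surface_area(0), "bw")
})

test_that("formation rate and heated-water adjustment", {
  expect_equal(formation_rate(0), 0.0011)
  expect_equal(formation_rate(40), 0.0011 * exp(0.0407 * 40))
  expect_equal(formation_rate(40) / formation_rate(15),
               exp(0.0407 * 25))
  expect_error(formation_rate(150), "temp")
  expect_equal(heated_concentration(10, 0, 40, 15), 10)
  expect_equal(heated_concentration(10, 10, 40, 40), 10)
  expect_equal(heated_concentration(10, 10, 40, 15), 10.3642,
               tolerance = 1e-4)
  # hotter water never lowers the concentration
  expect_true(all(heated_concentration(10, c(1, 5, 20), 45, 10) >= 10))
})

test_that("ingestion intake matches hand evaluation and is linear", {
  expect_equal(cdi_ingestion(30.22, 2, 350, 72, 55, 26280),
               30.22 * 2 * 350 * 72 * 0.001 / (55 * 26280))
  expect_equal(cdi_ingestion(30.22, 2, 350, 72, 55, 26280), 1.0537e-3,
               tolerance = 1e-4)
  expect_equal(cdi_ingestion(0, 2, 350, 72, 55, 26280), 0)
  expect_equal(cdi_ingestion(20, 2, 350, 72, 55, 26280),
               2 * cdi_ingestion(10, 2, 350, 72, 55, 26280))
  expect_error(cdi_ingestion(10, 2, 350, 72, 0, 26280), "bw")
})

test_that("dermal intake matches hand evaluation", {
  expect_equal(cdi_dermal(30.22, 1.644, 3.057e-5, 10, 0.74, 331.67, 72,
                          60, 25550),
               1.750e-4, tolerance = 1e-3)
  expect_equal(cdi_dermal(30.22, 1.644, 0, 10, 0.74, 331.67, 72, 60,
                          25550), 0)
  one <- cdi_dermal(30.22, 1.644, 3.057e-5, 1, 0.74, 331.67, 72, 60,
                    25550)
  expect_equal(cdi_dermal(30.22, 1.644, 3.057e-5, 7, 0.74, 331.67, 72,
                          60, 25550), 7 * one)
})

test_that("exposure time and exposure concentration", {
  expect_equal(exposure_time(10, 0.74), 10 * 0.74 / 60)
  expect_equal(exposure_time(10, 0), 0)
  expect_equal(exposure_time(60, 1), 1)
  expect_equal(exposure_concentration(100, 0.1233, 330, 72, 630720),
               0.46449, tolerance = 1e-4)
  expect_equal(exposure_concentration(100, 0, 330, 72, 630720), 0)
  # continuous-exposure identity: all duty factors unity
  ed <- 70
  expect_equal(exposure_concentration(42, 24, 365, ed, ed * 365 * 24), 42)
  expect_error(exposure_concentration(1, 1, 1, 1, 0), "at_hours")
})

test_that("risk conversions are simple products", {
  expect_equal(cancer_risk_oral(3.55e-4, 0.084), 2.982e-5,
               tolerance = 1e-3)
  expect_equal(cancer_risk_oral(0, 1), 0)
  expect_equal(cancer_risk_oral(1.23e-4, 1), 1.23e-4)
  expect_equal(cancer_risk_inhalation(0.1, 2.3e-5), 2.3e-6)
  expect_equal(cancer_risk_inhalation(0.1, 0), 0)
  expect_equal(cancer_risk_inhalation(0.2, 2.3e-5),
               2 * cancer_risk_inhalation(0.1, 2.3e-5))
})

test_that("total risk sums a complete grid and rejects holes", {
  m <- matrix(1e-6 * c(48.73, 8.69, 1.11), 1, 3,
              dimnames = list("all", c("ing", "der", "inh")))
  tot <- total_risk(m)
  expect_equal(tot$grand, 58.53e-6)
  m2 <- matrix(runif(12), 4, 3,
               dimnames = list(thm_species(), c("ing", "der", "inh")))
  tot2 <- total_risk(m2)
  expect_equal(sum(tot2$by_route), tot2$grand)
  expect_equal(sum(tot2$by_species), tot2$grand)
  expect_equal(total_risk(m2[sample(4), sample(3)])$grand, tot2$grand)
  m2[2, 3] <- NA
  expect_error(total_risk(m2), "missing")
})

test_that("every equation matches an inline spreadsheet oracle", {
  set.seed(31)
  for (i in 1:20) {
    cw <- runif(1, 1, 50); ir <- runif(1, 1, 3); ef <- runif(1, 300, 365)
    ed <- runif(1, 65, 77); bw <- runif(1, 50, 70)
    at <- runif(1, 23000, 28000); sa <- runif(1, 1.4, 1.9)
    pd <- runif(1, 2.6e-5, 3.6e-5); t <- runif(1, 5, 25)
    f <- runif(1, 0.7, 0.8); th <- runif(1, 35, 45); tc <- runif(1, 10, 20)
    vs <- runif(1, 2000, 5000); qw <- runif(1, 3, 5); qg <- runif(1, 0, 80)
    H <- runif(1, 0.05, 0.3); kola <- runif(1, 3, 8)
    expect_equal(cdi_ingestion(cw, ir, ef, ed, bw, at),
                 cw * ir * ef * ed * 0.001 / (bw * at),
                 tolerance = 1e-10)
    expect_equal(cdi_dermal(cw, sa, pd, t, f, ef, ed, bw, at),
                 cw * sa * pd * t * f * ef * ed / (bw * at),
                 tolerance = 1e-10)
    expect_equal(heated_concentration(cw, t, th, tc),
                 cw * exp((0.0011 * exp(0.0407 * th) -
                           0.0011 * exp(0.0407 * tc)) * t),
                 tolerance = 1e-10)
    expect_equal(surface_area(bw), (4 * bw + 7) / (bw + 90),
                 tolerance = 1e-10)
    ab <- volatilization_coefficients(vs, qw, qg, H, kola, cw)
    expect_equal(ab$b,
                 ((qw / H) * (1 - exp(-kola / qw)) + qg) / vs,
                 tolerance = 1e-10)
    expect_equal(ab$a, qw * cw * (1 - exp(-kola / qw)) / vs,
                 tolerance = 1e-10)
    expect_equal(end_of_event_concentration(ab$a, ab$b, t),
                 (1 - exp(-ab$b * t)) * ab$a / ab$b,
                 tolerance = 1e-10)
    et <- exposure_time(t, f)
    expect_equal(exposure_concentration(cw, et, ef, ed, at * 24),
                 cw * et * ef * ed / (at * 24), tolerance = 1e-10)
  }
})
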