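test_that("dissolved pool enrichment is the spike/ambient mixing ratio", {
  ## ammonium spike into ambient 0.20 uM: 7.177 atom%
  expect_equal(dissolved_atom_pct(0.20, 0.015, 98), 7.177, tolerance = 1e-4)
  ## no ambient pool: pure spike
  expect_equal(dissolved_atom_pct(0, 0.03, 98), 98)
  ## unenriched spike changes nothing
  expect_equal(dissolved_atom_pct(0.5, 0.03, 0.366), 0.366)
  expect_error(dissolved_atom_pct(-1, 0.03, 98), class = "nsip_input_error")
  expect_error(dissolved_atom_pct(0.2, 0, 98), class = "nsip_input_error")
})

test_that("tracer uptake rates follow the atom-percent-excess formula", {
  expect_equal(uptake_rate(0.366, 0.366, 10, 1, 1), 0)
  expect_equal(uptake_rate(0.50, 0.366, 10, 1, 1), 0.134 / 9.634,
               tolerance = 1e-9)
  ## linear in particulate N
  expect_equal(uptake_rate(0.50, 0.366, 10, 2, 1),
               2 * uptake_rate(0.50, 0.366, 10, 1, 1))
  ## apparent negative uptake floors at zero with a warning
  expect_warning(r0 <- uptake_rate(0.30, 0.366, 10, 1, 1), "floored")
  expect_equal(r0, 0)
  expect_error(uptake_rate(0.5, 0.366, 10, 1, 0), class = "nsip_input_error")
  expect_error(uptake_rate(0.5, 0.366, 0.2, 1, 1),
               class = "nsip_input_error")
})

test_that("IRMS size and drift corrections calibrate and apply linearly", {
  expect_warning(same <- irms_correct(c(1, 2), 5, 1, NULL), "calibration")
  expect_equal(same, c(1, 2))
  expect_equal(irms_correct(2, 10, 3, list(a = 0.001, b = 0)), 2 - 0.01)
  expect_equal(irms_correct(2, 0, 0, list(a = 0.3, b = 0.3)), 2)

  ## standards with a known size slope and drift recover it by least squares
  set.seed(23)
  a <- 0.0014; b <- -0.0006
  std <- data.frame(true = 0.366,
                    size_signal = runif(12, 5, 40),
                    drift_index = 1:12)
  std$measured <- std$true + a * std$size_signal + b * std$drift_index
  cal <- irms_calibrate(std)
  expect_equal(cal$a, a, tolerance = 1e-6)
  expect_equal(cal$b, b, tolerance = 1e-6)
  expect_equal(irms_correct(std$measured, std$size_signal, std$drift_index,
                            cal),
               rep(0.366, 12), tolerance = 1e-9)
})

test_that("depth integration is trapezoidal with a surface extension", {
  ## constant rate over 0-35 m
  expect_equal(depth_integrate(c(5, 17, 35), rep(0.2, 3)), 0.2 * 35)
  ## single depth: rectangle to the bottom bound
  expect_equal(depth_integrate(10, 0.3, z_bottom = 35), 0.3 * 35)
  ## hand trapezoid: 0.1*5 + 0.15*12 + 0.3*18
  expect_equal(depth_integrate(c(5, 17, 35), c(0.1, 0.2, 0.4)), 7.7)
  expect_error(depth_integrate(c(17, 5), c(0.1, 0.2)),
               class = "nsip_input_error")

  ## exact on affine profiles, and equal to the brute-force trapezoid
  set.seed(37)
  for (i in 1:25) {
    z <- sort(runif(sample(2:6, 1), 1, 40))
    a <- runif(1, 0, 0.05); b <- runif(1, 0.01, 0.5)
    r <- a * z + b
    got <- depth_integrate(z, r, z_top = 0, z_bottom = max(z))
    zz <- c(0, z); rr <- c(r[1], r)
    expect_equal(got, bf_trapz(zz, rr), tolerance = 1e-12)
    ## analytic integral of the affine part beyond the surface extension
    exact <- r[1] * z[1] + a / 2 * (max(z)^2 - z[1]^2) + b * (max(z) - z[1])
    expect_equal(got, exact, tolerance = 1e-12)
  }
})

test_that("f-ratio and Redfield conversions reproduce the budget arithmetic", {
  ## printed-table check: NO3 3.1 + N2 0.19 over a total of 8.8
  expect_equal(round(f_ratio(no3 = 3.1, n2 = 0.19, total = 8.8), 2), 0.37)
  expect_equal(f_ratio(no3 = 0, n2 = 0, nh4 = 2, urea = 0), 0)
  expect_equal(f_ratio(no3 = 5), 1)
  expect_error(f_ratio(no3 = 0, n2 = 0), class = "nsip_input_error")

  expect_equal(round(redfield_c(0.19), 1), 1.3)
  expect_equal(redfield_c(16), 106)
  expect_equal(redfield_c(0), 0)
})

test_that("budgets integrate profiles, close to 1 and carry the f-ratio", {
  ## equal integrated rates: each fraction 1/4
  eq <- n_budget(list(NH4 = 1, NO3 = 1, urea = 1, N2 = 1))
  expect_equal(eq$table$fraction_of_total, rep(0.25, 4))
  expect_equal(eq$f_ratio, 0.5)

  ## N2-only budget
  expect_warning(n2 <- n_budget(list(N2 = 0.2)), "treated as 0")
  expect_equal(n2$f_ratio, 1)
  expect_equal(n2$table$fraction_of_total[n2$table$substrate == "N2"], 1)

  ## constant profiles built to integrate to the published per-substrate
  ## euphotic-zone rates reproduce the budget within printed rounding
  rates <- c(urea = 3.4, NO3 = 3.1, NH4 = 2.4, N2 = 0.19)
  profs <- lapply(rates, function(r)
    data.frame(depth = c(5, 17, 35), rate = r / 35))
  bud <- n_budget(profs, z_top = 0)
  expect_equal(bud$table$integrated_rate[match(names(rates),
                                               bud$table$substrate)],
               unname(rates), tolerance = 1e-9)
  expect_equal(sum(bud$table$fraction_of_total), 1, tolerance = 1e-9)
  expect_equal(bud$f_ratio, (3.1 + 0.19) / sum(rates), tolerance = 1e-9)
  expect_equal(round(bud$total_n), 9)
  expect_equal(round(bud$total_c), 60)
  expect_equal(round(redfield_c(0.19), 1), 1.3)
  fr <- bud$table$fraction_of_total
  names(fr) <- bud$table$substrate
  printed <- c(urea = 0.38, NO3 = 0.34, NH4 = 0.26, N2 = 0.02)
  expect_true(all(abs(fr[names(printed)] - printed) <= 0.01))

  expect_error(n_budget(list(NH4 = 0, NO3 = 0, urea = 0, N2 = 0)),
               class = "nsip_input_error")
  expect_output(print(eq), "f-ratio")
})

test_that("simulated tracer observations round-trip through the rate module", {
  ## exact inversion with no instrument noise
  truth <- c(0.02, 0.05, 0.11)
  obs <- simulate_uptake_obs(truth, pn_conc = 1, dissolved_atom_pct = 7.177)
  obs$rate <- uptake_rate(obs$atom_pct_tf, obs$atom_pct_t0,
                          obs$dissolved_atom_pct, obs$pn_conc, obs$duration)
  expect_equal(obs$rate, truth, tolerance = 1e-9)

  ## with 0.005 atom% IRMS noise at >= 5 atom% dissolved enrichment the
  ## recovered rates stay within 10% relative RMSE
  set.seed(97)
  true_rate <- runif(500, 0.02, 0.1)
  noisy <- simulate_uptake_obs(true_rate, pn_conc = 1,
                               dissolved_atom_pct = 7.177, irms_sd = 0.005)
  est <- uptake_rate(noisy$atom_pct_tf, noisy$atom_pct_t0,
                     noisy$dissolved_atom_pct, noisy$pn_conc, noisy$duration)
  rel_rmse <- sqrt(mean(((est - true_rate) / true_rate)^2))
  expect_lt(rel_rmse, 0.10)
})
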