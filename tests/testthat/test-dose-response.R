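# Plate normalization and 4PL dose-response fitting.

make_plate <- function(conc, kill, v_solv = 1, v_kill = 0) {
  # viability anchored between solvent and kill controls
  v <- v_kill + (1 - kill / 100) * (v_solv - v_kill)
  rbind(
    data.frame(well_id = "s1", concentration = 0, viability = v_solv,
               control_flag = "solvent"),
    data.frame(well_id = "k1", concentration = 0, viability = v_kill,
               control_flag = "kill"),
    data.frame(well_id = paste0("w", seq_along(conc)), concentration = conc,
               viability = v, control_flag = "treated"))
}

test_that("normalization anchors at the plate controls", {
  d <- make_plate(c(1e-9, 1e-8, 1e-7), c(0, 50, 100), v_solv = 0.9, v_kill = 0.1)
  out <- normalize_plate(d)
  expect_equal(out$kill_pct, c(0, 50, 100))
  # clipping to [0, 100]
  d2 <- make_plate(c(1e-9, 1e-8), c(-10, 110), v_solv = 0.9, v_kill = 0.1)
  expect_equal(normalize_plate(d2)$kill_pct, c(0, 100))
})

test_that("normalization rejects unusable controls", {
  d <- make_plate(1e-8, 50)
  expect_error(normalize_plate(d[d$control_flag != "kill", ]), "control")
  bad <- d
  bad$viability[bad$control_flag == "solvent"] <- 0.1
  bad$viability[bad$control_flag == "kill"] <- 0.9
  expect_error(normalize_plate(bad), "unusable")
})

test_that("clipping never reorders mean kill across concentrations on clean data", {
  conc <- 10^seq(-9, -6, length.out = 8)
  kill <- 100 / (1 + (5e-8 / conc)^1.2)
  out <- normalize_plate(make_plate(conc, kill))
  expect_identical(order(tapply(out$kill_pct, out$concentration, mean)),
                   seq_along(conc))
})

test_that("precursor stoichiometry divides administered concentration", {
  ala <- default_photosensitizers()$ala_ppix
  ru <- default_photosensitizers()$rutherrin
  expect_equal(effective_ps_concentration(6000e-6, ala), 750e-6)
  expect_equal(effective_ps_concentration(500e-9, ru), 500e-9)
  expect_identical(effective_ps_concentration(0, ala), 0)
})

test_that("noise-free 4PL data is recovered essentially exactly", {
  conc <- 10^seq(-9, -6.5, length.out = 10)
  kill <- function(lc) 100 / (1 + 10^(1.5 * (log10(50e-9) - lc)))
  d <- data.frame(concentration = conc, kill_pct = kill(log10(conc)))
  fit <- fit_dose_response(d)
  expect_equal(fit$ld50_concentration, 50e-9, tolerance = 1e-6)
  expect_equal(fit$hill_slope, 1.5, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_true(all(abs(residuals(fit)) < 1e-6))
})

test_that("monotone-decreasing viability implies positive fitted slope", {
  sc <- scenario_config(seed = 5)
  fit <- fit_dose_response(gen_plate(sc, "rutherrin"))
  expect_gt(fit$hill_slope, 0)
})

test_that("fit preconditions are enforced", {
  d <- data.frame(concentration = c(1e-9, 1e-8, 1e-7),
                  kill_pct = c(10, 50, 90))
  expect_error(fit_dose_response(d), "4 distinct")
  flat <- data.frame(concentration = 10^seq(-9, -6, length.out = 6),
                     kill_pct = rep(50, 6))
  expect_error(fit_dose_response(flat), "flat|degenerate")
})

test_that("LD50 in photons is invariant to re-expressing the light schedule", {
  ru <- default_photosensitizers()$rutherrin
  fit <- structure(list(ld50_concentration = 2.3e-8), class = "pdt_drfit")
  a <- light_source("a", 530, duration = 20 / 0.360, geometry = "flat_field",
                    irradiance = 0.360)
  b <- light_source("b", 530, duration = 2 * 20 / 0.360, geometry = "flat_field",
                    irradiance = 0.180) # half irradiance, double time
  expect_equal(ld50_in_photons(fit, a, ru), ld50_in_photons(fit, b, ru),
               tolerance = 1e-12)
})

test_that("published-LD50 inversion and forward conversion are mutual inverses", {
  ps <- default_photosensitizers()
  src <- default_light_sources()
  for (use_ln10 in c(TRUE, FALSE)) {
    c_ru <- implied_ld50_concentration(2.388e16, src$well_530, ps$rutherrin,
                                       use_ln10)
    expect_equal(ld50_in_photons(c_ru, src$well_530, ps$rutherrin, use_ln10),
                 2.388e16, tolerance = 1e-12)
    c_ala <- implied_ld50_concentration(1.539e19, src$well_635, ps$ala_ppix,
                                        use_ln10)
    expect_equal(ld50_in_photons(c_ala, src$well_635, ps$ala_ppix, use_ln10),
                 1.539e19, tolerance = 1e-12)
  }
})

test_that("delta-method CI for the LD50 has near-nominal coverage", {
  sc <- scenario_config(seed = 31)
  truth <- sc$plate$rutherrin$true_ld50
  hits <- vapply(seq_len(150), function(i) {
    fit <- fit_dose_response(gen_plate(sc, "rutherrin", seed = 5000 + i))
    ci <- confint(fit)
    ci["lower"] <= truth && truth <= ci["upper"]
  }, TRUE)
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("simulate() produces plates refittable near the original estimate", {
  sc <- scenario_config(seed = 9)
  fit <- fit_dose_response(gen_plate(sc, "rutherrin"))
  sims <- simulate(fit, nsim = 3, seed = 99)
  refits <- vapply(sims, function(s)
    fit_dose_response(s)$ld50_concentration, 0)
  expect_true(all(abs(refits / fit$ld50_concentration - 1) < 0.5))
})

test_that("plate CSV reader round-trips generated plates", {
  sc <- scenario_config(seed = 3)
  p <- gen_plate(sc, "ala")
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(well_id = p$well_id, agent = p$agent,
                       concentration_M = p$concentration,
                       viability = p$viability, control_flag = p$control_flag),
            tmp, row.names = FALSE)
  r <- read_plate_csv(tmp, agent = "ala")
  expect_equal(r$concentration, p$concentration, tolerance = 1e-12)
  expect_equal(r$viability, p$viability, tolerance = 1e-12)
  expect_error(read_plate_csv(textConnection("a,b\n1,2")), "columns")
})
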