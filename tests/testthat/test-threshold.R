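# Photodynamic threshold estimation, inversion, selectivity and edema helper.

th_setup <- function() {
  list(src = default_light_sources()$interstitial_808,
       opt = default_tissue_optics()$gray_808,
       ps = default_photosensitizers()$rutherrin,
       conc = 3.9e-8)
}

test_that("forward/inverse threshold round trip closes to 1e-9 relative", {
  s <- th_setup()
  for (T0 in c(1e18, 8.86e18, 5e19)) {
    r <- predict_necrosis_radius(T0, s$src, s$opt, s$ps, s$conc)
    expect_gt(r, 0)
    obs <- data.frame(animal_id = "a1", r_min_cm = r, r_max_cm = r)
    est <- threshold_at_boundary(obs, s$src, s$opt, s$ps, s$conc)
    expect_equal(est$threshold, T0, tolerance = 1e-9)
  }
})

test_that("threshold is strictly decreasing in boundary radius", {
  s <- th_setup()
  rr <- seq(0.2, 1.0, by = 0.1)
  th <- absorbed_photon_profile(rr, s$src, s$opt, s$ps, s$conc)
  expect_true(all(diff(th) < 0))
})

test_that("predicted radius grows with exposure time and vanishes for huge thresholds", {
  s <- th_setup()
  src2 <- light_source("x", 808, duration = 2 * s$src$duration,
                       geometry = "isotropic_point", power = s$src$power)
  r1 <- predict_necrosis_radius(8.86e18, s$src, s$opt, s$ps, s$conc)
  r2 <- predict_necrosis_radius(8.86e18, src2, s$opt, s$ps, s$conc)
  expect_gt(r2, r1)
  # threshold above anything achievable: a no-necrosis result, not an error
  expect_identical(predict_necrosis_radius(1e40, s$src, s$opt, s$ps, s$conc), 0)
})

test_that("synthetic cohort mean lands within one sample sd of the generating threshold", {
  sc <- scenario_config(seed = 12)
  obs <- gen_boundaries(sc)
  tc <- sc$threshold
  est <- threshold_at_boundary(obs, tc$source, tc$optics, tc$ps,
                               tc$tissue_concentration_M)
  expect_lt(abs(est$threshold - tc$true_threshold), est$sd)
})

test_that("first-order sd is comparable to a bootstrap sd on a 6-animal cohort", {
  sc <- scenario_config(seed = 8)
  tc <- sc$threshold
  obs <- gen_boundaries(sc)
  est <- threshold_at_boundary(obs, tc$source, tc$optics, tc$ps,
                               tc$tissue_concentration_M)
  set.seed(42)
  boot <- vapply(1:400, function(i) {
    idx <- sample(nrow(obs), replace = TRUE)
    threshold_at_boundary(obs[idx, ], tc$source, tc$optics, tc$ps,
                          tc$tissue_concentration_M)$threshold
  }, 0)
  sd_mean <- est$sd / sqrt(nrow(obs)) # sd of the cohort mean
  expect_lt(abs(sd(boot) / sd_mean - 1), 0.20)
})

test_that("normal brain (lower uptake) yields a lower threshold at the same boundary", {
  s <- th_setup()
  obs <- data.frame(animal_id = c("a1", "a2"), r_min_cm = c(0.4, 0.45),
                    r_max_cm = c(0.5, 0.55))
  sur <- 20
  tumor <- threshold_at_boundary(obs, s$src, s$opt, s$ps, s$conc)
  brain <- threshold_at_boundary(obs, s$src, s$opt, s$ps, s$conc / sur)
  expect_lt(brain$threshold, tumor$threshold)
  expect_equal(tumor$threshold / brain$threshold, sur, tolerance = 1e-12)
})

test_that("MC transport route interpolates the simulated field", {
  sh <- shared_mc_field()
  s <- th_setup()
  a_mc <- absorbed_photon_profile(0.5, sh$field$source, sh$optics, s$ps,
                                  s$conc, transport = "mc", field = sh$field)
  a_dif <- absorbed_photon_profile(0.5, sh$field$source, sh$optics, s$ps, s$conc)
  expect_equal(a_mc / a_dif, 1, tolerance = 0.1)
  expect_error(absorbed_photon_profile(10, sh$field$source, sh$optics, s$ps,
                                       s$conc, transport = "mc",
                                       field = sh$field), "outside")
  expect_error(absorbed_photon_profile(0.5, sh$field$source, sh$optics, s$ps,
                                       s$conc, transport = "mc"), "field")
})

test_that("selectivity depths follow the log-3 rule", {
  expect_equal(selectivity_depths(3)$depths, 1.0, tolerance = 1e-12)
  expect_equal(selectivity_depths(20)$depths, log(20) / log(3),
               tolerance = 1e-12)
  expect_equal(selectivity_depths(20)$depths, 2.73, tolerance = 2e-3)
  expect_equal(selectivity_depths(10.6)$depths, 2.15, tolerance = 2e-3)
  expect_equal(selectivity_depths(1)$depths, 0)
  opt <- default_tissue_optics()$gray_808
  sd_ <- selectivity_depths(20, opt)
  expect_equal(sd_$distance_cm, sd_$depths / opt$mu_eff)
  expect_error(selectivity_depths(0.5), "sur")
})

test_that("edema fold change and mask volumes behave", {
  expect_equal(edema_fold_change(2.5, 2.5), 1.0)
  expect_equal(edema_fold_change(2, 5), 2.5)
  expect_error(edema_fold_change(0, 1), "positive")
  expect_equal(mask_volume(1), 0.02)       # 0.2 x 0.2 x 0.5 mm voxels
  expect_equal(mask_volume(250), 5)        # mm^3
})

test_that("hand-written Welch t matches stats::t.test", {
  set.seed(3)
  x <- rnorm(8, 2, 0.5); y <- rnorm(6, 2.6, 0.9)
  ours <- fold_change_test(x, y)
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # equal-mean groups give a near-zero statistic
  z <- fold_change_test(c(1, 2, 3, 2), c(2, 1, 2, 3))
  expect_lt(abs(z$statistic), 1e-12)
})

test_that("boundary observation invariants are enforced", {
  s <- th_setup()
  bad <- data.frame(animal_id = "a", r_min_cm = 0.5, r_max_cm = 0.4)
  expect_error(threshold_at_boundary(bad, s$src, s$opt, s$ps, s$conc),
               "r_min")
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(animal_id = "a", r_min_cm = 0.4, r_max_cm = 0.5,
                       tissue = "gray_808"), tmp, row.names = FALSE)
  expect_equal(read_boundaries_csv(tmp)$r_max_cm, 0.5)
})
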