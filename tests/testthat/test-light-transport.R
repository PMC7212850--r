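# Diffusion closed form, voxel Monte Carlo, and dose-volume summaries.

test_that("derived diffusion parameters are internally consistent", {
  o <- tissue_optics(0.02, 16.62, 0.9, "gray_808")
  expect_equal(o$D, 1 / (3 * (o$mu_a + o$mu_s_prime)), tolerance = 1e-12)
  expect_equal(o$mu_eff, sqrt(3 * o$mu_a * (o$mu_a + o$mu_s_prime)),
               tolerance = 1e-12)
  expect_equal(o$mu_eff, 1.0, tolerance = 1e-3)
  expect_error(tissue_optics(-0.1, 10), "mu_a")
  expect_error(tissue_optics(0.1, 0), "mu_s_prime")
  expect_error(tissue_optics(0.1, 10, g = 1), "'g'")
})

test_that("diffusion fluence matches independent evaluation of the closed form", {
  o <- tissue_optics(0.02, 16.62)
  P <- 0.2; r <- 1
  direct <- P * exp(-sqrt(3 * 0.02 * 16.64) * r) /
    (4 * pi * (1 / (3 * 16.64)) * r)
  expect_equal(diffusion_fluence(r, P, o), direct, tolerance = 1e-12)
  expect_equal(diffusion_fluence(r, P, o), 0.29, tolerance = 0.01)
  # strictly decreasing, linear in power
  rr <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(diffusion_fluence(rr, P, o)) < 0))
  expect_equal(diffusion_fluence(rr, 2 * P, o), 2 * diffusion_fluence(rr, P, o))
  expect_error(diffusion_fluence(0, P, o), "singular")
})

test_that("effective penetration depth is 1/mu_eff and deeper in gray than white", {
  o <- tissue_optics(0.02, 16.62)
  expect_equal(effective_penetration_depth(o), 1 / o$mu_eff)
  o2 <- tissue_optics(0.08, 16.56) # mu_a x4 at equal transport sum: mu_eff doubled
  expect_equal(effective_penetration_depth(o2),
               effective_penetration_depth(o) / 2, tolerance = 1e-3)
  # at equal mu_a, higher mu_s' (white matter) means shallower penetration
  gray <- tissue_optics(0.02, 16.62, label = "gray")
  white <- tissue_optics(0.02, 30, label = "white")
  expect_gt(effective_penetration_depth(gray),
            effective_penetration_depth(white))
})

test_that("phantom construction validates geometry and labels", {
  o <- tissue_optics(0.05, 10)
  expect_error(phantom(array(1L, c(4, 4)), 0.1, c(0.2, 0.2, 0.2), o), "3D")
  expect_error(phantom(array(2L, c(4, 4, 4)), 0.1, c(0.2, 0.2, 0.2), list(o)),
               "label")
  expect_error(phantom(array(1L, c(4, 4, 4)), 0.1, c(1, 0.2, 0.2), list(o)),
               "inside")
  ph <- homogeneous_phantom(n = 9, voxel_cm = 0.1, optics = o)
  expect_equal(ph$source_cm, rep(0.45, 3))
})

test_that("phantom text format round-trips", {
  o <- list(tissue_optics(0.05, 10, 0.8, "tumor"),
            tissue_optics(0.02, 16.62, 0.9, "gray"))
  lab <- array(1L, c(5, 6, 7)); lab[3:5, , ] <- 2L
  ph <- phantom(lab, 0.05, c(0.12, 0.15, 0.17), o)
  tmp <- tempfile(fileext = ".txt")
  write_phantom(ph, tmp)
  ph2 <- read_phantom(tmp)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$voxel_cm, ph$voxel_cm)
  expect_equal(ph2$source_cm, ph$source_cm)
  expect_equal(ph2$optics[[2]]$mu_eff, ph$optics[[2]]$mu_eff)
})

test_that("identical seeds give bit-identical fields; seeds are independent of R's RNG", {
  o <- tissue_optics(0.05, 10, g = 0)
  ph <- homogeneous_phantom(n = 11, voxel_cm = 0.1, optics = o)
  src <- default_light_sources()$interstitial_808
  set.seed(1); a <- mc_fluence(ph, src, packets = 1e4, seed = 42)
  set.seed(999); b <- mc_fluence(ph, src, packets = 1e4, seed = 42)
  expect_identical(a$photon_density, b$photon_density)
  c_ <- mc_fluence(ph, src, packets = 1e4, seed = 43)
  expect_false(identical(a$photon_density, c_$photon_density))
})

test_that("launched weight is fully accounted for", {
  o <- tissue_optics(0.05, 10, g = 0.9)
  ph <- homogeneous_phantom(n = 11, voxel_cm = 0.1, optics = o)
  src <- default_light_sources()$interstitial_808
  f <- mc_fluence(ph, src, packets = 2e4, seed = 5)
  expect_lt(abs(f$accounting$total - 1), 1e-6)
  expect_gt(f$accounting$absorbed, 0)
  expect_gt(f$accounting$escaped, 0)
})

test_that("MC radial average agrees with diffusion in the high-albedo regime", {
  sh <- shared_mc_field() # g = 0, mu_a 0.02, mu_s' 16.62, 1e5 packets, 41^3
  prof <- radial_profile(sh$field, r_max = 1.0)
  d <- prof[prof$r >= 0.2 & prof$r <= 0.85, ]
  ref <- diffusion_fluence(d$r, sh$field$source$power, sh$optics)
  expect_true(all(abs(d$fluence_rate / ref - 1) < 0.10))
})

test_that("anisotropic scattering at matched mu_s' reproduces the g = 0 field", {
  # similarity relation: transport depends on mu_s' away from the source
  src <- default_light_sources()$interstitial_808
  o0 <- tissue_optics(0.04, 8, g = 0)
  o5 <- tissue_optics(0.04, 8, g = 0.5)
  ph0 <- homogeneous_phantom(n = 31, voxel_cm = 0.1, optics = o0)
  ph5 <- homogeneous_phantom(n = 31, voxel_cm = 0.1, optics = o5)
  f0 <- mc_fluence(ph0, src, packets = 6e4, seed = 21)
  f5 <- mc_fluence(ph5, src, packets = 6e4, seed = 22)
  p0 <- radial_profile(f0, r_max = 0.7)
  p5 <- radial_profile(f5, r_max = 0.7)
  sel <- p0$r >= 0.2
  expect_true(all(abs(p5$fluence_rate[sel] / p0$fluence_rate[sel] - 1) < 0.12))
})

test_that("heterogeneous voxel marching agrees with the homogeneous fast path", {
  # two labels with identical optics: physically the same medium, but forces
  # the boundary-crossing code path
  src <- default_light_sources()$interstitial_808
  o <- tissue_optics(0.05, 10, g = 0)
  n <- 21
  lab <- array(1L, c(n, n, n)); lab[seq(1, n, by = 2), , ] <- 2L
  ph_het <- phantom(lab, 0.1, rep(n * 0.1 / 2, 3), list(o, o))
  ph_hom <- homogeneous_phantom(n = n, voxel_cm = 0.1, optics = o)
  fh <- mc_fluence(ph_het, src, packets = 5e4, seed = 31)
  fo <- mc_fluence(ph_hom, src, packets = 5e4, seed = 31)
  expect_lt(abs(fh$accounting$total - 1), 1e-6)
  ph_ <- radial_profile(fh, r_max = 0.6)
  po_ <- radial_profile(fo, r_max = 0.6)
  sel <- ph_$r >= 0.15
  expect_true(all(abs(ph_$fluence_rate[sel] / po_$fluence_rate[sel] - 1) < 0.08))
})

test_that("MC standard error scales like 1/sqrt(packets)", {
  src <- default_light_sources()$interstitial_808
  o <- tissue_optics(0.05, 10, g = 0)
  ph <- homogeneous_phantom(n = 15, voxel_cm = 0.1, optics = o)
  budgets <- c(1e4, 2e4, 4e4, 8e4)
  sds <- vapply(seq_along(budgets), function(bi) {
    reps <- vapply(1:6, function(k) {
      f <- mc_fluence(ph, src, packets = budgets[bi], seed = 1000 * bi + k)
      radial_profile(f, r_max = 0.45)$fluence_rate[3]
    }, 0)
    sd(reps)
  }, 0)
  slope <- coef(lm(log(sds) ~ log(budgets)))[2]
  expect_gt(slope, -0.85)
  expect_lt(slope, -0.2)
})

test_that("field is invariant under translating source and grid together", {
  src <- default_light_sources()$interstitial_808
  o <- tissue_optics(0.05, 10, g = 0)
  n <- 21
  ph1 <- phantom(array(1L, c(n, n, n)), 0.1, rep(1.05, 3), list(o))
  ph2 <- phantom(array(1L, c(n, n, n)), 0.1, rep(1.05, 3) + 0.1, list(o))
  f1 <- mc_fluence(ph1, src, packets = 4e4, seed = 77)
  f2 <- mc_fluence(ph2, src, packets = 4e4, seed = 77)
  p1 <- radial_profile(f1, r_max = 0.4)
  p2 <- radial_profile(f2, r_max = 0.4)
  sel1 <- p1$r > 0.1 & p1$r < 0.4
  sel2 <- p2$r > 0.1 & p2$r < 0.4
  expect_equal(p2$fluence_rate[sel2], p1$fluence_rate[sel1], tolerance = 0.08)
})

test_that("dose-volume histogram has the defining properties", {
  sh <- shared_mc_field()
  dvh <- dose_volume_histogram(sh$field)
  tb <- dvh$dvh
  # V(0) is the total phantom volume; curve non-increasing
  expect_equal(tb$volume_cm3[1], prod(dim(sh$field$phantom$labels)) *
                 sh$field$phantom$voxel_cm^3)
  expect_true(all(diff(tb$volume_cm3) <= 0))
  # brute-force oracle at sampled thresholds
  x <- as.numeric(sh$field$photon_density)
  v <- sh$field$phantom$voxel_cm^3
  for (d in sort(x)[c(10L, length(x) %/% 2, length(x) - 10L)]) {
    expect_equal(tb$volume_cm3[match(d, tb$dose)], sum(x >= d) * v,
                 tolerance = 1e-8)
  }
  # uniform field degenerates to a step function
  fu <- sh$field
  fu$photon_density[] <- 7
  tbu <- dose_volume_histogram(fu)$dvh
  expect_identical(nrow(tbu), 2L)
  expect_equal(tbu$dose, c(0, 7))
  expect_equal(tbu$volume_cm3[1], tbu$volume_cm3[2])
  # grid congruence check
  o <- tissue_optics(0.05, 10)
  expect_error(dose_volume_histogram(sh$field,
                                     homogeneous_phantom(5, 0.1, o)), "match")
})

test_that("mc_fluence rejects wrong geometry and tiny budgets", {
  o <- tissue_optics(0.05, 10)
  ph <- homogeneous_phantom(n = 9, voxel_cm = 0.1, optics = o)
  expect_error(mc_fluence(ph, default_light_sources()$well_530, 1e4),
               "isotropic_point")
  expect_error(mc_fluence(ph, default_light_sources()$interstitial_808, 100),
               "1e4|10000")
})
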