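# Independent oracles and shared fixtures for the test suite.

# Product-limit estimate by explicit risk-set recomputation (loops, no
# vectorized shortcuts) -- independent of km_estimate's code path.
brute_km <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  surv <- numeric(length(dt))
  s <- 1
  for (i in seq_along(dt)) {
    at_risk <- 0; deaths <- 0
    for (j in seq_along(time)) {
      if (time[j] >= dt[i]) at_risk <- at_risk + 1
      if (time[j] == dt[i] && event[j] == 1) deaths <- deaths + 1
    }
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  data.frame(time = dt, surv = surv)
}

# Mantel-Cox O, E, V by explicit per-time tabulation.
brute_logrank <- function(time, event, arm) {
  lv <- sort(unique(arm))
  dt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in dt) {
    n <- sum(time >= t)
    na <- sum(time >= t & arm == lv[1])
    d <- sum(time == t & event == 1)
    da <- sum(time == t & event == 1 & arm == lv[1])
    O <- O + da
    E <- E + d * na / n
    if (n > 1) V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V,
       chisq = if (V > 0) (O - E)^2 / V else NA_real_)
}

# Small shared Monte Carlo field (computed lazily, reused across tests).
.test_env <- new.env(parent = emptyenv())
shared_mc_field <- function() {
  if (is.null(.test_env$field)) {
    opt <- tissue_optics(0.02, 16.62, g = 0, label = "bench")
    ph <- homogeneous_phantom(n = 41, voxel_cm = 0.1, optics = opt)
    src <- default_light_sources()$interstitial_808
    .test_env$field <- mc_fluence(ph, src, packets = 1e5, seed = 11)
    .test_env$field_optics <- opt
  }
  list(field = .test_env$field, optics = .test_env$field_optics)
}
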