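# Seeded generators for every input table the pipeline consumes. Each
# generator is a pure function of (config, seed): it seeds R's RNG itself, so
# regenerating with the stored seed is bit-identical.

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles the study conditions the generators emulate: in vitro plate
#' designs over the assay concentration ranges (Rutherrin 0-500 nM, ALA
#' 0-6000 uM) with true LD50s implied by the published absorbed-photon LD50s;
#' the ICP-MS uptake design (tumor / contralateral brain / cerebellum at 4,
#' 24, 48 h and 5, 10 mg/kg with true SUR 20, 20, 12 and lognormal 15% CV);
#' the threshold design (generating threshold 8.86e18 hv cm^-3, boundary
#' radii jittered 5% around the forward-model radius, n = 6); and three
#' survival arms with medians 4.5 / 8.5 / 12.5 days (Weibull, shape 3 by
#' default; shape 1 recovers the exponential family).
#'
#' @param seed integer master seed; generator-specific seeds are derived from
#'   it by small fixed offsets.
#' @param ... named overrides for any of the nested blocks `plate`, `uptake`,
#'   `threshold`, `survival` (partial lists are merged over the defaults).
#' @return Object of class `pdt_scenario`.
#' @export
#' @examples
#' sc <- scenario_config(seed = 42, survival = list(n_per_arm = 12))
scenario_config <- function(seed = 1, ...) {
  ps <- default_photosensitizers()
  src <- default_light_sources()
  opt <- default_tissue_optics()
  cfg <- list(
    seed = as.integer(seed),
    photosensitizers = ps,
    light_sources = src,
    tissue_optics = opt,
    plate = list(
      rutherrin = list(
        concentrations = c(2, 5, 10, 20, 50, 100, 200, 500) * 1e-9,
        true_ld50 = implied_ld50_concentration(2.388e16, src$well_530,
                                               ps$rutherrin),
        hill_slope = 1.5, replicates = 6, noise_sd = 0.05,
        solvent_level = 1.0, kill_level = 0.02, n_controls = 6),
      ala = list(
        concentrations = c(25, 50, 100, 200, 400, 800, 1600, 3000, 6000) * 1e-6,
        true_ld50 = implied_ld50_concentration(1.539e19, src$well_635,
                                               ps$ala_ppix),
        hill_slope = 1.5, replicates = 6, noise_sd = 0.05,
        solvent_level = 1.0, kill_level = 0.02, n_controls = 6)),
    uptake = list(
      tissues = c("tumor", "contralateral_brain", "cerebellum"),
      timepoints_h = c(4, 24, 48),
      doses_mg_per_kg = c(5, 10),
      true_sur = c("4" = 20, "24" = 20, "48" = 12),
      reference_median_ug_per_g = 1.0,
      cv = 0.15, n_per_group = 3, absent_prob = 0,
      digest_volume_L = 0.002),
    threshold = list(
      true_threshold = 8.86e18,
      # placeholder tumor TLD1433 concentration putting the forward necrosis
      # boundary near 5 mm, the anatomical scale of a 3 mm tumor plus margin
      tissue_concentration_M = 3.9e-8,
      source = src$interstitial_808, optics = opt$gray_808,
      ps = ps$rutherrin, jitter = 0.05, n_animals = 6),
    survival = list(
      arm_medians = c(control = 4.5, ala_pdt = 8.5, rutherrin_pdt = 12.5),
      n_per_arm = 8, family = "weibull", shape = 3,
      censor_time = Inf)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown scenario block '", nm, "'", call. = FALSE)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
  }
  structure(cfg, class = "pdt_scenario")
}

#' @export
print.pdt_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario (seed %d):\n", x$seed))
  cat(sprintf("  plates: %s\n", paste(names(x$plate), collapse = ", ")))
  cat(sprintf("  uptake: SUR %s at %s h, %d/group\n",
              paste(x$uptake$true_sur, collapse = "/"),
              paste(x$uptake$timepoints_h, collapse = "/"),
              x$uptake$n_per_group))
  cat(sprintf("  threshold: %.3g hv cm^-3, %d animals, %.0f%% jitter\n",
              x$threshold$true_threshold, x$threshold$n_animals,
              100 * x$threshold$jitter))
  cat(sprintf("  survival: medians %s d, n = %d/arm, %s(shape %g)\n",
              paste(x$survival$arm_medians, collapse = "/"),
              x$survival$n_per_arm, x$survival$family, x$survival$shape))
  invisible(x)
}

#' Generate a synthetic in vitro plate
#'
#' True viability follows a four-parameter logistic kill curve between the
#' solvent and kill-control levels, plus Gaussian noise clipped at zero.
#' Solvent and kill-control wells are included so the plate is
#' self-normalizing.
#'
#' @param config a [scenario_config()].
#' @param agent which plate design (`"rutherrin"` or `"ala"`).
#' @param seed RNG seed (default derived from the scenario seed).
#' @return Plate records data frame ([normalize_plate()] layout) with the
#'   seed stored in `attr(, "seed")`.
#' @export
gen_plate <- function(config, agent = "rutherrin", seed = NULL) {
  stopifnot(inherits(config, "pdt_scenario"))
  p <- config$plate[[agent]]
  if (is.null(p)) stop("no plate design for agent '", agent, "'", call. = FALSE)
  if (is.null(seed)) seed <- config$seed + 101L
  set.seed(seed)
  conc <- rep(p$concentrations, each = p$replicates)
  kill_frac <- 1 / (1 + (p$true_ld50 / conc)^p$hill_slope)
  v_true <- p$kill_level + (1 - kill_frac) * (p$solvent_level - p$kill_level)
  noise <- function(n) rnorm(n, 0, p$noise_sd)
  treated <- data.frame(
    well_id = sprintf("%s_w%03d", agent, seq_along(conc)),
    agent = agent, concentration = conc,
    viability = pmax(0, v_true + noise(length(conc))),
    control_flag = "treated", stringsAsFactors = FALSE)
  ctrl <- data.frame(
    well_id = c(sprintf("%s_solv%d", agent, seq_len(p$n_controls)),
                sprintf("%s_kill%d", agent, seq_len(p$n_controls))),
    agent = agent, concentration = 0,
    viability = pmax(0, c(p$solvent_level + noise(p$n_controls),
                          p$kill_level + noise(p$n_controls))),
    control_flag = rep(c("solvent", "kill"), each = p$n_controls),
    stringsAsFactors = FALSE)
  out <- rbind(ctrl, treated)
  attr(out, "seed") <- seed
  out
}

#' Generate synthetic ICP-MS uptake samples
#'
#' Per-tissue concentrations are lognormal around tissue medians chosen so
#' the tumor-to-reference ratio of means equals the configured SUR at each
#' timepoint (equal log-sd in all tissues makes the mean ratio equal the
#' median ratio). Raw ppb readouts are back-computed through the ICP-MS
#' conversion so the generated table round-trips the real pipeline. With
#' `absent_prob > 0`, reference-tissue draws are zeroed at that probability
#' to exercise the "complete absence" sentinel path.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed.
#' @return Raw uptake table (see [process_uptake()]) with `attr(, "seed")`.
#' @export
gen_uptake <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pdt_scenario"))
  u <- config$uptake
  if (is.null(seed)) seed <- config$seed + 202L
  set.seed(seed)
  sdlog <- sqrt(log(1 + u$cv^2))
  rows <- list()
  k <- 0L
  for (tp in u$timepoints_h) for (dg in u$doses_mg_per_kg) {
    sur <- u$true_sur[[as.character(tp)]]
    med <- c(tumor = u$reference_median_ug_per_g * sur,
             contralateral_brain = u$reference_median_ug_per_g,
             cerebellum = u$reference_median_ug_per_g)
    for (ts in u$tissues) for (i in seq_len(u$n_per_group)) {
      conc <- rlnorm(1, log(med[[ts]]), sdlog)
      if (ts != "tumor" && u$absent_prob > 0 && runif(1) < u$absent_prob)
        conc <- 0
      mass <- runif(1, 0.05, 0.15)
      tld_ug <- conc * mass
      ru_ug <- tld_ug * .RU_ATOMIC_WEIGHT / .TLD1433_MW
      k <- k + 1L
      rows[[k]] <- data.frame(
        animal = sprintf("r%02d_%gh_%gmg", i, tp, dg), tissue = ts,
        timepoint_h = tp, dose_mg_per_kg = dg,
        ru_ppb = ru_ug / u$digest_volume_L, tissue_mass_g = mass,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Generate synthetic necrosis-boundary observations
#'
#' Runs the forward threshold model to the radius where the absorbed photon
#' density equals the generating threshold, then jitters per-animal maximum
#' boundary radii multiplicatively (Gaussian, sd = `jitter`). Minimum
#' distances are drawn as a fixed fraction band below the maximum.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed.
#' @return Boundary observation data frame with `attr(, "seed")` and
#'   `attr(, "true_radius_cm")`.
#' @export
gen_boundaries <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pdt_scenario"))
  th <- config$threshold
  if (is.null(seed)) seed <- config$seed + 303L
  set.seed(seed)
  r_star <- predict_necrosis_radius(th$true_threshold, th$source, th$optics,
                                    th$ps, th$tissue_concentration_M)
  if (r_star <= 0)
    stop("generating threshold is never reached: check the scenario", call. = FALSE)
  r_max <- r_star * (1 + rnorm(th$n_animals, 0, th$jitter))
  r_min <- r_max * runif(th$n_animals, 0.75, 0.95)
  out <- data.frame(animal_id = sprintf("a%02d", seq_len(th$n_animals)),
                    r_min_cm = r_min, r_max_cm = r_max,
                    tissue = th$optics$label, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "true_radius_cm") <- r_star
  out
}

#' Generate synthetic survival records
#'
#' Arm event times are Weibull with common shape and per-arm medians
#' (scale = median / log(2)^(1/shape)); shape 1 is the exponential family.
#' Administrative censoring at `censor_time` if finite.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed.
#' @return Survival records (`subject`, `arm`, `time`, `event`) with
#'   `attr(, "seed")`.
#' @export
gen_survival <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pdt_scenario"))
  s <- config$survival
  if (is.null(seed)) seed <- config$seed + 404L
  set.seed(seed)
  rows <- lapply(names(s$arm_medians), function(arm) {
    med <- s$arm_medians[[arm]]
    t <- if (s$family == "weibull")
      rweibull(s$n_per_arm, s$shape, med / log(2)^(1 / s$shape))
    else if (s$family == "exponential")
      rexp(s$n_per_arm, log(2) / med)
    else stop("unknown survival family '", s$family, "'", call. = FALSE)
    ev <- as.integer(t <= s$censor_time)
    data.frame(subject = sprintf("%s_%02d", arm, seq_len(s$n_per_arm)),
               arm = arm, time = pmin(t, s$censor_time), event = ev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Write a full synthetic scenario to disk
#'
#' Emits the plate, uptake, boundary and survival CSVs plus a JSON manifest
#' recording the seed, the derived per-generator seeds, the package version
#' and an md5 hash of the serialized configuration.
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_scenario <- function(config, dir) {
  stopifnot(inherits(config, "pdt_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plates <- lapply(names(config$plate), function(a) {
    p <- gen_plate(config, a)
    data.frame(well_id = p$well_id, agent = p$agent,
               concentration_M = p$concentration, viability = p$viability,
               control_flag = p$control_flag)
  })
  plate <- do.call(rbind, plates)
  write.csv(plate, file.path(dir, "plates.csv"), row.names = FALSE)
  upt <- gen_uptake(config)
  write.csv(upt, file.path(dir, "uptake.csv"), row.names = FALSE)
  bnd <- gen_boundaries(config)
  write.csv(bnd, file.path(dir, "boundaries.csv"), row.names = FALSE)
  srv <- gen_survival(config)
  write.csv(data.frame(subject = srv$subject, arm = srv$arm,
                       time_days = srv$time, event = srv$event),
            file.path(dir, "survival.csv"), row.names = FALSE)
  cfg_json <- file.path(dir, "scenario_config.json")
  jsonlite::write_json(.scenario_summary(config), cfg_json,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$seed,
    generator_seeds = list(plate = config$seed + 101L,
                           uptake = config$seed + 202L,
                           boundaries = config$seed + 303L,
                           survival = config$seed + 404L),
    package_version = as.character(packageVersion("pdtdose")),
    config_md5 = unname(tools::md5sum(cfg_json)),
    files = c("plates.csv", "uptake.csv", "boundaries.csv", "survival.csv",
              "scenario_config.json"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# serializable summary of a scenario (objects flattened to plain values)
.scenario_summary <- function(config) {
  list(seed = config$seed,
       plate = lapply(config$plate, function(p)
         p[c("concentrations", "true_ld50", "hill_slope", "replicates",
             "noise_sd", "solvent_level", "kill_level", "n_controls")]),
       uptake = config$uptake[c("tissues", "timepoints_h", "doses_mg_per_kg",
                                "true_sur", "reference_median_ug_per_g", "cv",
                                "n_per_group", "absent_prob")],
       threshold = list(true_threshold = config$threshold$true_threshold,
                        tissue_concentration_M = config$threshold$tissue_concentration_M,
                        jitter = config$threshold$jitter,
                        n_animals = config$threshold$n_animals,
                        source = config$threshold$source$name,
                        optics = config$threshold$optics$label,
                        ps = config$threshold$ps$name),
       survival = {
         s <- config$survival[c("arm_medians", "n_per_arm", "family", "shape")]
         s$censor_time <- if (is.finite(config$survival$censor_time))
           config$survival$censor_time else "none"
         s
       })
}
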