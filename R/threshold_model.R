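# Photodynamic threshold model: the absorbed photon density at the necrosis
# boundary, its inverse (predicted treatable radius), selectivity in units of
# effective penetration depths, and the edema fold-change helper.

#' Absorbed photon density profile around an interstitial emitter
#'
#' Absorbed photons per cm^3 at radius `r`: the areal photon density
#' delivered over the illumination (fluence rate x duration / photon energy)
#' times the photosensitizer absorption coefficient at the local tissue
#' concentration. Diffusion transport by default; a precomputed Monte Carlo
#' field can stand in for heterogeneous phantoms.
#'
#' @param r radius, cm, > 0.
#' @param source isotropic-point [light_source()].
#' @param optics [tissue_optics()].
#' @param ps [photosensitizer()].
#' @param tissue_concentration molar photosensitizer concentration in tissue.
#' @param use_ln10 see [ps_absorption_coefficient()].
#' @param transport `"diffusion"` or `"mc"`.
#' @param field [mc_fluence()] result, required for `transport = "mc"`.
#' @return hv cm^-3 at each `r`.
#' @export
absorbed_photon_profile <- function(r, source, optics, ps,
                                    tissue_concentration, use_ln10 = TRUE,
                                    transport = c("diffusion", "mc"),
                                    field = NULL) {
  stopifnot(inherits(source, "pdt_light"), inherits(ps, "pdt_ps"))
  transport <- match.arg(transport)
  if (source$geometry != "isotropic_point")
    stop("interstitial threshold work requires an isotropic_point source",
         call. = FALSE)
  mu_ps <- ps_absorption_coefficient(ps, tissue_concentration, use_ln10)
  if (transport == "diffusion") {
    stopifnot(inherits(optics, "pdt_optics"))
    fr <- diffusion_fluence(r, source$power, optics)
  } else {
    if (is.null(field)) stop("transport = 'mc' needs a 'field'", call. = FALSE)
    prof <- radial_profile(field)
    if (any(r > max(prof$r)) || any(r < min(prof$r)))
      stop("radius outside the simulated field", call. = FALSE)
    fr <- approx(prof$r, prof$fluence_rate, xout = r)$y
  }
  areal <- fr * source$duration / photon_energy(source$wavelength)
  absorbed_photon_density(areal, mu_ps)
}

#' Photodynamic threshold at observed necrosis boundaries
#'
#' For each animal, evaluates the absorbed photon density the forward model
#' predicts at the observed enhancement boundary radius; that value is the
#' photodynamic threshold the boundary implies. Per-animal thresholds are
#' aggregated as unweighted mean +/- sample sd. By default the upper
#' (maximum-distance) boundary is used, appropriate when the whole tumor
#' necrosed and only an upper bound on the threshold is identifiable.
#'
#' @param obs data frame with columns `animal_id`, `r_min_cm`, `r_max_cm`
#'   (and optionally `tissue`).
#' @param source,optics,ps,tissue_concentration,use_ln10,transport,field as
#'   in [absorbed_photon_profile()].
#' @param boundary `"max"` (upper boundary, default) or `"min"`.
#' @return Object of class `pdt_threshold` with `threshold` (mean), `sd`,
#'   per-animal values, and an input snapshot.
#' @export
threshold_at_boundary <- function(obs, source, optics, ps,
                                  tissue_concentration, use_ln10 = TRUE,
                                  transport = c("diffusion", "mc"),
                                  field = NULL, boundary = c("max", "min")) {
  boundary <- match.arg(boundary)
  transport <- match.arg(transport)
  req <- c("animal_id", "r_min_cm", "r_max_cm")
  if (!all(req %in% names(obs)))
    stop("boundary observations need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(obs$r_min_cm <= 0) || any(obs$r_max_cm < obs$r_min_cm))
    stop("need 0 < r_min_cm <= r_max_cm for every animal", call. = FALSE)
  r <- if (boundary == "max") obs$r_max_cm else obs$r_min_cm
  th <- absorbed_photon_profile(r, source, optics, ps, tissue_concentration,
                                use_ln10, transport, field)
  structure(list(threshold = mean(th), sd = if (length(th) > 1) sd(th) else 0,
                 per_animal = data.frame(animal_id = obs$animal_id,
                                         radius_cm = r, threshold = th),
                 boundary = boundary,
                 inputs = list(source = source, optics = optics, ps = ps,
                               tissue_concentration = tissue_concentration,
                               use_ln10 = use_ln10, transport = transport)),
            class = "pdt_threshold")
}

#' @export
print.pdt_threshold <- function(x, ...) {
  cat(sprintf("Photodynamic threshold (%s boundary, %s transport):\n",
              x$boundary, x$inputs$transport))
  cat(sprintf("  %.4g +/- %.3g hv cm^-3 over %d animal(s)\n",
              x$threshold, x$sd, nrow(x$per_animal)))
  invisible(x)
}

#' Predict the necrosis radius for a given photodynamic threshold
#'
#' Inverts the monotone absorbed-photon profile by bracketed root finding
#' (uniroot) to sub-micrometre tolerance, so the forward/inverse round trip
#' closes well below any measurement scale. A threshold above the
#' near-source absorbed density is a
#' no-necrosis outcome and returns radius 0 rather than an error.
#'
#' @param threshold hv cm^-3, > 0.
#' @param source,optics,ps,tissue_concentration,use_ln10 forward-model inputs.
#' @param r_max search bracket upper end, cm.
#' @return Radius in cm (0 when the threshold is never reached).
#' @export
predict_necrosis_radius <- function(threshold, source, optics, ps,
                                    tissue_concentration, use_ln10 = TRUE,
                                    r_max = 10) {
  if (threshold <= 0) stop("'threshold' must be positive", call. = FALSE)
  f <- function(r) absorbed_photon_profile(r, source, optics, ps,
                                           tissue_concentration, use_ln10) - threshold
  r_lo <- 1e-4 # 1 um: the profile diverges at the source
  if (f(r_lo) <= 0) return(0)
  while (f(r_max) > 0) r_max <- r_max * 2
  uniroot(f, c(r_lo, r_max), tol = 1e-10)$root
}

#' Selectivity expressed in effective penetration depths
#'
#' The rule of thumb that every factor of 3 in the tumor-to-normal specific
#' uptake ratio buys one effective penetration depth of treatment selectivity:
#' depths = log3(SUR), distance = depths / mu_eff.
#'
#' @param sur specific uptake ratio, >= 1.
#' @param optics optional [tissue_optics()]; when given, the physical
#'   distance is returned alongside.
#' @return List with `depths` and (when optics given) `distance_cm`.
#' @export
#' @examples
#' selectivity_depths(20)$depths # 2.73 penetration depths
selectivity_depths <- function(sur, optics = NULL) {
  if (any(!is.finite(sur)) || any(sur < 1))
    stop("'sur' must be >= 1", call. = FALSE)
  depths <- log(sur) / log(3)
  out <- list(depths = depths)
  if (!is.null(optics)) {
    stopifnot(inherits(optics, "pdt_optics"))
    out$distance_cm <- depths * effective_penetration_depth(optics)
  }
  out
}

#' Edema fold change from mask volumes
#'
#' @param pre_volume pre-treatment enhancement volume, > 0 (any volume unit).
#' @param post_volume post-treatment volume, >= 0, same unit.
#' @return post / pre, dimensionless.
#' @export
edema_fold_change <- function(pre_volume, post_volume) {
  if (any(!is.finite(pre_volume)) || any(pre_volume <= 0))
    stop("'pre_volume' must be positive", call. = FALSE)
  if (any(post_volume < 0)) stop("'post_volume' must be >= 0", call. = FALSE)
  post_volume / pre_volume
}

#' Volume of a voxel mask
#'
#' @param n_voxels voxel count in the mask.
#' @param dx,dy,dz voxel dimensions in mm (defaults: 0.2 x 0.2 mm in-plane,
#'   0.5 mm slices).
#' @return Volume in mm^3.
#' @export
mask_volume <- function(n_voxels, dx = 0.2, dy = 0.2, dz = 0.5) {
  if (any(n_voxels < 0)) stop("'n_voxels' must be >= 0", call. = FALSE)
  n_voxels * dx * dy * dz
}

#' Welch two-sample t test on fold changes
#'
#' Unpaired two-sample t statistic with unequal variances, written out from
#' the textbook formula: t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y numeric vectors of per-animal fold changes.
#' @return List with `statistic`, `df`, `p_value` (two-sided).
#' @export
fold_change_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 observations per group", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df))
}

#' Read necrosis-boundary observations from CSV
#'
#' Expects columns `animal_id`, `r_min_cm`, `r_max_cm`, `tissue`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_boundaries_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "r_min_cm", "r_max_cm", "tissue")
  if (!all(req %in% names(d)))
    stop("boundary CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  d
}
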