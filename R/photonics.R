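# Photonic and radiometric unit conversions. Everything downstream (LD50 in
# absorbed photons, thresholds at the necrosis boundary) reduces to these.

# CODATA 2018 / SI exact values
.PLANCK_H <- 6.62607015e-34 # J s
.LIGHT_C <- 2.99792458e8    # m/s

#' Photosensitizer definition
#'
#' Bundles the optical and chemical identity of a photosensitizer: molar
#' extinction coefficient at its activation wavelength, molecular weight and,
#' for pro-drugs, the precursor stoichiometry (number of administered
#' precursor molecules consumed per active photosensitizer molecule; 8 for
#' ALA -> protoporphyrin IX, 1 for drugs administered in active form).
#'
#' @param name label, e.g. `"rutherrin"`.
#' @param epsilon molar extinction coefficient at `wavelength`
#'   (decadic, M^-1 cm^-1), > 0.
#' @param wavelength activation wavelength in nm, in (300, 1100).
#' @param molecular_weight g/mol of the active photosensitizer.
#' @param precursor_ratio precursor molecules per active molecule, >= 1.
#' @return An object of class `pdt_ps`.
#' @export
#' @examples
#' photosensitizer("rutherrin", epsilon = 8427.4, wavelength = 530,
#'                 molecular_weight = 1007)
photosensitizer <- function(name, epsilon, wavelength, molecular_weight,
                            precursor_ratio = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a positive molar extinction coefficient", call. = FALSE)
  if (!is.numeric(wavelength) || wavelength <= 300 || wavelength >= 1100)
    stop("'wavelength' must lie in (300, 1100) nm", call. = FALSE)
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("'molecular_weight' must be positive", call. = FALSE)
  if (!is.numeric(precursor_ratio) || precursor_ratio < 1)
    stop("'precursor_ratio' must be >= 1", call. = FALSE)
  structure(list(name = name, epsilon = epsilon, wavelength = wavelength,
                 molecular_weight = molecular_weight,
                 precursor_ratio = precursor_ratio),
            class = "pdt_ps")
}

#' @export
print.pdt_ps <- function(x, ...) {
  cat(sprintf("Photosensitizer '%s': epsilon = %.1f M^-1 cm^-1 at %g nm, MW = %.1f g/mol",
              x$name, x$epsilon, x$wavelength, x$molecular_weight))
  if (x$precursor_ratio != 1)
    cat(sprintf(", %g precursor molecules per active molecule", x$precursor_ratio))
  cat("\n")
  invisible(x)
}

#' Light source definition
#'
#' A light delivery schedule. The power mode is explicit: a flat-field well
#' irradiator is specified by its irradiance (W cm^-2), an interstitial
#' isotropic emitter by its emitted power (W). Operations check the geometry
#' and mode they require and refuse mismatches rather than silently convert.
#'
#' @param name label.
#' @param wavelength nm.
#' @param duration illumination time in seconds, > 0.
#' @param geometry `"flat_field"` or `"isotropic_point"`.
#' @param irradiance W cm^-2 (flat-field sources only).
#' @param power W (isotropic point sources only).
#' @return An object of class `pdt_light`.
#' @export
#' @examples
#' # 360 mW/cm^2 green LED well irradiator delivering 20 J/cm^2
#' light_source("well_530", 530, duration = 20 / 0.360,
#'              geometry = "flat_field", irradiance = 0.360)
light_source <- function(name, wavelength, duration,
                         geometry = c("flat_field", "isotropic_point"),
                         irradiance = NULL, power = NULL) {
  geometry <- match.arg(geometry)
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("'wavelength' must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive", call. = FALSE)
  if (geometry == "flat_field") {
    if (is.null(irradiance) || !is.null(power))
      stop("flat_field sources are specified by 'irradiance' (W cm^-2), not 'power'",
           call. = FALSE)
    if (irradiance <= 0) stop("'irradiance' must be positive", call. = FALSE)
  } else {
    if (is.null(power) || !is.null(irradiance))
      stop("isotropic_point sources are specified by 'power' (W), not 'irradiance'",
           call. = FALSE)
    if (power <= 0) stop("'power' must be positive", call. = FALSE)
  }
  structure(list(name = name, wavelength = wavelength, duration = duration,
                 geometry = geometry, irradiance = irradiance, power = power),
            class = "pdt_light")
}

#' @export
print.pdt_light <- function(x, ...) {
  if (x$geometry == "flat_field")
    cat(sprintf("Light source '%s': flat field, %.3g W cm^-2 at %g nm for %.4g s (%.3g J cm^-2)\n",
                x$name, x$irradiance, x$wavelength, x$duration,
                x$irradiance * x$duration))
  else
    cat(sprintf("Light source '%s': isotropic point, %.3g W at %g nm for %.4g s (%.3g J)\n",
                x$name, x$power, x$wavelength, x$duration,
                x$power * x$duration))
  invisible(x)
}

#' Energy of a single photon
#'
#' @param wavelength wavelength in nm, > 0.
#' @return Energy per photon in joules, h*c/lambda.
#' @export
#' @examples
#' photon_energy(530) # ~3.75e-19 J
photon_energy <- function(wavelength) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("'wavelength' must be positive", call. = FALSE)
  .PLANCK_H * .LIGHT_C / (wavelength * 1e-9)
}

#' Radiant exposure to areal photon density
#'
#' Converts delivered optical energy per unit area into the number of photons
#' crossing unit area.
#'
#' @param exposure radiant exposure in J cm^-2, >= 0.
#' @param wavelength nm.
#' @return Areal photon density in hv cm^-2.
#' @seealso [photon_density_to_radiant_exposure()] for the inverse.
#' @export
#' @examples
#' radiant_exposure_to_photon_density(20, 530) # ~5.34e19 hv cm^-2
radiant_exposure_to_photon_density <- function(exposure, wavelength) {
  if (any(!is.finite(exposure)) || any(exposure < 0))
    stop("'exposure' must be non-negative", call. = FALSE)
  exposure / photon_energy(wavelength)
}

#' Areal photon density back to radiant exposure
#'
#' @param photon_density hv cm^-2, >= 0.
#' @param wavelength nm.
#' @return Radiant exposure in J cm^-2.
#' @export
photon_density_to_radiant_exposure <- function(photon_density, wavelength) {
  if (any(!is.finite(photon_density)) || any(photon_density < 0))
    stop("'photon_density' must be non-negative", call. = FALSE)
  photon_density * photon_energy(wavelength)
}

#' Time needed to deliver a target radiant exposure
#'
#' Full-precision seconds; rounding to whole seconds is a display concern
#' (see `round`).
#'
#' @param target_exposure J cm^-2, >= 0.
#' @param irradiance W cm^-2, > 0.
#' @param round round to the nearest whole second (default `FALSE`).
#' @return Seconds.
#' @export
#' @examples
#' exposure_time(20, 0.360)               # 55.56 s
#' exposure_time(20, 0.360, round = TRUE) # 56 s
exposure_time <- function(target_exposure, irradiance, round = FALSE) {
  if (any(!is.finite(target_exposure)) || any(target_exposure < 0))
    stop("'target_exposure' must be non-negative", call. = FALSE)
  if (any(!is.finite(irradiance)) || any(irradiance <= 0))
    stop("'irradiance' must be positive", call. = FALSE)
  t <- target_exposure / irradiance
  if (round) round(t) else t
}

#' Total delivered optical energy
#'
#' @param power W, > 0.
#' @param duration s, > 0.
#' @return Energy in joules.
#' @export
#' @examples
#' total_energy(0.2, 50 * 60) # 600 J
total_energy <- function(power, duration) {
  if (any(!is.finite(power)) || any(power <= 0))
    stop("'power' must be positive", call. = FALSE)
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("'duration' must be positive", call. = FALSE)
  power * duration
}

#' Photosensitizer absorption coefficient at a tissue/medium concentration
#'
#' Beer-Lambert absorption coefficient contributed by the photosensitizer,
#' mu_a,ps = ln(10) * epsilon * C. Extinction coefficients are tabulated on
#' the decadic (base-10) convention; the ln(10) factor converts them to the
#' natural-log attenuation coefficient radiative transport uses. Setting
#' `use_ln10 = FALSE` drops the factor, which is useful as a sensitivity
#' switch because published absorbed-photon doses do not always state which
#' convention they used.
#'
#' @param ps a [photosensitizer()].
#' @param concentration molar concentration of the active photosensitizer,
#'   >= 0.
#' @param use_ln10 include the decadic-to-natural factor (default `TRUE`).
#' @return Absorption coefficient in cm^-1.
#' @export
#' @examples
#' ru <- photosensitizer("rutherrin", 8427.4, 530, 1007)
#' ps_absorption_coefficient(ru, 500e-9) # ~9.7e-3 cm^-1
ps_absorption_coefficient <- function(ps, concentration, use_ln10 = TRUE) {
  stopifnot(inherits(ps, "pdt_ps"))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("'concentration' must be non-negative", call. = FALSE)
  fac <- if (isTRUE(use_ln10)) log(10) else 1
  fac * ps$epsilon * concentration
}

#' Absorbed photon density
#'
#' Photons absorbed by the photosensitizer per unit tissue volume: the
#' product of the areal photon density traversing the tissue and the
#' photosensitizer absorption coefficient. This is the common dose currency
#' used to compare photosensitizers.
#'
#' @param areal_density hv cm^-2, >= 0.
#' @param mu_a_ps photosensitizer absorption coefficient, cm^-1, >= 0.
#' @return Volumetric absorbed photon density in hv cm^-3.
#' @export
absorbed_photon_density <- function(areal_density, mu_a_ps) {
  if (any(!is.finite(areal_density)) || any(areal_density < 0))
    stop("'areal_density' must be non-negative", call. = FALSE)
  if (any(!is.finite(mu_a_ps)) || any(mu_a_ps < 0))
    stop("'mu_a_ps' must be non-negative", call. = FALSE)
  areal_density * mu_a_ps
}

#' Radiant exposure delivered by a flat-field source
#'
#' @param source a [light_source()] with `geometry = "flat_field"`.
#' @return J cm^-2.
#' @export
source_exposure <- function(source) {
  stopifnot(inherits(source, "pdt_light"))
  if (source$geometry != "flat_field")
    stop("radiant exposure is defined for flat_field sources; got '",
         source$geometry, "'", call. = FALSE)
  source$irradiance * source$duration
}

#' Built-in photosensitizer definitions
#'
#' The two agents of the reference rat glioma comparison: Rutherrin (the
#' ruthenium complex TLD1433 formulated with apo-transferrin; epsilon =
#' 8427.4 M^-1 cm^-1 at 530 nm, MW 1007 g/mol) and ALA-induced
#' protoporphyrin IX (epsilon = 5121 M^-1 cm^-1 at 635 nm, MW 562.66 g/mol,
#' 8 ALA molecules consumed per PpIX).
#'
#' @return Named list of [photosensitizer()] objects.
#' @export
default_photosensitizers <- function() {
  list(
    rutherrin = photosensitizer("rutherrin", epsilon = 8427.4,
                                wavelength = 530, molecular_weight = 1007,
                                precursor_ratio = 1),
    ala_ppix = photosensitizer("ala_ppix", epsilon = 5121,
                               wavelength = 635, molecular_weight = 562.66,
                               precursor_ratio = 8)
  )
}

#' Built-in light schedules
#'
#' The four delivery schedules of the reference study: the in vitro well
#' irradiators (530 nm at 360 mW cm^-2 delivering 20 J cm^-2; 635 nm at
#' 75 mW cm^-2 delivering 10 J cm^-2) and the in vivo interstitial isotropic
#' emitters (808 nm, 200 mW for 50 min = 600 J; 635 nm, 18 mW for
#' 22 min 13 s = 24 J).
#'
#' @return Named list of [light_source()] objects.
#' @export
default_light_sources <- function() {
  list(
    well_530 = light_source("well_530", 530, duration = 20 / 0.360,
                            geometry = "flat_field", irradiance = 0.360),
    well_635 = light_source("well_635", 635, duration = 10 / 0.075,
                            geometry = "flat_field", irradiance = 0.075),
    interstitial_808 = light_source("interstitial_808", 808,
                                    duration = 50 * 60,
                                    geometry = "isotropic_point", power = 0.2),
    interstitial_635 = light_source("interstitial_635", 635,
                                    duration = 22 * 60 + 13,
                                    geometry = "isotropic_point", power = 0.018)
  )
}

#' Read photosensitizer / light-source / optics definitions from YAML
#'
#' The config declares units explicitly per field. Expected top-level keys:
#' `photosensitizers`, `light_sources`, `tissue_optics`; see the file shipped
#' at `system.file("extdata", "default_config.yaml", package = "pdtdose")`.
#'
#' @param path YAML file.
#' @return List with elements `photosensitizers`, `light_sources`,
#'   `tissue_optics` (each possibly empty).
#' @export
read_pdt_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ps <- lapply(cfg$photosensitizers, function(p)
    photosensitizer(p$name, epsilon = p$epsilon_M_cm,
                    wavelength = p$wavelength_nm,
                    molecular_weight = p$molecular_weight_g_mol,
                    precursor_ratio = if (is.null(p$precursor_ratio)) 1 else p$precursor_ratio))
  if (length(ps)) names(ps) <- vapply(ps, `[[`, "", "name")
  ls_ <- lapply(cfg$light_sources, function(s)
    light_source(s$name, wavelength = s$wavelength_nm,
                 duration = s$duration_s, geometry = s$geometry,
                 irradiance = s$irradiance_W_cm2, power = s$power_W))
  if (length(ls_)) names(ls_) <- vapply(ls_, `[[`, "", "name")
  to <- lapply(cfg$tissue_optics, function(o)
    tissue_optics(mu_a = o$mu_a_cm, mu_s_prime = o$mu_s_prime_cm,
                  g = if (is.null(o$g)) 0.9 else o$g, label = o$label))
  if (length(to)) names(to) <- vapply(to, `[[`, "", "label")
  list(photosensitizers = ps, light_sources = ls_, tissue_optics = to)
}
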