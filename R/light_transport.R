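# Interstitial light transport in turbid tissue: diffusion closed form around
# an isotropic point emitter, a seeded voxel Monte Carlo simulator, and
# dose-volume summaries.

#' Tissue optical properties
#'
#' Absorption and reduced-scattering coefficients of a tissue class, with the
#' derived diffusion parameters: diffusion coefficient
#' D = 1 / (3 (mu_a + mu_s')) and effective attenuation
#' mu_eff = sqrt(3 mu_a (mu_a + mu_s')).
#'
#' @param mu_a absorption coefficient, cm^-1, > 0.
#' @param mu_s_prime reduced scattering coefficient mu_s' = mu_s (1 - g),
#'   cm^-1, > 0.
#' @param g scattering anisotropy for Monte Carlo transport, in (-1, 1).
#'   The diffusion quantities depend only on `mu_s_prime`.
#' @param label tissue class label, e.g. `"gray_808"`.
#' @return Object of class `pdt_optics` with `D` and `mu_eff` attached.
#' @export
#' @examples
#' tissue_optics(0.02, 16.62, g = 0.9, label = "gray_808")
tissue_optics <- function(mu_a, mu_s_prime, g = 0.9, label = "tissue") {
  if (!is.numeric(mu_a) || mu_a <= 0) stop("'mu_a' must be > 0", call. = FALSE)
  if (!is.numeric(mu_s_prime) || mu_s_prime <= 0)
    stop("'mu_s_prime' must be > 0", call. = FALSE)
  if (!is.numeric(g) || g <= -1 || g >= 1)
    stop("'g' must lie in (-1, 1)", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g, label = label,
                 D = 1 / (3 * (mu_a + mu_s_prime)),
                 mu_eff = sqrt(3 * mu_a * (mu_a + mu_s_prime))),
            class = "pdt_optics")
}

#' @export
print.pdt_optics <- function(x, ...) {
  cat(sprintf("Tissue optics '%s': mu_a = %.4g, mu_s' = %.4g cm^-1, g = %.2f | mu_eff = %.4g cm^-1, 1/mu_eff = %.3g cm\n",
              x$label, x$mu_a, x$mu_s_prime, x$g, x$mu_eff, 1 / x$mu_eff))
  invisible(x)
}

#' Placeholder optics table for rat brain tissue classes
#'
#' Literature-typical values, not measured ones: chosen so the effective
#' penetration depths are consistent with the selectivity distances printed
#' for the reference study (gray matter 1.0 cm at 808 nm, 0.54 cm white at
#' 808 nm, 0.83 cm gray / 0.36 cm white at 635 nm). Treat as placeholders and
#' replace with measured properties whenever available.
#'
#' @return Named list of [tissue_optics()].
#' @export
default_tissue_optics <- function() {
  list(
    tumor_808 = tissue_optics(0.03, 15.0, 0.9, "tumor_808"),
    gray_808  = tissue_optics(0.02, 16.62, 0.9, "gray_808"),
    white_808 = tissue_optics(0.07, 16.6, 0.9, "white_808"),
    gray_635  = tissue_optics(0.024, 20.0, 0.9, "gray_635"),
    white_635 = tissue_optics(0.064, 40.0, 0.9, "white_635")
  )
}

#' Diffusion-approximation fluence rate around an isotropic point source
#'
#' Infinite homogeneous medium closed form:
#' phi(r) = P exp(-mu_eff r) / (4 pi D r).
#'
#' @param r radial distance from the emitter, cm, > 0.
#' @param power emitted power, W.
#' @param optics [tissue_optics()].
#' @return Fluence rate in W cm^-2.
#' @export
#' @examples
#' diffusion_fluence(1, 0.2, tissue_optics(0.02, 16.62)) # ~0.29 W/cm^2
diffusion_fluence <- function(r, power, optics) {
  stopifnot(inherits(optics, "pdt_optics"))
  if (any(!is.finite(r)) || any(r <= 0))
    stop("fluence is singular at r = 0; 'r' must be > 0", call. = FALSE)
  if (any(power <= 0)) stop("'power' must be positive", call. = FALSE)
  power * exp(-optics$mu_eff * r) / (4 * pi * optics$D * r)
}

#' Effective penetration depth
#'
#' The 1/e decay length of the diffuse fluence, 1/mu_eff.
#'
#' @param optics [tissue_optics()].
#' @return Depth in cm.
#' @export
effective_penetration_depth <- function(optics) {
  stopifnot(inherits(optics, "pdt_optics"))
  1 / optics$mu_eff
}

#' Voxel phantom
#'
#' An isotropic voxel grid of tissue labels with an interstitial source
#' position, the geometry the Monte Carlo simulator transports through.
#' Physical coordinates have their origin at the grid corner, so the grid
#' spans `[0, dim * voxel_cm]` on each axis.
#'
#' @param labels 3D integer array of tissue labels, values indexing `optics`.
#' @param voxel_cm voxel edge length, cm.
#' @param source_cm numeric length-3 source position, cm, strictly inside.
#' @param optics list of [tissue_optics()], one per label value.
#' @return Object of class `pdt_phantom`.
#' @export
phantom <- function(labels, voxel_cm, source_cm, optics) {
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_cm) || voxel_cm <= 0)
    stop("'voxel_cm' must be > 0", call. = FALSE)
  if (inherits(optics, "pdt_optics")) optics <- list(optics)
  if (!all(vapply(optics, inherits, TRUE, "pdt_optics")))
    stop("'optics' must be a list of tissue_optics objects", call. = FALSE)
  lab <- as.integer(labels)
  if (any(is.na(lab)) || any(lab < 1L) || any(lab > length(optics)))
    stop("all labels must index the optics table (1..", length(optics), ")",
         call. = FALSE)
  ext <- dim(labels) * voxel_cm
  if (length(source_cm) != 3L || any(source_cm <= 0) || any(source_cm >= ext))
    stop("'source_cm' must lie strictly inside the grid", call. = FALSE)
  structure(list(labels = array(lab, dim(labels)), voxel_cm = voxel_cm,
                 source_cm = as.numeric(source_cm), optics = optics),
            class = "pdt_phantom")
}

#' @export
print.pdt_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Voxel phantom: %d x %d x %d voxels of %.3g cm (%.3g x %.3g x %.3g cm), %d tissue class(es)\n",
              d[1], d[2], d[3], x$voxel_cm, d[1] * x$voxel_cm,
              d[2] * x$voxel_cm, d[3] * x$voxel_cm, length(x$optics)))
  cat(sprintf("  source at (%.3g, %.3g, %.3g) cm\n",
              x$source_cm[1], x$source_cm[2], x$source_cm[3]))
  invisible(x)
}

#' Homogeneous cubic phantom with a centred source
#'
#' @param n voxels per edge.
#' @param voxel_cm voxel edge, cm.
#' @param optics a single [tissue_optics()].
#' @return A [phantom()].
#' @export
homogeneous_phantom <- function(n = 51, voxel_cm = 0.1, optics) {
  phantom(array(1L, c(n, n, n)), voxel_cm,
          rep(n * voxel_cm / 2, 3), list(optics))
}

#' Write / read a phantom in the package's plain-text grid format
#'
#' Header lines (`key: value`) followed by the label array in x-fastest
#' order, whitespace-separated. Optics are stored as `mu_a mu_s_prime g label`
#' rows.
#'
#' @param x a [phantom()].
#' @param path file path.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` a
#'   [phantom()].
#' @export
write_phantom <- function(x, path) {
  stopifnot(inherits(x, "pdt_phantom"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(x$labels)
  writeLines(c("pdtdose-phantom: 1",
               paste("dims:", paste(d, collapse = " ")),
               paste("voxel_cm:", format(x$voxel_cm, digits = 17)),
               paste("source_cm:", paste(format(x$source_cm, digits = 17), collapse = " ")),
               paste("n_optics:", length(x$optics))), con)
  for (o in x$optics)
    writeLines(paste("optics:", format(o$mu_a, digits = 17),
                     format(o$mu_s_prime, digits = 17),
                     format(o$g, digits = 17), o$label), con)
  writeLines(paste(as.integer(x$labels), collapse = " "), con)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  ln <- readLines(path)
  if (!grepl("^pdtdose-phantom:", ln[1]))
    stop("not a pdtdose phantom file", call. = FALSE)
  val <- function(key) sub(paste0("^", key, ": *"), "",
                           ln[grep(paste0("^", key, ":"), ln)[1]])
  d <- as.integer(strsplit(val("dims"), " +")[[1]])
  vox <- as.numeric(val("voxel_cm"))
  src <- as.numeric(strsplit(val("source_cm"), " +")[[1]])
  orows <- grep("^optics:", ln, value = TRUE)
  optics <- lapply(orows, function(r) {
    f <- strsplit(sub("^optics: *", "", r), " +")[[1]]
    tissue_optics(as.numeric(f[1]), as.numeric(f[2]), as.numeric(f[3]), f[4])
  })
  lab <- as.integer(strsplit(ln[length(ln)], " +")[[1]])
  phantom(array(lab, d), vox, src, optics)
}

#' Monte Carlo fluence around an interstitial isotropic emitter
#'
#' Photon-packet transport through the phantom's voxel grid with
#' Henyey-Greenstein scattering (sampled at mu_s = mu_s' / (1 - g)),
#' absorption-weight deposition, and Russian roulette. Boundaries are
#' refractive-index matched (packets leaving the grid escape). The per-voxel
#' fluence rate is deposited weight / (mu_a * voxel volume), scaled by the
#' emitted power; the integrated areal photon density additionally folds in
#' the illumination time and photon energy.
#'
#' Identical `seed` gives a bit-identical field: the simulator uses its own
#' counter-seeded generator and leaves R's RNG untouched.
#'
#' @param phantom a [phantom()].
#' @param source [light_source()] with `geometry = "isotropic_point"`.
#' @param packets number of photon packets, >= 1e4.
#' @param seed integer seed.
#' @param weight_threshold Russian-roulette trigger weight.
#' @param roulette_p survival probability in roulette.
#' @return Object of class `pdt_fluence`: `fluence_rate` (W cm^-2, 3D array),
#'   `photon_density` (hv cm^-2, 3D array), energy accounting, packet count
#'   and seed.
#' @export
mc_fluence <- function(phantom, source, packets = 1e5, seed = 1,
                       weight_threshold = 1e-4, roulette_p = 0.1) {
  stopifnot(inherits(phantom, "pdt_phantom"), inherits(source, "pdt_light"))
  if (source$geometry != "isotropic_point")
    stop("mc_fluence requires an isotropic_point source", call. = FALSE)
  if (packets < 1e4) stop("'packets' must be >= 1e4", call. = FALSE)
  mu_a <- vapply(phantom$optics, `[[`, 0, "mu_a")
  msp <- vapply(phantom$optics, `[[`, 0, "mu_s_prime")
  g <- vapply(phantom$optics, `[[`, 0, "g")
  mu_s <- msp / (1 - g)
  res <- .mc_transport_cpp(as.integer(phantom$labels), dim(phantom$labels),
                           phantom$voxel_cm, phantom$source_cm,
                           mu_a, mu_s, g, as.double(packets), as.double(seed),
                           weight_threshold, roulette_p)
  total <- res$absorbed + res$escaped + res$terminated
  if (abs(total - res$packets) / res$packets > 1e-6 ||
      res$lost_packets / res$packets > 0.01)
    stop(sprintf("energy accounting failed: %.8g of %g launched weight accounted, %g packets lost",
                 total, res$packets, res$lost_packets), call. = FALSE)
  d <- dim(phantom$labels)
  vvox <- phantom$voxel_cm^3
  mua_vox <- mu_a[as.integer(phantom$labels)]
  frac <- res$deposit / res$packets
  fl_rate <- array(source$power * frac / (mua_vox * vvox), d)
  pdens <- fl_rate * source$duration / photon_energy(source$wavelength)
  structure(list(fluence_rate = fl_rate, photon_density = pdens,
                 packets = res$packets, seed = seed,
                 accounting = list(absorbed = res$absorbed / res$packets,
                                   escaped = res$escaped / res$packets,
                                   terminated = res$terminated / res$packets,
                                   total = total / res$packets,
                                   lost_packets = res$lost_packets),
                 phantom = phantom, source = source),
            class = "pdt_fluence")
}

#' @export
print.pdt_fluence <- function(x, ...) {
  cat(sprintf("Monte Carlo fluence field: %g packets, seed %g\n", x$packets, x$seed))
  cat(sprintf("  weight: absorbed %.4f, escaped %.4f, roulette net %.4g (sum %.8f)\n",
              x$accounting$absorbed, x$accounting$escaped,
              x$accounting$terminated, x$accounting$total))
  invisible(x)
}

#' Radially averaged profile of a fluence field
#'
#' Bins voxel centres by distance to the source and averages the fluence
#' rate and photon density in each shell.
#'
#' @param field a [mc_fluence()] result.
#' @param r_max outer radius, cm (default: largest inscribed radius).
#' @param dr bin width, cm (default: one voxel).
#' @return Data frame with `r` (bin midpoint), `fluence_rate`,
#'   `photon_density`, `n_voxels`.
#' @export
radial_profile <- function(field, r_max = NULL, dr = NULL) {
  stopifnot(inherits(field, "pdt_fluence"))
  ph <- field$phantom
  d <- dim(ph$labels)
  h <- ph$voxel_cm
  if (is.null(dr)) dr <- h
  if (is.null(r_max))
    r_max <- min(c(ph$source_cm, d * h - ph$source_cm))
  cx <- (seq_len(d[1]) - 0.5) * h - ph$source_cm[1]
  cy <- (seq_len(d[2]) - 0.5) * h - ph$source_cm[2]
  cz <- (seq_len(d[3]) - 0.5) * h - ph$source_cm[3]
  r <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  keep <- r <= r_max
  bin <- floor(r[keep] / dr)
  fr <- tapply(field$fluence_rate[keep], bin, mean)
  pd <- tapply(field$photon_density[keep], bin, mean)
  n <- tapply(rep(1L, sum(keep)), bin, length)
  data.frame(r = (as.numeric(names(fr)) + 0.5) * dr,
             fluence_rate = as.numeric(fr),
             photon_density = as.numeric(pd),
             n_voxels = as.integer(n))
}

#' Dose-volume histogram of a fluence field
#'
#' Cumulative tissue volume receiving at least a given absorbed-photon areal
#' density. `V(0)` equals the total phantom volume and the curve is
#' non-increasing.
#'
#' @param field a [mc_fluence()] result.
#' @param phantom optional phantom to check congruence against.
#' @param what which per-voxel quantity to histogram
#'   (`"photon_density"` or `"fluence_rate"`).
#' @return Object of class `pdt_dvh`: data frame `dose`, `volume_cm3`.
#' @export
dose_volume_histogram <- function(field, phantom = NULL,
                                  what = c("photon_density", "fluence_rate")) {
  stopifnot(inherits(field, "pdt_fluence"))
  what <- match.arg(what)
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "pdt_phantom"))
    if (!identical(dim(phantom$labels), dim(field$phantom$labels)) ||
        phantom$voxel_cm != field$phantom$voxel_cm)
      stop("field and phantom grids do not match", call. = FALSE)
  }
  v <- field$phantom$voxel_cm^3
  x <- sort(as.numeric(field[[what]]))
  n <- length(x)
  dose <- c(0, unique(x))
  # volume with dose >= d: count of voxels at or above each threshold
  vol <- vapply(dose, function(d) (n - sum(x < d)) * v, 0)
  structure(list(dvh = data.frame(dose = dose, volume_cm3 = vol),
                 what = what, total_volume_cm3 = n * v),
            class = "pdt_dvh")
}

#' @export
print.pdt_dvh <- function(x, ...) {
  cat(sprintf("Dose-volume histogram over %s: total volume %.4g cm^3, dose range [%.3g, %.3g]\n",
              x$what, x$total_volume_cm3, min(x$dvh$dose), max(x$dvh$dose)))
  invisible(x)
}

#' @export
plot.pdt_dvh <- function(x, ...) {
  plot(x$dvh$dose, x$dvh$volume_cm3, type = "s",
       xlab = paste(x$what, if (x$what == "photon_density") "[hv cm^-2]" else "[W cm^-2]"),
       ylab = "volume receiving >= dose [cm^3]", ...)
  invisible(x)
}
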