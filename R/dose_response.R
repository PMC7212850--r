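# In vitro dose-response: plate normalization, 4PL fitting on log10
# concentration, and LD50 expressed in absorbed photons per cm^3.

#' Normalize a plate of viability readings to percent kill
#'
#' Anchors each well between the plate's own solvent (0% kill) and cell-death
#' (100% kill) controls:
#' kill% = 100 * (1 - (viability - mean_kill) / (mean_solvent - mean_kill)),
#' clipped to \[0, 100\].
#'
#' @param records data frame with columns `well_id`, `concentration`
#'   (molar, administered agent), `viability` (fraction relative to solvent
#'   control) and `control_flag` (`"solvent"`, `"kill"` or `"treated"`).
#' @return The treated rows with an added `kill_pct` column.
#' @export
normalize_plate <- function(records) {
  req <- c("well_id", "concentration", "viability", "control_flag")
  if (!all(req %in% names(records)))
    stop("plate records need columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(records$viability < 0 | records$viability > 1.2))
    stop("viability outside [0, 1.2]: corrupt plate?", call. = FALSE)
  if (any(records$concentration < 0))
    stop("negative concentration", call. = FALSE)
  solv <- records$viability[records$control_flag == "solvent"]
  kill <- records$viability[records$control_flag == "kill"]
  if (length(solv) < 1L || length(kill) < 1L)
    stop("plate must contain at least one solvent and one kill control", call. = FALSE)
  ms <- mean(solv); mk <- mean(kill)
  if (ms <= mk)
    stop("solvent-control mean (", signif(ms, 3), ") <= kill-control mean (",
         signif(mk, 3), "): controls unusable", call. = FALSE)
  out <- records[records$control_flag == "treated", , drop = FALSE]
  kp <- 100 * (1 - (out$viability - mk) / (ms - mk))
  out$kill_pct <- pmin(100, pmax(0, kp))
  out
}

#' Effective active-photosensitizer concentration
#'
#' Divides the administered precursor concentration by the precursor
#' stoichiometry, assuming complete conversion (8 ALA per protoporphyrin IX;
#' identity for agents given in active form).
#'
#' @param administered molar concentration administered, >= 0.
#' @param ps a [photosensitizer()].
#' @return Molar concentration of active photosensitizer.
#' @export
effective_ps_concentration <- function(administered, ps) {
  stopifnot(inherits(ps, "pdt_ps"))
  if (any(!is.finite(administered)) || any(administered < 0))
    stop("'administered' must be non-negative", call. = FALSE)
  administered / ps$precursor_ratio
}

# 4PL on log10 concentration, increasing in dose:
# kill = bottom + (top - bottom) / (1 + 10^(slope * (log_ld50 - logc)))
.fourpl <- function(logc, bottom, top, log_ld50, slope) {
  bottom + (top - bottom) / (1 + 10^(slope * (log_ld50 - logc)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits percent kill against log10 administered concentration with free
#' asymptotes (assay floors and ceilings drift, so 0/100 are not imposed).
#' LD50 is the concentration at the midpoint between the fitted asymptotes.
#' Zero-concentration wells take part in plate normalization but are excluded
#' here (no log dose). When a light schedule and photosensitizer are supplied
#' the LD50 is also expressed in absorbed photons per cm^3, with a
#' first-order delta-method standard deviation.
#'
#' @param records either raw plate records (see [normalize_plate()]) or a
#'   data frame already carrying `concentration` and `kill_pct`.
#' @param ps optional [photosensitizer()]; enables precursor correction and
#'   photon-unit LD50.
#' @param source optional flat-field [light_source()]; with `ps`, attaches
#'   `ld50_photon_density`.
#' @param use_ln10 passed to [ps_absorption_coefficient()].
#' @param start optional named list overriding self-start values
#'   (`bottom`, `top`, `log_ld50`, `slope`).
#' @return Object of class `pdt_drfit`: fitted parameters, covariance, LD50
#'   in molar and (if a schedule is attached) absorbed-photon units.
#' @export
#' @examples
#' ru <- default_photosensitizers()$rutherrin
#' sc <- scenario_config(seed = 7)
#' plate <- gen_plate(sc, agent = "rutherrin")
#' fit <- fit_dose_response(plate, ps = ru, source = default_light_sources()$well_530)
#' fit
fit_dose_response <- function(records, ps = NULL, source = NULL,
                              use_ln10 = TRUE, start = NULL) {
  if (!"kill_pct" %in% names(records)) records <- normalize_plate(records)
  d <- records[records$concentration > 0, , drop = FALSE]
  if (length(unique(d$concentration)) < 4L)
    stop("need >= 4 distinct non-zero concentrations to fit a 4PL", call. = FALSE)
  d$logc <- log10(d$concentration)
  if (diff(range(tapply(d$kill_pct, d$logc, mean))) < 1e-8)
    stop("degenerate data: kill% flat across concentrations", call. = FALSE)

  mk <- tapply(d$kill_pct, d$logc, mean)
  lc <- as.numeric(names(mk))
  s0 <- list(bottom = max(0, min(mk)), top = min(100, max(mk)),
             log_ld50 = lc[which.min(abs(mk - (min(mk) + max(mk)) / 2))],
             slope = 1)
  if (!is.null(start)) s0[names(start)] <- start

  fit <- tryCatch(
    minpack.lm::nlsLM(
      kill_pct ~ .fourpl(logc, bottom, top, log_ld50, slope),
      data = d, start = s0,
      lower = c(bottom = -20, top = 0, log_ld50 = min(d$logc) - 3, slope = 0.01),
      upper = c(bottom = 100, top = 140, log_ld50 = max(d$logc) + 3, slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("4PL fit did not converge: ", conditionMessage(e), call. = FALSE))

  est <- coef(fit)
  if (est[["bottom"]] >= est[["top"]])
    stop("degenerate fit: bottom asymptote >= top asymptote", call. = FALSE)
  covm <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 4, 4))
  ld50_conc <- 10^est[["log_ld50"]]
  # sd on the raw-concentration scale via d C / d log10 C = ln(10) C
  sd_logld50 <- sqrt(covm["log_ld50", "log_ld50"])
  ld50_sd <- log(10) * ld50_conc * sd_logld50

  out <- structure(list(
    parameters = est, covariance = covm,
    ld50_concentration = ld50_conc, ld50_concentration_sd = ld50_sd,
    hill_slope = est[["slope"]],
    bottom = est[["bottom"]], top = est[["top"]],
    data = d[, c("concentration", "logc", "kill_pct")],
    nls = fit, ps = ps, source = source, use_ln10 = use_ln10,
    ld50_photon_density = NULL, ld50_photon_density_sd = NULL
  ), class = "pdt_drfit")

  if (!is.null(ps) && !is.null(source)) {
    pd <- ld50_in_photons(out, source, ps, use_ln10 = use_ln10)
    out$ld50_photon_density <- pd
    # photon-unit LD50 is linear in the molar LD50, so the delta-method sd
    # carries the same relative error
    out$ld50_photon_density_sd <- pd * (ld50_sd / ld50_conc)
  }
  out
}

#' Express a fitted LD50 in absorbed photons per cm^3
#'
#' Chains the photon conversions: areal photon density of the delivered
#' exposure times the photosensitizer absorption coefficient at the effective
#' (precursor-corrected) LD50 concentration.
#'
#' @param fit a `pdt_drfit` (or a bare molar LD50).
#' @param source flat-field [light_source()].
#' @param ps [photosensitizer()].
#' @param use_ln10 see [ps_absorption_coefficient()].
#' @return LD50 in hv cm^-3.
#' @export
ld50_in_photons <- function(fit, source, ps, use_ln10 = TRUE) {
  stopifnot(inherits(source, "pdt_light"), inherits(ps, "pdt_ps"))
  ld50 <- if (inherits(fit, "pdt_drfit")) fit$ld50_concentration else fit
  areal <- radiant_exposure_to_photon_density(source_exposure(source),
                                              source$wavelength)
  ceff <- effective_ps_concentration(ld50, ps)
  absorbed_photon_density(areal, ps_absorption_coefficient(ps, ceff, use_ln10))
}

#' Invert a published absorbed-photon LD50 to an implied concentration
#'
#' Given an LD50 printed in hv cm^-3 and the light schedule it was measured
#' under, returns the administered concentration it implies:
#' C = ratio * LD50_hv / (areal_density * ln(10) * epsilon). Useful when a
#' study prints photon-unit LD50s but not the underlying concentrations.
#'
#' @param ld50_photons hv cm^-3.
#' @param source flat-field [light_source()].
#' @param ps [photosensitizer()].
#' @param use_ln10 see [ps_absorption_coefficient()].
#' @return Implied administered concentration, molar.
#' @export
#' @examples
#' ru <- default_photosensitizers()$rutherrin
#' implied_ld50_concentration(2.388e16, default_light_sources()$well_530, ru)
implied_ld50_concentration <- function(ld50_photons, source, ps,
                                       use_ln10 = TRUE) {
  stopifnot(inherits(source, "pdt_light"), inherits(ps, "pdt_ps"))
  if (any(ld50_photons <= 0)) stop("'ld50_photons' must be positive", call. = FALSE)
  areal <- radiant_exposure_to_photon_density(source_exposure(source),
                                              source$wavelength)
  fac <- if (isTRUE(use_ln10)) log(10) else 1
  ps$precursor_ratio * ld50_photons / (areal * fac * ps$epsilon)
}

#' @export
print.pdt_drfit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  LD50: %.4g M (sd %.2g M)\n",
              x$ld50_concentration, x$ld50_concentration_sd))
  cat(sprintf("  Hill slope: %.3g   asymptotes: %.3g / %.3g %% kill\n",
              x$hill_slope, x$bottom, x$top))
  if (!is.null(x$ld50_photon_density))
    cat(sprintf("  LD50 in absorbed photons: %.4g hv cm^-3 (sd %.2g)\n",
                x$ld50_photon_density, x$ld50_photon_density_sd))
  invisible(x)
}

#' @export
summary.pdt_drfit <- function(object, ...) {
  s <- summary(object$nls)
  cat("Four-parameter logistic fit on log10 concentration\n\n")
  print(s$coefficients)
  cat(sprintf("\nLD50 = %.4g M, residual sd = %.3g %% kill on %d wells\n",
              object$ld50_concentration, s$sigma, nrow(object$data)))
  if (!is.null(object$ld50_photon_density))
    cat(sprintf("LD50 = %.4g hv cm^-3 under the attached light schedule\n",
                object$ld50_photon_density))
  invisible(s)
}

#' @export
coef.pdt_drfit <- function(object, ...) object$parameters

#' @export
vcov.pdt_drfit <- function(object, ...) object$covariance

#' @export
predict.pdt_drfit <- function(object, newdata = NULL, ...) {
  lc <- if (is.null(newdata)) object$data$logc else log10(newdata$concentration)
  p <- object$parameters
  .fourpl(lc, p[["bottom"]], p[["top"]], p[["log_ld50"]], p[["slope"]])
}

#' @export
residuals.pdt_drfit <- function(object, ...)
  object$data$kill_pct - predict(object)

#' @export
confint.pdt_drfit <- function(object, parm = "ld50", level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  l <- object$parameters[["log_ld50"]]
  s <- sqrt(object$covariance["log_ld50", "log_ld50"])
  ci <- 10^(l + c(-1, 1) * z * s)
  setNames(ci, c("lower", "upper"))
}

#' @export
plot.pdt_drfit <- function(x, n = 200, ...) {
  d <- x$data
  plot(d$logc, d$kill_pct, xlab = "log10 concentration [M]",
       ylab = "cell kill [%]", ylim = c(0, 105), ...)
  lc <- seq(min(d$logc), max(d$logc), length.out = n)
  p <- x$parameters
  lines(lc, .fourpl(lc, p[["bottom"]], p[["top"]], p[["log_ld50"]], p[["slope"]]))
  abline(v = p[["log_ld50"]], lty = 3)
  invisible(x)
}

#' Simulate plates from a fitted dose-response model
#'
#' Draws new synthetic plates whose true curve is the fitted one, useful for
#' parametric-bootstrap uncertainty on the LD50.
#'
#' @param object a `pdt_drfit`.
#' @param nsim number of plates.
#' @param seed optional seed.
#' @param noise_sd Gaussian viability noise, fraction (default residual-based).
#' @param ... unused.
#' @return List of data frames with `concentration` and `kill_pct`.
#' @export
simulate.pdt_drfit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- sd(residuals(object)) / 100
  mu <- predict(object)
  lapply(seq_len(nsim), function(i) {
    k <- pmin(100, pmax(0, mu + 100 * rnorm(length(mu), 0, noise_sd)))
    data.frame(concentration = object$data$concentration, kill_pct = k)
  })
}

#' Read plate records from CSV
#'
#' Expects columns `well_id`, `agent`, `concentration_M`, `viability`,
#' `control_flag`.
#'
#' @param path CSV file.
#' @param agent optional agent name to filter on.
#' @return Data frame in [normalize_plate()] layout.
#' @export
read_plate_csv <- function(path, agent = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("well_id", "agent", "concentration_M", "viability", "control_flag")
  if (!all(req %in% names(d)))
    stop("plate CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (!is.null(agent)) d <- d[d$agent == agent, , drop = FALSE]
  data.frame(well_id = d$well_id, agent = d$agent,
             concentration = d$concentration_M,
             viability = d$viability, control_flag = d$control_flag,
             stringsAsFactors = FALSE)
}
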