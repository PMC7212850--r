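# ICP-MS biodistribution: ruthenium readouts to TLD1433 tissue
# concentrations and tumor-to-normal specific uptake ratios.

.TLD1433_MW <- 1007      # g/mol
.RU_ATOMIC_WEIGHT <- 101.07   # standard atomic weight
.RU101_ISOTOPE_MASS <- 100.90576 # for isotope-specific sensitivity checks

#' Convert an ICP-MS ruthenium readout to TLD1433 mass
#'
#' Ruthenium mass is ppb (ug/L) times the acid digest volume; TLD1433 mass is
#' the ruthenium mass scaled by the molecular-weight ratio MW_TLD1433 / AM_Ru
#' (one ruthenium atom per TLD1433 molecule).
#'
#' @param ru_ppb ruthenium concentration in the digest, ug/L, >= 0.
#' @param digest_volume_L digest volume, L (default 0.002, i.e. 2 mL acid).
#' @param ru_atomic_mass g/mol; standard atomic weight 101.07 by default,
#'   switch to the 101Ru isotope mass 100.90576 if the readout is
#'   isotope-specific.
#' @param mw_tld1433 g/mol (default 1007).
#' @return TLD1433 mass in ug.
#' @export
#' @examples
#' ru_to_tld1433_mass(100, 0.002) # 0.2 ug Ru -> ~1.99 ug TLD1433
ru_to_tld1433_mass <- function(ru_ppb, digest_volume_L = 0.002,
                               ru_atomic_mass = .RU_ATOMIC_WEIGHT,
                               mw_tld1433 = .TLD1433_MW) {
  if (any(!is.finite(ru_ppb)) || any(ru_ppb < 0))
    stop("'ru_ppb' must be non-negative", call. = FALSE)
  if (any(digest_volume_L < 0)) stop("'digest_volume_L' must be >= 0", call. = FALSE)
  ru_mass_ug <- ru_ppb * digest_volume_L
  ru_mass_ug * mw_tld1433 / ru_atomic_mass
}

#' Tissue photosensitizer concentration
#'
#' Mass-normalised (ug/g) and molar concentration, assuming tissue density
#' 1 g/mL for the volume conversion.
#'
#' @param mass_ug photosensitizer mass in the sample, ug.
#' @param tissue_mass_g fresh tissue mass, g, > 0.
#' @param mw g/mol (default TLD1433, 1007).
#' @param density_g_ml tissue density (default 1).
#' @return List with `ug_per_g` and `molar`.
#' @export
tissue_concentration <- function(mass_ug, tissue_mass_g, mw = .TLD1433_MW,
                                 density_g_ml = 1) {
  if (any(!is.finite(tissue_mass_g)) || any(tissue_mass_g <= 0))
    stop("'tissue_mass_g' must be positive", call. = FALSE)
  if (any(mass_ug < 0)) stop("'mass_ug' must be >= 0", call. = FALSE)
  ug_per_g <- mass_ug / tissue_mass_g
  mol <- mass_ug * 1e-6 / mw
  vol_L <- tissue_mass_g / density_g_ml * 1e-3
  list(ug_per_g = ug_per_g, molar = mol / vol_L)
}

#' Convert ug/g tissue concentration to molar
#'
#' @param ug_per_g mass concentration.
#' @param mw molecular weight, g/mol.
#' @param density_g_ml tissue density (default 1).
#' @return Molar concentration.
#' @export
ug_per_g_to_molar <- function(ug_per_g, mw, density_g_ml = 1) {
  ug_per_g * density_g_ml / mw * 1e-3
}

#' Process raw ICP-MS uptake samples
#'
#' Adds TLD1433 mass and tissue concentration columns to a raw sample table.
#'
#' @param samples data frame with columns `animal`, `tissue`, `timepoint_h`,
#'   `dose_mg_per_kg`, `ru_ppb`, `tissue_mass_g` (optional `digest_volume_L`,
#'   default 0.002).
#' @param ... passed to [ru_to_tld1433_mass()].
#' @return Input with `tld1433_ug`, `conc_ug_per_g`, `conc_M` appended.
#' @export
process_uptake <- function(samples, ...) {
  req <- c("animal", "tissue", "timepoint_h", "dose_mg_per_kg", "ru_ppb",
           "tissue_mass_g")
  if (!all(req %in% names(samples)))
    stop("uptake table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  vol <- if ("digest_volume_L" %in% names(samples)) samples$digest_volume_L else 0.002
  m <- ru_to_tld1433_mass(samples$ru_ppb, vol, ...)
  cc <- tissue_concentration(m, samples$tissue_mass_g)
  samples$tld1433_ug <- m
  samples$conc_ug_per_g <- cc$ug_per_g
  samples$conc_M <- cc$molar
  samples
}

#' Specific uptake ratio between a target and a reference tissue
#'
#' Ratio of group mean concentrations (target / reference) within a timepoint
#' and dose group. A reference group whose concentrations are all zero is the
#' "complete absence" case: uptake in the reference tissue was below
#' detection, the ratio is unbounded, and a sentinel (`status = "absent"`) is
#' returned instead of a number. Groups of n = 1 are flagged, not rejected.
#' Uncertainty is a first-order delta-method standard error on the ratio of
#' means.
#'
#' @param samples output of [process_uptake()] (raw tables are processed on
#'   the fly).
#' @param target,reference tissue labels.
#' @param timepoint_h,dose_mg_per_kg group selectors (omit to pool).
#' @param value which concentration column to ratio
#'   (`"conc_ug_per_g"` or `"conc_M"`; the ratio is identical).
#' @return Object of class `pdt_sur`.
#' @export
compute_sur <- function(samples, target = "tumor",
                        reference = "contralateral_brain",
                        timepoint_h = NULL, dose_mg_per_kg = NULL,
                        value = c("conc_ug_per_g", "conc_M")) {
  value <- match.arg(value)
  if (!value %in% names(samples)) samples <- process_uptake(samples)
  d <- samples
  if (!is.null(timepoint_h)) d <- d[d$timepoint_h %in% timepoint_h, , drop = FALSE]
  if (!is.null(dose_mg_per_kg)) d <- d[d$dose_mg_per_kg %in% dose_mg_per_kg, , drop = FALSE]
  tg <- d[d$tissue == target, value]
  rf <- d[d$tissue == reference, value]
  if (length(tg) == 0L)
    stop("no samples in target group '", target, "'", call. = FALSE)
  res <- list(target = target, reference = reference,
              timepoint_h = timepoint_h, dose_mg_per_kg = dose_mg_per_kg,
              n_target = length(tg), n_reference = length(rf),
              mean_target = mean(tg), mean_reference = if (length(rf)) mean(rf) else NA_real_,
              low_n = length(tg) < 2L || length(rf) < 2L)
  if (length(rf) == 0L) {
    res$status <- "no_reference"; res$ratio <- NA_real_; res$se <- NA_real_
  } else if (mean(rf) == 0) {
    res$status <- "absent"; res$ratio <- NA_real_; res$se <- NA_real_
  } else {
    res$status <- "ok"
    res$ratio <- mean(tg) / mean(rf)
    # delta method on a ratio of independent group means
    vt <- if (length(tg) > 1) var(tg) / length(tg) else NA_real_
    vr <- if (length(rf) > 1) var(rf) / length(rf) else NA_real_
    res$se <- if (is.na(vt) || is.na(vr)) NA_real_ else
      res$ratio * sqrt(vt / mean(tg)^2 + vr / mean(rf)^2)
  }
  structure(res, class = "pdt_sur")
}

#' @export
print.pdt_sur <- function(x, ...) {
  sel <- c(if (!is.null(x$timepoint_h)) sprintf("%g h", x$timepoint_h),
           if (!is.null(x$dose_mg_per_kg)) sprintf("%g mg/kg", x$dose_mg_per_kg))
  cat(sprintf("SUR %s / %s%s: ", x$target, x$reference,
              if (length(sel)) paste0(" (", paste(sel, collapse = ", "), ")") else ""))
  if (x$status == "absent")
    cat("reference uptake absent (below detection); ratio unbounded\n")
  else if (x$status == "no_reference")
    cat("no reference samples\n")
  else
    cat(sprintf("%.3g (se %.2g), n = %d/%d%s\n", x$ratio, x$se,
                x$n_target, x$n_reference,
                if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' SUR table across the uptake design
#'
#' @param samples processed or raw uptake table.
#' @param target,reference tissue labels.
#' @return Data frame, one row per timepoint x dose cell.
#' @export
sur_table <- function(samples, target = "tumor",
                      reference = "contralateral_brain") {
  if (!"conc_ug_per_g" %in% names(samples)) samples <- process_uptake(samples)
  cells <- unique(samples[samples$tissue == target,
                          c("timepoint_h", "dose_mg_per_kg")])
  cells <- cells[order(cells$timepoint_h, cells$dose_mg_per_kg), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    s <- compute_sur(samples, target, reference,
                     cells$timepoint_h[i], cells$dose_mg_per_kg[i])
    data.frame(timepoint_h = cells$timepoint_h[i],
               dose_mg_per_kg = cells$dose_mg_per_kg[i],
               sur = s$ratio, se = s$se, status = s$status,
               n_target = s$n_target, n_reference = s$n_reference)
  })
  do.call(rbind, rows)
}

#' Read ICP-MS uptake samples from CSV
#'
#' Expects columns `animal`, `tissue`, `timepoint_h`, `dose_mg_per_kg`,
#' `ru_ppb`, `tissue_mass_g`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_uptake_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal", "tissue", "timepoint_h", "dose_mg_per_kg", "ru_ppb",
           "tissue_mass_g")
  if (!all(req %in% names(d)))
    stop("uptake CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  d
}
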