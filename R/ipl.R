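#' Effective PSII quantum efficiency
#'
#' PhiPSII = (Fm' - Fs) / Fm' from light-adapted steady-state (Fs) and
#' maximal (Fm') fluorescence.
#'
#' @param fs steady-state fluorescence (arbitrary units, >= 0)
#' @param fm_prime light-adapted maximal fluorescence (> 0, >= fs)
#' @return PhiPSII in \[0, 1\]
#' @export
phi_psii <- function(fs, fm_prime) {
  if (any(fm_prime <= 0)) stopf("Fm' must be > 0")
  if (any(fs < 0)) stopf("Fs must be >= 0")
  if (any(fs > fm_prime * (1 + 1e-12)))
    stopf("data error: Fs exceeds Fm'")
  (fm_prime - fs) / fm_prime
}

#' Electron transport rate exiting PSII
#'
#' J_PSII = PhiPSII x PPFD x absorptance x f_PSII, with the widely used
#' defaults of 0.84 leaf absorptance and an even (0.5) excitation partition
#' to PSII.
#'
#' @param phi_psii effective PSII quantum efficiency
#' @param ppfd photosynthetic photon flux density (umol m-2 s-1)
#' @param absorptance leaf absorptance
#' @param f_psii fraction of absorbed light reaching PSII
#' @return J_PSII in umol m-2 s-1
#' @export
j_psii <- function(phi_psii, ppfd, absorptance = 0.84, f_psii = 0.5) {
  if (any(phi_psii < 0) || any(ppfd < 0))
    stopf("PhiPSII and PPFD must be >= 0")
  phi_psii * ppfd * absorptance * f_psii
}

#' Temperature-response constants for the K_O / K_C ratio
#'
#' Arrhenius-form parameterization of the RuBisCO Michaelis-Menten constants
#' for photorespiration (K_O, mmol mol-1) and carboxylation (K_C, umol
#' mol-1), after the standard Bernacchi-style values (K_O25 = 278.4 mmol
#' mol-1, E_a 36.38 kJ mol-1; K_C25 = 404.9 umol mol-1, E_a 79.43 kJ mol-1).
#' With K_O in mmol and K_C in umol units the ratio is ~0.69 at 25 deg C,
#' keeping P_KO/KC on the umol m-2 s-1 scale of J_PSII. A `constant` mode
#' fixes the ratio (the downstream linear calibration absorbs any fixed
#' scale).
#'
#' @param ko25,kc25 reference constants at 25 deg C (mmol mol-1, umol mol-1)
#' @param ea_ko,ea_kc activation energies (J mol-1)
#' @param mode `"arrhenius"` (temperature-dependent) or `"constant"`
#' @param ratio fixed ratio used in constant mode (default ko25 / kc25)
#' @return list of class `ko_kc_constants`
#' @export
ko_kc_constants <- function(ko25 = 278.4, kc25 = 404.9, ea_ko = 36380,
                            ea_kc = 79430, mode = c("arrhenius", "constant"),
                            ratio = NULL) {
  mode <- match.arg(mode)
  structure(list(ko25 = ko25, kc25 = kc25, ea_ko = ea_ko, ea_kc = ea_kc,
                 mode = mode, ratio = ratio %||% (ko25 / kc25)),
            class = "ko_kc_constants")
}

#' Ratio of the RuBisCO Michaelis constants at leaf temperature
#'
#' Arrhenius temperature response of K_O / K_C around the 25 deg C reference.
#' Because the carboxylation constant has the larger activation energy the
#' ratio decreases monotonically with leaf temperature. Temperatures outside
#' the 0-50 deg C physiological range are extrapolated with a warning.
#'
#' @param tleaf leaf temperature(s) in deg C
#' @param constants a [ko_kc_constants()]
#' @return dimensionless K_O / K_C ratio(s)
#' @export
ko_kc_ratio <- function(tleaf, constants = ko_kc_constants()) {
  stopifnot(inherits(constants, "ko_kc_constants"))
  if (any(tleaf < 0 | tleaf > 50))
    warnf("leaf temperature outside 0-50 degC: extrapolating the response")
  if (constants$mode == "constant")
    return(rep_len(constants$ratio, length(tleaf)))
  tk <- tleaf + 273.15
  tref <- 298.15
  r_gas <- 8.314
  arrh <- function(k25, ea) k25 * exp(ea * (tk - tref) / (tref * r_gas * tk))
  arrh(constants$ko25, constants$ea_ko) / arrh(constants$kc25, constants$ea_kc)
}

# P_KO/KC = J_PSII x K_O/K_C from the fluorescence fields of a record table
p_ko_kc <- function(records, constants = ko_kc_constants(),
                    absorptance = 0.84, f_psii = 0.5) {
  phi <- phi_psii(records$Fs, records$Fm_prime)
  j <- j_psii(phi, records$PPFD, absorptance, f_psii)
  j * ko_kc_ratio(records$Tleaf, constants)
}

#' Calibrate the photo-assimilation performance index per device
#'
#' For each gas-exchange device: randomly splits the records with measured An
#' into a calibration fraction (default 2/3) and a validation remainder, fits
#' the linear model `An ~ P_KO/KC + (Tleaf - Tair)` by OLS on the calibration
#' set and reports calibration R-squared, validation R-squared and validation
#' RMSE. Devices are calibrated separately because fluorescence and
#' temperature readings carry device-specific internal calibrations.
#'
#' @param records data frame with columns `device`, `Fs`, `Fm_prime`, `PPFD`,
#'   `Tleaf`, `Tair` and `An` (records with missing An are dropped with a
#'   message); >= 10 usable records per device
#' @param split_fraction calibration fraction (default 2/3)
#' @param seed integer seed controlling the random split
#' @param constants a [ko_kc_constants()]
#' @param absorptance,f_psii constants passed to [j_psii()]
#' @return object of class `ipl_calibration`: named list of per-device
#'   models, each with `device`, `coefficients` (b0, b1, b2), `r2_cal`,
#'   `r2_val`, `rmse_val`, `p_values`, `n_cal`, `n_val`, `cal_rows`,
#'   `val_rows`, `constants`, `seed`
#' @export
calibrate_ipl <- function(records, split_fraction = 2 / 3, seed = NULL,
                          constants = ko_kc_constants(), absorptance = 0.84,
                          f_psii = 0.5) {
  if (!"An" %in% names(records)) stopf("calibration records must contain An")
  n_missing <- sum(is.na(records$An))
  if (n_missing > 0) {
    message(sprintf("dropping %d records with missing An", n_missing))
    records <- records[!is.na(records$An), , drop = FALSE]
  }
  if (split_fraction <= 0 || split_fraction >= 1)
    stopf("'split_fraction' must be in (0, 1)")
  devices <- unique(records$device)
  models <- with_seed_opt(seed, {
    lapply(devices, function(dev) {
      rec <- records[records$device == dev, , drop = FALSE]
      if (nrow(rec) < 10)
        stopf("device %s: insufficient data (%d records; need >= 10)", dev,
              nrow(rec))
      rec$p_ko_kc <- p_ko_kc(rec, constants, absorptance, f_psii)
      rec$t_diff <- rec$Tleaf - rec$Tair
      if (sd(rec$p_ko_kc) == 0 || sd(rec$t_diff) == 0)
        stopf("device %s: constant predictor, rank-deficient design", dev)
      n_cal <- max(2L, round(nrow(rec) * split_fraction))
      cal_rows <- sort(sample.int(nrow(rec), n_cal))
      val_rows <- setdiff(seq_len(nrow(rec)), cal_rows)
      fit <- lm(An ~ p_ko_kc + t_diff, data = rec[cal_rows, ])
      pr_cal <- predict(fit)
      pr_val <- predict(fit, newdata = rec[val_rows, ])
      obs_val <- rec$An[val_rows]
      r2 <- function(obs, prd) {
        if (length(obs) < 3 || sd(obs) == 0 || sd(prd) == 0) return(NA_real_)
        cor(obs, prd)^2
      }
      resid_val <- obs_val - pr_val
      structure(list(device = dev,
                     coefficients = setNames(coef(fit), c("b0", "b1", "b2")),
                     r2_cal = r2(rec$An[cal_rows], pr_cal),
                     r2_val = r2(obs_val, pr_val),
                     rmse_val = if (length(val_rows))
                       sqrt(mean(resid_val^2)) else NA_real_,
                     p_values = summary(fit)$coefficients[, 4],
                     conf_int = stats::confint(fit),
                     n_cal = length(cal_rows), n_val = length(val_rows),
                     cal_rows = cal_rows, val_rows = val_rows,
                     constants = constants,
                     absorptance = absorptance, f_psii = f_psii,
                     seed = seed),
                class = "ipl_model")
    })
  })
  structure(setNames(models, devices), class = "ipl_calibration")
}

#' @export
print.ipl_model <- function(x, ...) {
  cat(sprintf(
    "<ipl_model> %s: An = %.3f + %.4f P_KO/KC + %.3f dT | R2cal %.3f R2val %.3f RMSEval %.2f\n",
    x$device, x$coefficients[1], x$coefficients[2], x$coefficients[3],
    x$r2_cal, x$r2_val, x$rmse_val))
  invisible(x)
}

#' @export
print.ipl_calibration <- function(x, ...) {
  for (m in x) print(m)
  invisible(x)
}

#' Predict the photo-assimilation performance index
#'
#' I_PL = b0 + b1 * P_KO/KC + b2 * (Tleaf - Tair) with the coefficients of
#' the record's device. Records are matched to models by the `device` column;
#' an unknown device is an error.
#'
#' @param model an `ipl_calibration` (per-device set) or single `ipl_model`
#' @param records data frame of high-throughput fluorescence records
#'   (`device`, `Fs`, `Fm_prime`, `PPFD`, `Tleaf`, `Tair`)
#' @return numeric vector of I_PL values (umol m-2 s-1), one per record
#' @export
predict_ipl <- function(model, records) {
  if (inherits(model, "ipl_model")) {
    set <- structure(setNames(list(model), model$device),
                     class = "ipl_calibration")
    return(predict_ipl(set, records))
  }
  stopifnot(inherits(model, "ipl_calibration"))
  unknown <- setdiff(unique(records$device), names(model))
  if (length(unknown))
    stopf("no calibrated model for device(s): %s",
          paste(unknown, collapse = ", "))
  out <- numeric(nrow(records))
  for (dev in unique(records$device)) {
    m <- model[[dev]]
    sel <- records$device == dev
    rec <- records[sel, , drop = FALSE]
    p <- p_ko_kc(rec, m$constants, m$absorptance, m$f_psii)
    out[sel] <- m$coefficients[1] + m$coefficients[2] * p +
      m$coefficients[3] * (rec$Tleaf - rec$Tair)
  }
  out
}
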