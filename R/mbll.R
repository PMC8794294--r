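#' Molar extinction coefficients for hemoglobin
#'
#' Published base-10 molar extinction coefficients (Prahl compilation, as
#' used throughout continuous-wave NIRS) for oxy- and deoxyhemoglobin at the
#' two acquisition wavelengths, in cm^-1 per (mol/L). Versioned so analyses
#' can record which table produced their concentrations.
#'
#' @return Tibble with columns `wavelength_nm`, `hbo2`, `hbr` and attribute
#'   `version`.
#' @export
extinction_table <- function() {
  out <- tibble::tibble(
    wavelength_nm = c(690, 830),
    hbo2 = c(276.0, 974.0),
    hbr  = c(2051.96, 693.04)
  )
  attr(out, "version") <- "prahl-1998"
  out
}

ext_matrix <- function(extinction) {
  stopifnot(all(c(690, 830) %in% extinction$wavelength_nm))
  e <- extinction[match(c(690, 830), extinction$wavelength_nm), ]
  m <- rbind(c(e$hbo2[1], e$hbr[1]),
             c(e$hbo2[2], e$hbr[2]))
  if (abs(det(m)) < 1e-12)
    stop("extinction matrix is singular; cannot separate HbO2 from HbR")
  m
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes to optical-density changes and raw
#' intensities for one channel:
#' `dOD(lambda) = (eps_HbO2(lambda) * dHbO2 + eps_HbR(lambda) * dHbR) * d *
#' DPF(lambda) * 1e-6` with concentrations in micromolar, the source-detector
#' separation `d` in cm, and `intensity = baseline * exp(-dOD)`. This is the
#' exact algebraic inverse of [mbll()].
#'
#' @param hbo2,hbr Concentration-change series, micromolar.
#' @param distance_cm Source-detector separation in cm.
#' @param dpf Differential pathlength factors, length-2 `(690, 830)`.
#' @param extinction Extinction table, see [extinction_table()].
#' @param baseline Length-2 baseline intensities `(690, 830)`.
#' @return List with `od` (matrix, columns `w690`, `w830`) and `intensity`
#'   (same shape).
#' @export
forward_mbll <- function(hbo2, hbr, distance_cm, dpf = c(6, 6),
                         extinction = extinction_table(),
                         baseline = c(1, 1)) {
  stopifnot(length(hbo2) == length(hbr), distance_cm > 0, all(dpf > 0))
  E <- ext_matrix(extinction)
  conc <- cbind(hbo2, hbr)
  od <- conc %*% t(E) * 1e-6                 # cm^-1 * (per-uM) * uM
  od[, 1] <- od[, 1] * distance_cm * dpf[1]
  od[, 2] <- od[, 2] * distance_cm * dpf[2]
  colnames(od) <- c("w690", "w830")
  intensity <- cbind(w690 = baseline[1] * exp(-od[, 1]),
                     w830 = baseline[2] * exp(-od[, 2]))
  list(od = od, intensity = intensity)
}

#' Convert optical density to hemoglobin concentration (modified
#' Beer-Lambert law)
#'
#' Solves the per-channel 2x2 linear system relating optical-density changes
#' at 690 and 830 nm to oxy-/deoxyhemoglobin concentration changes, using
#' each channel's source-detector separation and the differential pathlength
#' factor. Total hemoglobin is appended as the exact sum HbO2 + HbR.
#'
#' @param od An optical-density set from [intensity_to_od()] (list with
#'   matrices `w690`, `w830`, `channel_ids`, `fs`, `time_s`).
#' @param montage Montage from [load_montage()] (provides separations).
#' @param dpf Differential pathlength factors `(690, 830)`; default 6.0 both.
#' @param extinction Extinction table.
#' @return A concentration set: list with micromolar matrices `hbo2`, `hbr`,
#'   `hbt` (samples x channels), `channel_ids`, `fs`, `time_s`, and a
#'   `provenance` character vector of applied stages.
#' @export
mbll <- function(od, montage, dpf = c(6, 6),
                 extinction = extinction_table()) {
  stopifnot(all(dpf > 0))
  E <- ext_matrix(extinction)
  Einv <- solve(E)
  d_cm <- channel_distance_cm(montage, od$channel_ids)
  if (any(d_cm <= 0))
    stop("non-positive source-detector distance for channel(s) ",
         paste(od$channel_ids[d_cm <= 0], collapse = ", "))
  # scale OD back to (extinction %*% conc) units, then invert the 2x2 system
  u690 <- sweep(od$w690, 2, d_cm * dpf[1], "/") * 1e6
  u830 <- sweep(od$w830, 2, d_cm * dpf[2], "/") * 1e6
  hbo2 <- Einv[1, 1] * u690 + Einv[1, 2] * u830
  hbr  <- Einv[2, 1] * u690 + Einv[2, 2] * u830
  conc_set(hbo2, hbr, od$channel_ids, od$fs, od$time_s,
           provenance = c(od$provenance, "mbll"))
}

conc_set <- function(hbo2, hbr, channel_ids, fs, time_s, provenance) {
  dimnames(hbo2) <- dimnames(hbr) <- list(NULL, channel_ids)
  list(hbo2 = hbo2, hbr = hbr, hbt = hbo2 + hbr,
       channel_ids = channel_ids, fs = fs, time_s = time_s,
       provenance = provenance)
}
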