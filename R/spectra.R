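#' Wavelength-indexed spectral curve
#'
#' A nonnegative function of wavelength sampled on a strictly increasing
#' grid, linearly interpolated inside its support and zero outside. The
#' same container serves for LED spectral power distributions, leaf
#' reflectance/transmittance, and biological action spectra.
#'
#' @param wavelength_nm strictly increasing wavelengths (nm), length >= 2.
#' @param value nonnegative values (unit depends on role).
#' @return An object of class `spectral_curve`.
#' @export
spectral_curve <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2) stop("a spectral curve needs at least 2 points")
  if (length(value) != length(wavelength_nm)) stop("wavelength/value length mismatch")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(value))) {
    stop("spectral curve contains non-finite entries")
  }
  if (any(diff(wavelength_nm) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(value < 0)) stop("spectral curve values must be nonnegative")
  structure(list(wavelength_nm = wavelength_nm, value = value),
    class = "spectral_curve"
  )
}

#' Evaluate a spectral curve
#'
#' Linear interpolation on the curve's support, zero outside.
#'
#' @param curve a [spectral_curve()].
#' @param wavelength_nm wavelengths (nm) at which to evaluate.
#' @return Numeric vector of values.
#' @export
eval_spectrum <- function(curve, wavelength_nm) {
  stopifnot(inherits(curve, "spectral_curve"))
  stats::approx(curve$wavelength_nm, curve$value,
    xout = wavelength_nm,
    yleft = 0, yright = 0
  )$y
}

#' Read a 2-column spectrum CSV (wavelength nm, value)
#'
#' @param path CSV path; first column wavelength in nm, second the value.
#' @return A [spectral_curve()].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop(sprintf("spectrum CSV '%s' needs two columns", path))
  spectral_curve(d[[1]], d[[2]])
}

#' Trapezoidal band integral of a spectral curve
#'
#' Integrates the linearly interpolated curve over `[lo, hi]` nm, treating
#' the curve as zero outside its support. Used for band-integrating
#' irradiance spectra (e.g. PAR 400-700 nm, UV 280-400 nm).
#'
#' @param curve a [spectral_curve()].
#' @param lo,hi band edges in nm, `lo < hi`.
#' @return The integral (units of value x nm).
#' @export
band_integrate <- function(curve, lo, hi) {
  stopifnot(inherits(curve, "spectral_curve"))
  if (lo >= hi) stop("band_integrate: lo must be < hi")
  w <- curve$wavelength_nm
  if (hi <= w[1] || lo >= w[length(w)]) {
    warning("band does not overlap the curve's support; integral is 0")
    return(0)
  }
  # the curve is zero outside its support, so integrate only over the
  # overlap (the value can step to zero at a support edge; bridging that
  # edge with a trapezoid would be wrong)
  lo <- max(lo, w[1])
  hi <- min(hi, w[length(w)])
  # knots: curve grid clipped to the overlap, plus the overlap edges
  knots <- sort(unique(c(lo, hi, w[w > lo & w < hi])))
  v <- eval_spectrum(curve, knots)
  sum(diff(knots) * (v[-1] + v[-length(v)]) / 2)
}

# J m / mol: N_A * h * c
.na_hc <- 6.02214076e23 * 6.62607015e-34 * 2.99792458e8

#' Photon flux (PPFD) from a spectral irradiance curve
#'
#' Converts spectral irradiance (W m^-2 nm^-1) to photosynthetic photon flux
#' density over a band (default PAR, 400-700 nm): the integral of
#' `spd(lambda) * lambda / (N_A h c)`, expressed in micromol m^-2 s^-1.
#'
#' @param spd a [spectral_curve()] of spectral irradiance (W m^-2 nm^-1).
#' @param lo,hi band edges in nm.
#' @return PPFD in micromol m^-2 s^-1.
#' @export
irradiance_to_ppfd <- function(spd, lo = 400, hi = 700) {
  stopifnot(inherits(spd, "spectral_curve"))
  # weight the curve by lambda (photon energy hc/lambda) then band-integrate
  lam <- spd$wavelength_nm
  photon <- spectral_curve(lam, spd$value * lam * 1e-9 / .na_hc * 1e6)
  suppressWarnings(band_integrate(photon, lo, hi))
}

#' Photon-per-energy factor of a source spectrum
#'
#' Micromoles of photons per joule for band-integrated irradiance of a given
#' source shape: `irradiance_to_ppfd(spd) / band_integrate(spd)`. Multiplying
#' a band irradiance in W m^-2 by this factor yields PPFD.
#'
#' @inheritParams irradiance_to_ppfd
#' @return micromol per J.
#' @export
ppfd_per_watt <- function(spd, lo = 400, hi = 700) {
  e <- suppressWarnings(band_integrate(spd, lo, hi))
  if (e <= 0) stop("source spectrum has no energy in the band")
  irradiance_to_ppfd(spd, lo, hi) / e
}

#' Daily radiant dose from a constant irradiance
#'
#' `irradiance * hours * 3600 / 1000`: a photoperiod at constant irradiance
#' (W m^-2) expressed as kJ m^-2 d^-1.
#'
#' @param irradiance_w_m2 irradiance in W m^-2, >= 0.
#' @param hours_per_day photoperiod in hours, within `[0, 24]`.
#' @return Dose in kJ m^-2 d^-1.
#' @export
daily_dose <- function(irradiance_w_m2, hours_per_day) {
  if (any(irradiance_w_m2 < 0)) stop("irradiance must be nonnegative")
  if (any(hours_per_day < 0 | hours_per_day > 24)) {
    stop("hours_per_day must lie in [0, 24]")
  }
  irradiance_w_m2 * hours_per_day * 3600 / 1000
}

#' Biological action spectrum
#'
#' A [spectral_curve()] normalized to 1 at a stated wavelength (default
#' 300 nm), used to weight UV spectral irradiance into biologically
#' effective dose.
#'
#' @param curve a [spectral_curve()] of relative effectiveness.
#' @param normalization_nm wavelength at which the value must equal 1.
#' @param label provenance label.
#' @return An object of classes `action_spectrum` and `spectral_curve`.
#' @export
action_spectrum <- function(curve, normalization_nm = 300, label = "custom") {
  stopifnot(inherits(curve, "spectral_curve"))
  v <- eval_spectrum(curve, normalization_nm)
  if (abs(v - 1) > 1e-9) {
    stop(sprintf(
      "action spectrum is not normalized: value(%g nm) = %.6g, expected 1",
      normalization_nm, v
    ))
  }
  structure(
    list(
      wavelength_nm = curve$wavelength_nm, value = curve$value,
      normalization_nm = normalization_nm, label = label
    ),
    class = c("action_spectrum", "spectral_curve")
  )
}

#' Generalized plant action spectrum (analytic form)
#'
#' Green's analytic parameterization of the generalized plant damage action
#' spectrum, `(1 - (lambda/313.3)^2) * exp(-(lambda - 300)/31.08)` on
#' 280-313.3 nm and zero above, renormalized here so the value at the
#' normalization wavelength (300 nm) is exactly 1 — the standard weighting
#' for biologically effective UV in plant supplementation work.
#'
#' @param step_nm tabulation step in nm.
#' @return An [action_spectrum()] normalized at 300 nm.
#' @export
gpas_action_spectrum <- function(step_nm = 0.1) {
  lam <- seq(280, 313.3, by = step_nm)
  if (lam[length(lam)] < 313.3) lam <- c(lam, 313.3)
  raw <- function(l) pmax(0, (1 - (l / 313.3)^2)) * exp(-(l - 300) / 31.08)
  v <- raw(lam) / raw(300)
  # extend with explicit zeros so interpolation stays zero above the cutoff
  action_spectrum(
    spectral_curve(c(lam, 313.4, 400), c(v, 0, 0)),
    normalization_nm = 300, label = "generalized plant action spectrum (analytic)"
  )
}

#' Biologically effective UV dose report
#'
#' Weights a UV spectral irradiance distribution by an action spectrum and
#' integrates per sub-band (UV-C below 280 nm — empty for the supported
#' sensor range, UV-B 280-315 nm, UV-A 315-400 nm), converting to daily
#' doses for the given photoperiod. Unweighted band doses are reported
#' alongside.
#'
#' @param spd a [spectral_curve()] of spectral irradiance (W m^-2 nm^-1)
#'   covering 280-400 nm.
#' @param action an [action_spectrum()].
#' @param hours_per_day photoperiod in hours.
#' @return A list of class `dose_report` with elements `unweighted`
#'   (kJ m^-2 d^-1 per band) and `weighted` (`uvc_be`, `uvb_be`, `uva_be`,
#'   `total_be`).
#' @export
biologically_effective <- function(spd, action, hours_per_day = 12) {
  stopifnot(inherits(spd, "spectral_curve"))
  if (!inherits(action, "action_spectrum")) {
    stop("action must be an action_spectrum (normalized weighting curve)")
  }
  lam <- sort(unique(c(spd$wavelength_nm, action$wavelength_nm, 280, 315, 400)))
  lam <- lam[lam >= 280 & lam <= 400]
  weighted <- spectral_curve(lam, eval_spectrum(spd, lam) * eval_spectrum(action, lam))
  band <- function(curve, lo, hi) {
    daily_dose(suppressWarnings(band_integrate(curve, lo, hi)), hours_per_day)
  }
  w <- c(
    uvc_be = 0, # curves are defined on [280, 400]; no UV-C content
    uvb_be = band(weighted, 280, 315),
    uva_be = band(weighted, 315, 400)
  )
  structure(
    list(
      unweighted = c(
        uvb = band(spd, 280, 315), uva = band(spd, 315, 400),
        uv_total = band(spd, 280, 400)
      ),
      weighted = c(w, total_be = sum(w)),
      hours_per_day = hours_per_day,
      action_label = action$label
    ),
    class = "dose_report"
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report> (kJ m^-2 d^-1, photoperiod", x$hours_per_day, "h)\n")
  cat(sprintf(
    "  unweighted: UV-B %.2f  UV-A %.2f  total %.2f\n",
    x$unweighted["uvb"], x$unweighted["uva"], x$unweighted["uv_total"]
  ))
  cat(sprintf(
    "  weighted (%s):\n  UV-C_BE %.2f  UV-B_BE %.2f  UV-A_BE %.2f  total %.2f\n",
    x$action_label, x$weighted["uvc_be"], x$weighted["uvb_be"],
    x$weighted["uva_be"], x$weighted["total_be"]
  ))
  invisible(x)
}

#' Synthetic LED source spectra
#'
#' Stand-ins for measured LED spectra: `spd_uvb_led()` is a Gaussian peaking
#' at 310 nm (sigma 5 nm) typical of narrow-band UV-B LEDs; `spd_rbw_led()`
#' sums blue (450 nm) and red (630 nm) peaks with a broad white phosphor
#' component. Both are scaled so the band-integrated irradiance equals
#' `total_w_m2` over their nominal band (UV 280-400, PAR 400-700).
#'
#' @param total_w_m2 band-integrated irradiance of the returned curve.
#' @return A [spectral_curve()] in W m^-2 nm^-1.
#' @export
spd_uvb_led <- function(total_w_m2 = 1.0) {
  lam <- seq(280, 400, by = 0.5)
  v <- exp(-0.5 * ((lam - 310) / 5)^2)
  s <- spectral_curve(lam, v)
  spectral_curve(lam, v * total_w_m2 / band_integrate(s, 280, 400))
}

#' @rdname spd_uvb_led
#' @export
spd_rbw_led <- function(total_w_m2 = 1.0) {
  lam <- seq(380, 780, by = 1)
  v <- 1.0 * exp(-0.5 * ((lam - 450) / 10)^2) + # blue die
    0.9 * exp(-0.5 * ((lam - 630) / 12)^2) + # red die
    0.45 * exp(-0.5 * ((lam - 560) / 60)^2) # white phosphor hump
  s <- spectral_curve(lam, v)
  spectral_curve(lam, v * total_w_m2 / band_integrate(s, 400, 700))
}
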