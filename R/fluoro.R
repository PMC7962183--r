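#' Chlorophyll-fluorescence quenching protocol
#'
#' The pulse-amplitude protocol assumed by the extraction routines, matching
#' a standard imaging-fluorometer quenching run: a weak measuring light in
#' darkness (5 s) defining Fo, a dark saturating pulse (0.8 s) defining Fm,
#' 17 s of dark relaxation, then actinic light (70 s) during which five
#' saturating pulses probe the light-adapted maxima; the final pulse is
#' taken at the light-adapted steady state (Fm'), with F' the steady-state
#' fluorescence just before it.
#'
#' @param dark_ml_s,dark_pulse_s,relax_s,actinic_s phase durations (s).
#' @param n_light_pulses number of saturating pulses under actinic light.
#' @param pulse_s duration of each light-adapted pulse (s).
#' @param dt sampling interval (s).
#' @return A list of class `chlf_protocol`.
#' @export
chlf_protocol <- function(dark_ml_s = 5, dark_pulse_s = 0.8, relax_s = 17,
                          actinic_s = 70, n_light_pulses = 5, pulse_s = 0.8,
                          dt = 0.05) {
  stopifnot(dark_ml_s > 0, dark_pulse_s > 0, actinic_s > 0, n_light_pulses >= 1)
  structure(as.list(environment()), class = "chlf_protocol")
}

phase_table <- function(p) {
  t0 <- 0
  rows <- list()
  add <- function(phase, dur) {
    rows[[length(rows) + 1L]] <<- data.frame(
      phase = phase, start = t0, end = t0 + dur, stringsAsFactors = FALSE
    )
    t0 <<- t0 + dur
  }
  add("dark_ml", p$dark_ml_s)
  add("dark_pulse", p$dark_pulse_s)
  add("relax", p$relax_s)
  # pulses evenly spread over the actinic period, the last one at its end
  gap <- (p$actinic_s - p$n_light_pulses * p$pulse_s) / p$n_light_pulses
  for (i in seq_len(p$n_light_pulses)) {
    add("actinic", gap)
    add(sprintf("light_pulse_%d", i), p$pulse_s)
  }
  do.call(rbind, rows)
}

#' Simulate a fluorescence trace
#'
#' Generates a protocol-timed 1-D fluorescence trace (the mean-ROI signal an
#' imaging fluorometer reduces to) whose underlying plateaus are the given
#' true signals, plus i.i.d. Gaussian noise. Induction/relaxation kinetics
#' are rendered as exponential approaches so the trace looks like a real
#' quenching run; the plateau values are exact at the sampling windows used
#' by [extract_signals()].
#'
#' @param f_o,f_m,f_prime,f_m_prime true signal levels (arbitrary units);
#'   must satisfy `f_m >= f_o > 0`, `f_m_prime >= f_prime > 0`.
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param seed integer seed (uses R's RNG).
#' @param protocol a [chlf_protocol()].
#' @return A `fluorescence_trace`: data frame with `time_s`, `f`, `phase`.
#' @export
simulate_trace <- function(f_o, f_m, f_prime, f_m_prime, sigma = 0,
                           seed = 1, protocol = chlf_protocol()) {
  if (sigma < 0) stop("noise sigma must be nonnegative")
  if (!(f_m >= f_o && f_o > 0)) stop("invalid parameters: need f_m >= f_o > 0")
  if (!(f_m_prime >= f_prime && f_prime > 0)) {
    stop("invalid parameters: need f_m_prime >= f_prime > 0")
  }
  set.seed(seed)
  ph <- phase_table(protocol)
  n_pulse <- protocol$n_light_pulses
  rows <- list()
  actinic_seen <- 0L
  for (i in seq_len(nrow(ph))) {
    tt <- seq(ph$start[i], ph$end[i], by = protocol$dt)
    tt <- tt[tt < ph$end[i]]
    if (!length(tt)) tt <- ph$start[i]
    phase <- ph$phase[i]
    rel <- (tt - ph$start[i]) / max(ph$end[i] - ph$start[i], 1e-9)
    f <- if (phase == "dark_ml") {
      rep(f_o, length(tt))
    } else if (phase == "dark_pulse") {
      f_o + (f_m - f_o) * pmin(1, rel / 0.3) # fast rise to Fm
    } else if (phase == "relax") {
      f_m - (f_m - f_o) * pmin(1, rel / 0.2)
    } else if (phase == "actinic") {
      actinic_seen <- actinic_seen + 1L
      if (actinic_seen == 1L) {
        # induction spike then linear settle to steady-state F' (exact from
        # 60% of the window onward, so the pre-pulse sampling window is flat)
        peak <- f_prime + 0.35 * (f_m - f_prime)
        peak + (f_prime - peak) * pmin(1, rel / 0.6)
      } else {
        rep(f_prime, length(tt))
      }
    } else { # light pulses: maxima relax from near Fm to Fm'
      k <- as.integer(sub("light_pulse_", "", phase))
      top_first <- f_m_prime + 0.8 * (f_m - f_m_prime)
      top <- if (n_pulse == 1) f_m_prime else {
        top_first + (f_m_prime - top_first) * (k - 1) / (n_pulse - 1)
      }
      f_prime + (top - f_prime) * pmin(1, rel / 0.3)
    }
    rows[[i]] <- data.frame(time_s = tt, f = f, phase = phase,
                            stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, rows)
  if (sigma > 0) tr$f <- tr$f + stats::rnorm(nrow(tr), 0, sigma)
  tr$f <- pmax(tr$f, 1e-9) # fluorescence is positive
  class(tr) <- c("fluorescence_trace", "data.frame")
  tr
}

#' Extract the four basic fluorescence signals from a trace
#'
#' `f_o` is the mean over the dark measuring-light window; `f_m` and
#' `f_m_prime` are the saturated maxima of the dark and of the final
#' light-adapted pulse, estimated as the mean over the second half of each
#' pulse window (the fluorescence rise saturates well before then, and
#' averaging the plateau keeps the estimate unbiased under measurement
#' noise, unlike a literal pointwise maximum); `f_prime` is the
#' steady-state level immediately before the final pulse (mean of the last
#' 10% of the preceding actinic window).
#'
#' @param tr a `fluorescence_trace` (data frame with `time_s`, `f`,
#'   `phase`).
#' @return Named list `f_o`, `f_m`, `f_prime`, `f_m_prime`.
#' @export
extract_signals <- function(tr) {
  stopifnot(is.data.frame(tr), all(c("time_s", "f", "phase") %in% names(tr)))
  if (any(tr$f <= 0)) stop("fluorescence must be positive everywhere")
  if (is.unsorted(tr$time_s)) stop("trace times must be ordered")
  need_phase <- function(p, label) {
    d <- tr[tr$phase == p, ]
    if (!nrow(d)) stop(sprintf("protocol error: missing %s phase ('%s')", label, p))
    d
  }
  dark_ml <- need_phase("dark_ml", "dark measuring-light")
  dark_pulse <- need_phase("dark_pulse", "dark saturating-pulse")
  pulses <- grep("^light_pulse_", unique(tr$phase), value = TRUE)
  if (!length(pulses)) stop("protocol error: missing light-adapted pulse phase ('light_pulse')")
  need_phase("actinic", "actinic")
  last_pulse <- pulses[which.max(as.integer(sub("light_pulse_", "", pulses)))]
  pl <- tr[tr$phase == last_pulse, ]
  before <- tr[tr$phase == "actinic" & tr$time_s < min(pl$time_s), ]
  if (!nrow(before)) stop("protocol error: missing actinic phase before the final pulse")
  tail_win <- before[before$time_s >= stats::quantile(before$time_s, 0.9), ]
  plateau <- function(d) {
    mid <- min(d$time_s) + 0.5 * (max(d$time_s) - min(d$time_s))
    mean(d$f[d$time_s >= mid])
  }
  list(
    f_o = mean(dark_ml$f),
    f_m = plateau(dark_pulse),
    f_prime = mean(tail_win$f),
    f_m_prime = plateau(pl)
  )
}

#' Quenching parameters from the four basic signals
#'
#' The standard ratios: maximum quantum yield of PSII
#' `Fv/Fm = (Fm - Fo)/Fm`, nonphotochemical quenching
#' `NPQ = (Fm - Fm')/Fm'`, and PSII operating efficiency
#' `PhiPSII = (Fm' - F')/Fm'`.
#'
#' @param f_o,f_m,f_prime,f_m_prime basic signals, all positive,
#'   `f_m >= f_o`.
#' @return Named list with the four inputs and `fv_fm`, `npq`, `phi_psii`.
#' @export
quench_params <- function(f_o, f_m, f_prime, f_m_prime) {
  vals <- c(f_o = f_o, f_m = f_m, f_prime = f_prime, f_m_prime = f_m_prime)
  if (any(vals <= 0)) stop("domain error: all fluorescence signals must be positive")
  if (f_m < f_o) stop("domain error: f_m must be >= f_o")
  list(
    f_o = f_o, f_m = f_m, f_prime = f_prime, f_m_prime = f_m_prime,
    fv_fm = (f_m - f_o) / f_m,
    npq = (f_m - f_m_prime) / f_m_prime,
    phi_psii = (f_m_prime - f_prime) / f_m_prime
  )
}

#' Quenching analysis of a trace
#'
#' Convenience wrapper: [extract_signals()] then [quench_params()].
#'
#' @param tr a `fluorescence_trace`.
#' @return See [quench_params()].
#' @export
quench_analysis <- function(tr) {
  s <- extract_signals(tr)
  quench_params(s$f_o, s$f_m, s$f_prime, s$f_m_prime)
}
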