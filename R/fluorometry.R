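#' Fluorescence trace
#'
#' Time-stamped single- or dual-channel fluorometer trace. Channels are named
#' by their excitation/emission pair, e.g. `"350/450"` (NAD(P)H), `"576/590"`
#' and `"551/590"` (ratiometric TMRM).
#'
#' @param time_s time stamps, seconds, strictly increasing.
#' @param channels named list of equal-length intensity vectors.
#' @param events optional [event_marks].
#' @return object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(time_s, channels, events = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  for (nm in names(channels)) {
    if (length(channels[[nm]]) != length(time_s)) {
      stop(sprintf("channel '%s' length differs from time_s", nm))
    }
    if (any(!is.finite(channels[[nm]]))) {
      stop(sprintf("channel '%s' contains non-finite intensities", nm))
    }
  }
  structure(list(time_s = time_s, channels = channels, events = events),
            class = "fluorescence_trace")
}

#' Percent reduction of the NAD(P)H pool
#'
#' `(F - F0) / (F100 - F0) * 100`, where `F0` is the 0 percent anchor (no
#' substrate) and `F100` the 100 percent anchor (cyanide). Values outside
#' `[0, 100]` are legal (hyper-reduction / hyper-oxidation) and flagged via
#' the `out_of_range` attribute rather than clipped.
#'
#' @param f observed intensity (vectorized).
#' @param f0 0 percent-reduction anchor intensity.
#' @param f100 100 percent-reduction anchor intensity.
#' @return percent reduction, same length as `f`.
#' @export
percent_reduction <- function(f, f0, f100) {
  if (f100 == f0) stop("f100 and f0 are equal; percent reduction undefined")
  out <- (f - f0) / (f100 - f0) * 100
  attr(out, "out_of_range") <- out < 0 | out > 100
  out
}

#' Ratiometric TMRM signal
#'
#' Pointwise 576/590 over 551/590 channel ratio. Samples with a zero
#' denominator become `NA` and are flagged, not errors.
#'
#' @param trace a [fluorescence_trace] with channels `"576/590"` and
#'   `"551/590"` (names configurable).
#' @param num,den channel names of numerator and denominator.
#' @return numeric ratio series with attribute `flagged` (logical).
#' @export
tmrm_ratio <- function(trace, num = "576/590", den = "551/590") {
  stopifnot(inherits(trace, "fluorescence_trace"))
  for (nm in c(num, den)) {
    if (!nm %in% names(trace$channels)) stop(sprintf("channel '%s' missing", nm))
  }
  a <- trace$channels[[num]]; b <- trace$channels[[den]]
  bad <- b == 0
  r <- ifelse(bad, NA_real_, a / b)
  attr(r, "flagged") <- bad
  r
}

#' Nernst potassium equilibrium potential
#'
#' `mV = -(RT/F) * ln(k_in / k_out) * 1000`, inside-negative convention:
#' with matrix K+ above external K+ the potential is negative, and
#' depolarization moves it toward 0.
#'
#' @param k_out external K+ (mol/L), > 0.
#' @param k_in matrix K+ (mol/L), > 0.
#' @param temperature kelvin.
#' @return millivolts.
#' @export
nernst_mv <- function(k_out, k_in = 0.120, temperature = 310.15) {
  if (any(k_out <= 0) || any(k_in <= 0)) stop("K+ concentrations must be > 0")
  faraday <- 96485.33212   # C/mol
  rt_f <- 8.314462618 * temperature / faraday   # volts
  -rt_f * log(k_in / k_out) * 1000
}

#' KCl/valinomycin calibration of the TMRM ratio
#'
#' Each calibration point (external KCl step in the presence of valinomycin)
#' is mapped to millivolts by [nernst_mv()]; the resulting (ratio, mV) pairs
#' define a monotone piecewise-linear map applied to the trace ratios.
#' Ratios outside the calibrated span are linearly extrapolated from the
#' nearest segment with a warning.
#'
#' @param k_out_M external K+ at each calibration step, mol/L.
#' @param ratio_cal TMRM ratio observed at each step (strictly monotone).
#' @param k_in assumed matrix K+, mol/L (default 120 mM; carried in metadata).
#' @param temperature kelvin.
#' @return object of class `potential_calibration`.
#' @export
potential_calibration <- function(k_out_M, ratio_cal, k_in = 0.120,
                                  temperature = 310.15) {
  stopifnot(length(k_out_M) == length(ratio_cal))
  if (length(k_out_M) < 2L) stop("need >= 2 calibration points")
  mv <- nernst_mv(k_out_M, k_in, temperature)
  o <- order(ratio_cal)
  r <- ratio_cal[o]; m <- mv[o]
  if (any(diff(r) <= 0)) stop("calibration ratios must be strictly monotone")
  if (!(all(diff(m) > 0) || all(diff(m) < 0))) {
    stop("calibration mV not monotone in ratio; check the point set")
  }
  structure(list(points = data.frame(k_out_M = k_out_M[o], ratio = r, mv = m),
                 k_in = k_in, temperature = temperature),
            class = "potential_calibration")
}

#' Convert TMRM ratios to millivolts
#'
#' @param ratios ratio series (e.g. from [tmrm_ratio()]).
#' @param calibration a [potential_calibration].
#' @return millivolt series; `NA` inputs propagate. Attribute `extrapolated`
#'   marks out-of-span values.
#' @export
calibrate_and_apply <- function(ratios, calibration) {
  stopifnot(inherits(calibration, "potential_calibration"))
  p <- calibration$points
  r <- as.numeric(ratios)
  lo <- p$ratio[1]; hi <- p$ratio[nrow(p)]
  out <- approx(p$ratio, p$mv, xout = pmin(pmax(r, lo), hi), ties = "ordered")$y
  below <- !is.na(r) & r < lo
  above <- !is.na(r) & r > hi
  if (any(below)) {
    s <- (p$mv[2] - p$mv[1]) / (p$ratio[2] - p$ratio[1])
    out[below] <- p$mv[1] + s * (r[below] - lo)
  }
  if (any(above)) {
    n <- nrow(p)
    s <- (p$mv[n] - p$mv[n - 1]) / (p$ratio[n] - p$ratio[n - 1])
    out[above] <- p$mv[n] + s * (r[above] - hi)
  }
  if (any(below | above)) {
    warning(sum(below | above), " ratio value(s) outside the calibrated span; ",
            "linearly extrapolated")
  }
  attr(out, "extrapolated") <- below | above
  attr(out, "k_in") <- calibration$k_in
  out
}

#' Read a fluorometry CSV
#'
#' Accepts `time_s,ch_576_590,ch_551_590` (TMRM mode) or `time_s,ch_350_450`
#' (NADH mode); column names `ch_<ex>_<em>` become channels `"<ex>/<em>"`.
#'
#' @param path file path.
#' @return a [fluorescence_trace].
#' @export
read_fluorometry_csv <- function(path) {
  d <- read.csv(path)
  stopifnot("time_s" %in% names(d))
  chcols <- grep("^ch_", names(d), value = TRUE)
  if (!length(chcols)) stop("no channel columns (ch_<ex>_<em>) found")
  chans <- lapply(chcols, function(cc) d[[cc]])
  names(chans) <- vapply(chcols, function(cc) {
    parts <- strsplit(sub("^ch_", "", cc), "_")[[1]]
    paste(parts, collapse = "/")
  }, character(1))
  fluorescence_trace(d$time_s, chans)
}
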