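#' Chamber respirometry oxygen trace
#'
#' A time-stamped chamber O2 concentration series, as produced by closed-chamber
#' high-resolution respirometry, together with the chamber volume and a sample
#' descriptor used later for normalization.
#'
#' @param time_s strictly increasing time stamps, seconds (>= 2 samples).
#' @param o2_uM chamber O2 concentration, micromol/L, all >= 0.
#' @param chamber_ml chamber volume in mL, > 0.
#' @param sample optional [sample_info()] descriptor.
#' @return object of class `oxygen_trace` (a data.frame with attributes).
#' @export
oxygen_trace <- function(time_s, o2_uM, chamber_ml, sample = sample_info()) {
  if (length(time_s) < 2L) stop("trace too short: need >= 2 samples")
  if (length(time_s) != length(o2_uM)) stop("time_s and o2_uM lengths differ")
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (any(!is.finite(o2_uM)) || any(o2_uM < 0)) stop("o2_uM must be finite and >= 0")
  if (!is.numeric(chamber_ml) || chamber_ml <= 0) stop("chamber_ml must be > 0")
  structure(data.frame(time_s = time_s, o2_uM = o2_uM),
            chamber_ml = chamber_ml, sample = sample,
            class = c("oxygen_trace", "data.frame"))
}

#' Sample descriptor
#'
#' @param label sample label.
#' @param cells_millions cell count in millions (optional).
#' @param protein_mg protein mass in mg (optional).
#' @return list of class `sample_info`.
#' @export
sample_info <- function(label = "sample", cells_millions = NA_real_,
                        protein_mg = NA_real_) {
  if (!is.na(cells_millions) && cells_millions <= 0) stop("cells_millions must be > 0")
  if (!is.na(protein_mg) && protein_mg <= 0) stop("protein_mg must be > 0")
  structure(list(label = label, cells_millions = cells_millions,
                 protein_mg = protein_mg), class = "sample_info")
}

#' Event marks on a trace
#'
#' @param time_s event times, seconds.
#' @param label event labels (e.g. "Oligo", "FC", "Rot", "Ant", "Digi", "PCR").
#' @param reagent optional reagent names.
#' @param conc optional concentration strings (value + unit).
#' @return data.frame of class `event_marks`, sorted by time.
#' @export
event_marks <- function(time_s, label, reagent = NA_character_, conc = NA_character_) {
  stopifnot(length(time_s) == length(label))
  out <- data.frame(time_s = as.numeric(time_s), label = as.character(label),
                    reagent = rep_len(reagent, length(time_s)),
                    conc = rep_len(conc, length(time_s)))
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_marks", "data.frame")
  out
}

#' Oxygen flux from a trace
#'
#' JO2(t) = -d[O2]/dt x chamber volume, with the derivative estimated by a
#' centered local linear regression of half-width `smoothing_halfwidth`
#' seconds around each point. Consumption is positive.
#'
#' @param trace an [oxygen_trace].
#' @param smoothing_halfwidth half-width of the regression window, seconds;
#'   0 uses adjacent-point slopes.
#' @param breaks optional reagent-addition times (seconds, e.g.
#'   `events$time_s`): the regression window is clipped at these so the
#'   derivative is never smoothed across a protocol transition.
#' @return data.frame with `time_s` and `jo2_pmol_s` (chamber total, pmol O2/s).
#' @export
compute_flux <- function(trace, smoothing_halfwidth = 10, breaks = NULL) {
  stopifnot(inherits(trace, "oxygen_trace"))
  t <- trace$time_s; y <- trace$o2_uM
  n <- length(t)
  if (n < 3L) stop("trace too short to differentiate")
  span <- t[n] - t[1]
  if (smoothing_halfwidth < 0 || smoothing_halfwidth >= span) {
    stop("smoothing_halfwidth must be >= 0 and smaller than the trace span")
  }
  seg <- if (length(breaks)) findInterval(t, sort(breaks)) else integer(n)
  slope <- numeric(n)
  # rolling local OLS slope; windows are contiguous index ranges so the
  # two-pointer sweep is O(n) amortized
  lo <- 1L; hi <- 1L
  for (i in seq_len(n)) {
    if (lo > i) lo <- i
    while (t[i] - t[lo] > smoothing_halfwidth || seg[lo] != seg[i]) lo <- lo + 1L
    if (hi < i) hi <- i
    while (hi < n && t[hi + 1L] - t[i] <= smoothing_halfwidth &&
           seg[hi + 1L] == seg[i]) hi <- hi + 1L
    idx <- lo:hi
    if (length(idx) < 2L) {
      idx <- max(1L, i - 1L):min(n, i + 1L)
      idx <- idx[seg[idx] == seg[i]]
      if (length(idx) < 2L) { slope[i] <- NA_real_; next }
    }
    tt <- t[idx]; yy <- y[idx]
    tc <- tt - mean(tt)
    slope[i] <- sum(tc * (yy - mean(yy))) / sum(tc^2)
  }
  # isolated single-point segments inherit the nearest defined slope
  if (anyNA(slope)) slope <- approx(t[!is.na(slope)], slope[!is.na(slope)],
                                    xout = t, rule = 2)$y
  vol_l <- attr(trace, "chamber_ml") / 1000
  # uM/s * L = umol/s; *1e6 -> pmol/s; consumption (declining O2) positive
  data.frame(time_s = t, jo2_pmol_s = -slope * vol_l * 1e6)
}

#' Steady-state window policy
#'
#' @param lag_s seconds to skip after each event before a window may start.
#' @param window_s length of the rate window (taken from the end of each
#'   inter-event segment).
#' @param cv_max coefficient-of-variation threshold for auto-acceptance.
#' @return list of class `window_policy`.
#' @export
window_policy <- function(lag_s = 90, window_s = 60, cv_max = 0.1) {
  stopifnot(lag_s >= 0, window_s > 0, cv_max >= 0)
  structure(list(lag_s = lag_s, window_s = window_s, cv_max = cv_max),
            class = "window_policy")
}

#' Extract per-step steady-state rates
#'
#' Segments the flux series at the event marks and reports one steady state
#' per inter-event segment: the mean flux over the last `window_s` seconds of
#' the segment, starting no earlier than `lag_s` after the segment's event.
#' Segments too short for the policy are returned flagged
#' (`accepted = FALSE`), never silently dropped. The segment before the first
#' event is labelled `"basal"`.
#'
#' @param flux data.frame from [compute_flux()].
#' @param events an [event_marks] table (may have zero rows).
#' @param policy a [window_policy()].
#' @return data.frame of class `steady_states`: `label`, `jo2_pmol_s`,
#'   `window_start_s`, `window_end_s`, `cv`, `accepted`, `flag`.
#' @export
extract_steady_states <- function(flux, events = event_marks(numeric(0), character(0)),
                                  policy = window_policy()) {
  stopifnot(is.data.frame(flux), all(c("time_s", "jo2_pmol_s") %in% names(flux)))
  t0 <- flux$time_s[1]; t1 <- flux$time_s[nrow(flux)]
  if (nrow(events) && (any(events$time_s < t0) || any(events$time_s > t1))) {
    stop("event beyond trace span")
  }
  if (nrow(events) && any(diff(events$time_s) < 0)) stop("events must be sorted")
  labs <- c("basal", if (nrow(events)) make.unique(events$label, sep = "#"))
  starts <- c(t0, if (nrow(events)) events$time_s)
  ends <- c(if (nrow(events)) events$time_s, t1)
  rows <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    seg_start <- starts[i]; seg_end <- ends[i]
    lag <- if (i == 1L) 0 else policy$lag_s   # no reagent precedes the basal segment
    win_start <- max(seg_start + lag, seg_end - policy$window_s)
    flag <- ""
    if (win_start >= seg_end || (seg_end - win_start) < policy$window_s - 1e-9) {
      flag <- "short_segment"
      win_start <- max(seg_start + min(lag, max(0, seg_end - seg_start - 1e-9)),
                       seg_start)
    }
    # the instant of the next addition belongs to the next segment
    sel <- flux$time_s >= win_start &
      (if (i == length(labs)) flux$time_s <= seg_end else flux$time_s < seg_end)
    if (!any(sel)) {
      rows[[i]] <- data.frame(label = labs[i], jo2_pmol_s = NA_real_,
                              window_start_s = win_start, window_end_s = seg_end,
                              cv = NA_real_, accepted = FALSE, flag = "empty_window")
      next
    }
    jj <- flux$jo2_pmol_s[sel]
    m <- mean(jj)
    cv <- if (abs(m) > 0) sd(jj) / abs(m) else Inf
    accepted <- flag == "" && is.finite(cv) && cv <= policy$cv_max
    if (flag == "" && !accepted) flag <- "high_cv"
    rows[[i]] <- data.frame(label = labs[i], jo2_pmol_s = m,
                            window_start_s = win_start, window_end_s = seg_end,
                            cv = cv, accepted = accepted, flag = flag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("steady_states", "data.frame")
  out
}

#' Correct steady states for non-mitochondrial oxygen consumption
#'
#' Subtracts the residual (post rotenone/antimycin A) rate from every other
#' state. Rates that would go negative are floored at 0 with a warning. The
#' residual state itself is dropped from the corrected output.
#'
#' @param states a `steady_states` data.frame.
#' @param residual_label label of the residual state (default `"Ant"`).
#' @return corrected `steady_states` (without the residual row), with the
#'   subtracted residual recorded in attribute `residual_jo2`.
#' @export
correct_nonmito <- function(states, residual_label = "Ant") {
  stopifnot(is.data.frame(states), "label" %in% names(states))
  hit <- which(states$label == residual_label)
  if (!length(hit)) {
    stop(sprintf("missing residual state '%s' (have: %s)", residual_label,
                 paste(states$label, collapse = ", ")))
  }
  residual <- states$jo2_pmol_s[hit[length(hit)]]
  out <- states[-hit, , drop = FALSE]
  corrected <- out$jo2_pmol_s - residual
  if (any(corrected < 0, na.rm = TRUE)) {
    warning("non-mitochondrial correction drove ",
            sum(corrected < 0, na.rm = TRUE),
            " state(s) negative; floored at 0")
    corrected[corrected < 0] <- 0
  }
  out$jo2_pmol_s <- corrected
  rownames(out) <- NULL
  attr(out, "residual_jo2") <- residual
  out
}

#' Normalize steady-state rates
#'
#' @param states a `steady_states` data.frame.
#' @param sample a [sample_info()] descriptor carrying the denominators.
#' @param basis `"cells"` (pmol O2/s per million cells), `"protein"`
#'   (pmol O2/s/mg protein) or `"percent_basal"` (the pre-permeabilization
#'   basal state is 100 percent).
#' @param basal_label label of the basal state for `"percent_basal"`.
#' @return data.frame of class `normalized_rates` with `label`, `rate`,
#'   `basis`.
#' @export
normalize_rates <- function(states, sample, basis = c("cells", "protein", "percent_basal"),
                            basal_label = "basal") {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(states))
  rate <- switch(basis,
    cells = {
      if (is.na(sample$cells_millions)) stop("basis 'cells' requires sample cells_millions")
      states$jo2_pmol_s / sample$cells_millions
    },
    protein = {
      if (is.na(sample$protein_mg)) stop("basis 'protein' requires sample protein_mg")
      states$jo2_pmol_s / sample$protein_mg
    },
    percent_basal = {
      i <- which(states$label == basal_label)
      if (!length(i)) stop(sprintf("basis 'percent_basal' requires a '%s' state", basal_label))
      basal <- states$jo2_pmol_s[i[1]]
      if (basal == 0) stop("basal rate is 0; percent-of-basal undefined")
      (states$jo2_pmol_s / basal) * 100    # x/x*100 is exactly 100
    })
  structure(data.frame(label = states$label, rate = rate, basis = basis),
            class = c("normalized_rates", "data.frame"))
}

#' Michaelis constant of the FCCP dose response
#'
#' Fits the above-baseline rate increment to `Vmax * [FCCP] / (Km + [FCCP])`
#' by least squares on the ascending limb. Points at or beyond the dose that
#' achieves the maximum observed rate are excluded before fitting, because the
#' bioenergetic collapse at supra-optimal uncoupler cannot be represented by a
#' hyperbola. The first dose reaching the maximum within 1e-9 is the tie-break.
#'
#' @param dose_uM uncoupler doses, micromolar, ascending; a 0 dose provides
#'   the baseline unless `baseline` is given.
#' @param rate rates at each dose (same basis throughout).
#' @param baseline pre-titration rate; defaults to the rate at dose 0.
#' @return list with `km_uM`, `vmax` (above-baseline asymptote), `n_used`,
#'   and the fitted model's residual sum of squares `rss`.
#' @export
fccp_km <- function(dose_uM, rate, baseline = NULL) {
  stopifnot(length(dose_uM) == length(rate))
  o <- order(dose_uM)
  dose_uM <- dose_uM[o]; rate <- rate[o]
  if (is.null(baseline)) {
    z <- which(dose_uM == 0)
    if (!length(z)) stop("no baseline: supply `baseline` or include a 0 dose")
    baseline <- rate[z[1]]
    dose_uM <- dose_uM[-z]; rate <- rate[-z]
  }
  peak <- which(rate >= max(rate) - 1e-9)[1]
  keep <- seq_len(peak - 1L)   # strictly before the peak dose
  if (length(keep) < 3L) {
    # a saturating curve can legitimately peak at the final dose; in that case
    # the whole ascending limb (including the plateau point) is usable
    if (peak == length(rate)) keep <- seq_along(rate) else
      stop("fewer than 3 usable ascending-limb points for the Km fit")
  }
  d <- dose_uM[keep]; y <- rate[keep] - baseline
  if (length(d) < 3L) stop("fewer than 3 usable ascending-limb points for the Km fit")
  # starting values by Hanes linearization, guarded
  vmax0 <- max(y) * 1.2
  km0 <- max(min(d[y >= vmax0 / 2.4][1], max(d), na.rm = TRUE), min(d) / 2, na.rm = TRUE)
  fit <- tryCatch(
    nls(y ~ vmax * d / (km + d), start = list(vmax = vmax0, km = km0),
        control = list(warnOnly = FALSE), lower = c(1e-9, 1e-9),
        algorithm = "port"),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("FCCP Km fit did not converge: ", conditionMessage(fit),
         " (n=", length(d), ", doses=", paste(signif(d, 3), collapse = "/"), ")")
  }
  cf <- coef(fit)
  if (cf[["km"]] <= 0) stop("FCCP Km fit returned non-positive Km")
  list(km_uM = unname(cf[["km"]]), vmax = unname(cf[["vmax"]]),
       n_used = length(d), rss = sum(residuals(fit)^2))
}

# ---- CSV dialects ------------------------------------------------------------

#' Read/write the package's respirometry CSV dialects
#'
#' Traces: columns `time_s,o2_uM`. Events: `time_s,label,reagent,conc`.
#'
#' @param path file path.
#' @param chamber_ml chamber volume for the constructed trace.
#' @param sample a [sample_info()].
#' @return [read_trace_csv()] returns an [oxygen_trace];
#'   [read_events_csv()] an [event_marks] table.
#' @export
read_trace_csv <- function(path, chamber_ml, sample = sample_info()) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "o2_uM") %in% names(d)))
  oxygen_trace(d$time_s, d$o2_uM, chamber_ml, sample)
}

#' @rdname read_trace_csv
#' @export
read_events_csv <- function(path) {
  d <- read.csv(path, colClasses = c(label = "character"))
  stopifnot(all(c("time_s", "label") %in% names(d)))
  event_marks(d$time_s, d$label,
              reagent = if ("reagent" %in% names(d)) d$reagent else NA,
              conc = if ("conc" %in% names(d)) d$conc else NA)
}
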