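# Dual-reporter (GFP/mCherry) quantification: background gating against a
# negative control, quadrant classification, fold enrichment, and growth
# curve doubling times.

#' Per-cell two-channel fluorescence event table
#'
#' @param gfp,mcherry positive, finite intensities (arbitrary fluorescence
#'   units), one value per event.
#' @param sample sample label (recycled).
#' @return data.frame of class `event_table` with columns sample, gfp,
#'   mcherry.
#' @export
event_table <- function(gfp, mcherry, sample = "sample") {
  if (length(gfp) != length(mcherry)) stopf("gfp and mcherry must have equal length")
  if (any(!is.finite(gfp)) || any(!is.finite(mcherry)) ||
      any(gfp <= 0) || any(mcherry <= 0)) {
    stopf("intensities must be finite and positive")
  }
  structure(
    data.frame(sample = sample, gfp = gfp, mcherry = mcherry,
               stringsAsFactors = FALSE),
    class = c("event_table", "data.frame")
  )
}

#' Derive background gates from a negative control
#'
#' Sets each channel threshold to the given empirical percentile of the
#' negative control's intensities (the control expresses neither reporter,
#' so the percentile marks background-level fluorescence). The empirical
#' percentile is the inverse-ECDF order statistic `sorted[ceiling(p * n)]`.
#'
#' @param negative_control an [event_table()] with at least 100 events.
#' @param percentile fraction in (0, 1]; default 0.995. 1 gives the channel
#'   maxima.
#' @return list of class `gate_spec`: gfp_threshold, mcherry_threshold,
#'   percentile, n_control.
#' @export
derive_gates <- function(negative_control, percentile = 0.995) {
  n <- nrow(negative_control)
  if (is.null(n) || n == 0L) stopf("empty negative control")
  if (n < 100L) stopf("need >= 100 control events, got %d", n)
  if (percentile <= 0 || percentile > 1) stopf("percentile must be in (0, 1]")
  pick <- function(x) sort(x)[ceiling(percentile * length(x))]
  structure(
    list(
      gfp_threshold = pick(negative_control$gfp),
      mcherry_threshold = pick(negative_control$mcherry),
      percentile = percentile, n_control = n
    ),
    class = "gate_spec"
  )
}

#' Classify events into fluorescence quadrants
#'
#' An event is channel-positive iff its intensity is strictly above the gate
#' threshold (boundary equality counts as negative). Quadrants follow the
#' usual dual-reporter dot-plot convention:
#' Q1 GFP-/mCherry+, Q2 GFP+/mCherry+, Q3 GFP-/mCherry-, Q4 GFP+/mCherry-.
#'
#' @param events an [event_table()].
#' @param gates a `gate_spec` from [derive_gates()] (or a compatible list).
#' @return list of class `quadrant_summary`: counts, fractions (named
#'   Q1..Q4), channel means (arithmetic, linear scale), n_total.
#' @export
classify_quadrants <- function(events, gates) {
  if (nrow(events) == 0L) stopf("empty event table")
  gfp_pos <- events$gfp > gates$gfp_threshold
  mch_pos <- events$mcherry > gates$mcherry_threshold
  counts <- c(
    Q1 = sum(!gfp_pos & mch_pos),
    Q2 = sum(gfp_pos & mch_pos),
    Q3 = sum(!gfp_pos & !mch_pos),
    Q4 = sum(gfp_pos & !mch_pos)
  )
  structure(
    list(
      counts = counts, fractions = counts / nrow(events),
      gfp_mean = mean(events$gfp), mcherry_mean = mean(events$mcherry),
      n_total = nrow(events)
    ),
    class = "quadrant_summary"
  )
}

#' Fold enrichment of a quadrant between two samples
#'
#' @param sample,reference `quadrant_summary` objects.
#' @param quadrant one of "Q1".."Q4".
#' @return list: fold (sample fraction / reference fraction; `NA` when
#'   undefined), undefined (TRUE when the reference fraction is 0).
#' @export
enrichment_fold <- function(sample, reference, quadrant = "Q4") {
  quadrant <- match.arg(quadrant, c("Q1", "Q2", "Q3", "Q4"))
  fs <- sample$fractions[[quadrant]]
  fr <- reference$fractions[[quadrant]]
  if (fr == 0) {
    list(fold = NA_real_, undefined = TRUE)
  } else {
    list(fold = fs / fr, undefined = FALSE)
  }
}

#' Doubling time from a growth curve
#'
#' Fits log2(OD - blank) against time by least squares over the exponential
#' window (blank-subtracted OD within `window`, default 0.02-0.4) and
#' returns 1/slope.
#'
#' @param time_min time points, minutes.
#' @param od600 raw OD600 readings.
#' @param blank blank OD to subtract.
#' @param window blanked-OD band treated as log phase.
#' @return list: minutes (doubling time; `NA` when flagged), slope (per
#'   minute, log2 scale), n_points, no_growth flag.
#' @export
doubling_time <- function(time_min, od600, blank = 0, window = c(0.02, 0.4)) {
  if (length(time_min) != length(od600)) stopf("time and OD vectors differ in length")
  od <- od600 - blank
  keep <- is.finite(od) & od > 0 & od >= window[1] & od <= window[2]
  if (sum(keep) < 5L) stopf("too few in-window points (%d) for a log-phase fit", sum(keep))
  fit <- lm(log2(od[keep]) ~ time_min[keep])
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 1e-12) {
    return(list(minutes = NA_real_, slope = slope, n_points = sum(keep),
                no_growth = TRUE))
  }
  list(minutes = 1 / slope, slope = slope, n_points = sum(keep), no_growth = FALSE)
}
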