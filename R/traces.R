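#' Construct a per-cell time series
#'
#' The trace convention used throughout the package: a tibble with a strictly
#' increasing, uniformly spaced `time_min` column and a `value` column, plus
#' optional `channel` and `cell_id` identifiers. Most analysis functions take
#' such a data frame as their first argument and return tibbles, so calls
#' chain with the pipe.
#'
#' @param time_min Time in minutes (uniform spacing).
#' @param value Measured values (intensity, perimeter, ...).
#' @param channel,cell_id Optional identifiers.
#' @return A tibble of class `trace_series`.
#' @export
trace_series <- function(time_min, value, channel = NULL, cell_id = NULL) {
  check_trace(time_min, value)
  out <- tibble(time_min = as.double(time_min), value = as.double(value))
  if (!is.null(channel)) out$channel <- channel
  if (!is.null(cell_id)) out$cell_id <- cell_id
  class(out) <- c("trace_series", class(out))
  out
}

check_trace <- function(time_min, value) {
  if (length(time_min) != length(value)) {
    abort("`time_min` and `value` must have the same length",
          class = "extrudr_parameter_error")
  }
  if (length(time_min) >= 2) {
    dt <- diff(time_min)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * max(abs(dt))) {
      abort("`time_min` must be strictly increasing and uniformly spaced",
            class = "extrudr_parameter_error")
    }
  }
  invisible(TRUE)
}

frame_interval <- function(trace) {
  if (nrow(trace) < 2) return(NA_real_)
  trace$time_min[2] - trace$time_min[1]
}

#' Smooth a trace
#'
#' Either locally weighted regression (`"loess"`, with `span` expressed as a
#' fraction of the trace length, default 0.07) or a centred moving average
#' (`"moving_average"`, default 5-point window) whose window shrinks
#' symmetrically at the trace ends. Output has the same length and time axis
#' as the input.
#'
#' @param trace A trace data frame (`time_min`, `value`).
#' @param method `"loess"` or `"moving_average"`.
#' @param span Loess span as a fraction of the trace length (>= 3 points are
#'   always used).
#' @param window Moving-average window in frames (odd).
#' @return The smoothed trace (same columns).
#' @export
smooth_trace <- function(trace, method = c("loess", "moving_average"),
                         span = 0.07, window = 5L) {
  method <- match.arg(method)
  check_trace(trace$time_min, trace$value)
  n <- nrow(trace)
  if (method == "moving_average") {
    window <- as.integer(window)
    if (window < 1L) {
      abort("`window` must be at least 1", class = "extrudr_parameter_error")
    }
    if (window %% 2L == 0L) {
      abort("`window` must be odd", class = "extrudr_parameter_error")
    }
    if (n < window) {
      abort("trace shorter than the smoothing window",
            class = "extrudr_parameter_error")
    }
    trace$value <- moving_average(trace$value, window)
  } else {
    if (!is.finite(span) || span <= 0) {
      abort("`span` must be positive", class = "extrudr_parameter_error")
    }
    if (sd(trace$value) == 0) return(trace)  # constant: loess is degenerate
    span_pts <- max(span, min(1, 4 / n))
    fit <- loess(value ~ time_min, data = trace, span = span_pts, degree = 2,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct"))
    trace$value <- as.double(predict(fit, trace$time_min))
  }
  trace
}

# centred moving average with window shrinking symmetrically at the ends
moving_average <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  hh <- pmin(h, idx - 1L, n - idx)  # symmetric shrink keeps endpoints unbiased
  (cs[idx + hh + 1L] - cs[idx - hh]) / (2 * hh + 1)
}

#' Detect the constriction onset (inflection point) of a perimeter trace
#'
#' Smooths the trace with a 5-point moving average, then scans every
#' candidate breakpoint, fitting one least-squares line to the left segment
#' and one to the right segment and scoring the total squared error of the
#' two fits against the raw trace. The breakpoint with minimal total error
#' is the onset. If the fitted slope does not steepen downwards by at least
#' `slope_min` at the breakpoint, the trace is flagged as non-constricting.
#'
#' @param trace A trace data frame (`time_min`, `value`), typically the
#'   apical perimeter.
#' @param min_segment Minimum points per segment (default 5).
#' @param window Pre-smoothing moving-average window (default 5).
#' @param slope_min Minimum downward slope change (value units per minute)
#'   for the trace to count as constricting (default 0.1).
#' @return An object of class `extr_onset`; `tidy()` returns the
#'   per-candidate error curve, `glance()` (and the object fields) the onset
#'   index/time, the two slopes and the `constricting` flag.
#' @export
detect_onset <- function(trace, min_segment = 5L, window = 5L,
                         slope_min = 0.1) {
  check_trace(trace$time_min, trace$value)
  n <- nrow(trace)
  min_segment <- as.integer(min_segment)
  if (n < 2L * min_segment) {
    abort("trace too short for two segments", class = "extrudr_detection_error")
  }
  sm <- smooth_trace(trace, "moving_average", window = window)
  t <- sm$time_min; ys <- sm$value; yr <- trace$value

  # closed-form two-segment least squares on the smoothed trace, error
  # against the raw trace, via cumulative sums
  cst <- cumsum(t); cst2 <- cumsum(t^2)
  csy <- cumsum(ys); csty <- cumsum(t * ys)
  seg_fit <- function(lo, hi) {
    m <- hi - lo + 1
    st <- cst[hi] - if (lo > 1) cst[lo - 1] else 0
    st2 <- cst2[hi] - if (lo > 1) cst2[lo - 1] else 0
    sy <- csy[hi] - if (lo > 1) csy[lo - 1] else 0
    sty <- csty[hi] - if (lo > 1) csty[lo - 1] else 0
    den <- m * st2 - st^2
    if (abs(den) < 1e-300) {
      c(slope = 0, intercept = sy / m)
    } else {
      slope <- (m * sty - st * sy) / den
      c(slope = slope, intercept = (sy - slope * st) / m)
    }
  }
  cand <- seq(min_segment, n - min_segment + 1L)
  err <- rep(NA_real_, length(cand))
  slopes <- matrix(NA_real_, length(cand), 2)
  for (i in seq_along(cand)) {
    k <- cand[i]
    fl <- seg_fit(1L, k)
    fr <- seg_fit(k, n)
    el <- yr[1:k] - (fl["intercept"] + fl["slope"] * t[1:k])
    er <- yr[k:n] - (fr["intercept"] + fr["slope"] * t[k:n])
    err[i] <- sum(el^2) + sum(er^2)
    slopes[i, ] <- c(fl["slope"], fr["slope"])
  }
  best <- which.min(err)
  k <- cand[best]
  slope_change <- slopes[best, 2] - slopes[best, 1]
  structure(
    list(onset_index = k, onset_time = t[k],
         slope_pre = slopes[best, 1], slope_post = slopes[best, 2],
         constricting = slope_change < -abs(slope_min),
         sse = err[best],
         diagnostics = tibble(breakpoint = cand, time = t[cand], sse = err)),
    class = "extr_onset")
}

#' @export
print.extr_onset <- function(x, ...) {
  cat(sprintf("<extr_onset> onset at index %d (t = %.4g min), %s\n",
              x$onset_index, x$onset_time,
              if (x$constricting) "constricting" else "no constriction"))
  invisible(x)
}

#' @export
tidy.extr_onset <- function(x, ...) x$diagnostics

#' @export
glance.extr_onset <- function(x, ...) {
  tibble(onset_index = x$onset_index, onset_time = x$onset_time,
         slope_pre = x$slope_pre, slope_post = x$slope_post,
         constricting = x$constricting, sse = x$sse)
}

#' Align and normalise a cohort of traces
#'
#' Resamples each member onto a relative-time axis whose origin is either
#' the trace end (end of extrusion) or the per-cell onset, divides each
#' trace by its normalisation constant, and summarises the ensemble mean and
#' SEM at every relative time over the members present there.
#'
#' @param traces Long tibble with columns `cell_id`, `time_min`, `value`.
#' @param mode Alignment reference: `"end"` or `"onset"`.
#' @param norm `"first5_mean"` (mean of the first five values),
#'   `"pre_onset_mean"` (mean of all values before the onset) or `"none"`.
#' @param onsets For `mode = "onset"` (and `norm = "pre_onset_mean"`): tibble
#'   with columns `cell_id`, `onset_time`.
#' @return An object of class `extr_ensemble`: `$members` (per-cell
#'   normalised values on the relative axis) and `$summary`
#'   (`rel_time_min`, `mean`, `sem`, `n`). Cells with a zero normalisation
#'   constant are dropped with a warning.
#' @export
align_normalize <- function(traces, mode = c("end", "onset"),
                            norm = c("first5_mean", "pre_onset_mean", "none"),
                            onsets = NULL) {
  mode <- match.arg(mode)
  norm <- match.arg(norm)
  if ((mode == "onset" || norm == "pre_onset_mean") && is.null(onsets)) {
    abort("`onsets` (cell_id, onset_time) required for onset alignment",
          class = "extrudr_parameter_error")
  }
  members <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      ref <- if (mode == "end") max(df$time_min) else {
        onsets$onset_time[match(key$cell_id, onsets$cell_id)]
      }
      const <- switch(norm,
        first5_mean = mean(df$value[seq_len(min(5, nrow(df)))]),
        pre_onset_mean = {
          ot <- onsets$onset_time[match(key$cell_id, onsets$cell_id)]
          mean(df$value[df$time_min < ot])
        },
        none = 1)
      if (!is.finite(const) || const == 0) {
        warn(sprintf("cell %s dropped: zero or undefined normalisation constant",
                     key$cell_id))
        return(tibble(rel_time_min = double(), value_norm = double()))
      }
      tibble(rel_time_min = df$time_min - ref, value_norm = df$value / const)
    }) |>
    dplyr::ungroup()
  summary <- members |>
    dplyr::mutate(rel_time_min = round(.data$rel_time_min, 9)) |>
    dplyr::group_by(.data$rel_time_min) |>
    dplyr::summarise(mean = mean(.data$value_norm),
                     sem = sd(.data$value_norm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(members = members, summary = summary, mode = mode,
                 norm = norm),
            class = "extr_ensemble")
}

#' @export
print.extr_ensemble <- function(x, ...) {
  cat(sprintf("<extr_ensemble> %d cells aligned by %s, normalised by %s\n",
              dplyr::n_distinct(x$members$cell_id), x$mode, x$norm))
  invisible(x)
}

#' @export
tidy.extr_ensemble <- function(x, ...) x$summary

#' @export
autoplot.extr_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$rel_time_min, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("time relative to %s (min)", object$mode),
                  y = "normalised value")
}

#' Finite-difference rate of change of a trace
#'
#' Forward differences divided by the frame interval, reported at interval
#' midpoints. With `sign = "contraction"` the derivative is negated so that
#' a shrinking perimeter gives a positive contraction rate.
#'
#' @param trace A trace data frame (`time_min`, `value`).
#' @param sign `"signal"` (d value / dt) or `"contraction"`
#'   (-d value / dt).
#' @return A tibble with `time_min` (midpoints, length n - 1) and `rate`.
#' @export
rate_of_change <- function(trace, sign = c("signal", "contraction")) {
  sign <- match.arg(sign)
  check_trace(trace$time_min, trace$value)
  if (nrow(trace) < 2) {
    abort("need at least two points", class = "extrudr_parameter_error")
  }
  dt <- diff(trace$time_min)
  r <- diff(trace$value) / dt
  if (sign == "contraction") r <- -r
  tibble(time_min = trace$time_min[-nrow(trace)] + dt / 2, rate = r)
}

#' Contraction rate of a perimeter trace
#'
#' Convenience wrapper: `rate_of_change(trace, sign = "contraction")`.
#' @inheritParams rate_of_change
#' @return See [rate_of_change()].
#' @export
contraction_rate <- function(trace) rate_of_change(trace, "contraction")

#' Normalised cross-correlation of two traces
#'
#' Both series are mean-subtracted; the coefficient at lag L is
#' \eqn{\sum_t a'(t) b'(t+L) / \sqrt{\sum a'^2 \sum b'^2}} (the convention of
#' MATLAB's `xcorr(..., 'coeff')`). A positive peak lag means `b` lags `a`.
#'
#' @param a,b Trace data frames of equal length and frame interval.
#' @param max_lag Maximum lag in frames (default: one third of the trace
#'   length).
#' @return An object of class `extr_xcorr`; `tidy()` gives
#'   `lag_frames`, `lag_min`, `coef`; `$peak_lag_min` / `$peak_lag_frames`
#'   the argmax lag.
#' @export
xcorr_normalized <- function(a, b, max_lag = NULL) {
  check_trace(a$time_min, a$value)
  check_trace(b$time_min, b$value)
  n <- nrow(a)
  if (nrow(b) != n) {
    abort("traces must have equal length", class = "extrudr_parameter_error")
  }
  dt_a <- frame_interval(a); dt_b <- frame_interval(b)
  if (abs(dt_a - dt_b) > 1e-9) {
    abort("traces must share the frame interval", class = "extrudr_parameter_error")
  }
  ac <- a$value - mean(a$value)
  bc <- b$value - mean(b$value)
  denom <- sqrt(sum(ac^2) * sum(bc^2))
  if (denom == 0) {
    abort("zero-variance input: correlation undefined",
          class = "extrudr_undefined_correlation")
  }
  if (is.null(max_lag)) max_lag <- floor(n / 3)
  lags <- seq(-max_lag, max_lag)
  coef <- vapply(lags, function(L) {
    if (L >= 0) sum(ac[seq_len(n - L)] * bc[seq_len(n - L) + L]) / denom
    else sum(ac[seq_len(n + L) - L] * bc[seq_len(n + L)]) / denom
  }, 0)
  peak <- lags[which.max(coef)]
  structure(list(lags = tibble(lag_frames = lags, lag_min = lags * dt_a,
                               coef = coef),
                 peak_lag_frames = peak, peak_lag_min = peak * dt_a),
            class = "extr_xcorr")
}

#' @export
print.extr_xcorr <- function(x, ...) {
  cat(sprintf("<extr_xcorr> peak %.3f at lag %+g min\n",
              max(x$lags$coef), x$peak_lag_min))
  invisible(x)
}

#' @export
tidy.extr_xcorr <- function(x, ...) x$lags

#' @export
autoplot.extr_xcorr <- function(object, ...) {
  ggplot2::ggplot(object$lags, ggplot2::aes(.data$lag_min, .data$coef)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_lag_min, linetype = "dashed") +
    ggplot2::labs(x = "lag (min)", y = "cross-correlation")
}

#' Detect intensity pulses by topographic prominence
#'
#' Finds local maxima whose prominence (height above the higher of the two
#' flanking minima, searched out to the nearest higher point or the trace
#' end) reaches `min_prominence`. The pulse amplitude `a_peak` is that
#' prominence-style height, and `w_peak` is the width of the pulse at half
#' of `a_peak` below the peak, linearly interpolated.
#'
#' @param trace A trace data frame (`time_min`, `value`), smoothed upstream
#'   as the pipeline requires.
#' @param min_prominence Detection threshold in value units (default 7).
#' @return A tibble of pulses ordered by time: `t_peak`, `index`, `height`,
#'   `a_peak`, `prominence`, `w_peak` (minutes). Zero rows when nothing
#'   clears the threshold.
#' @export
detect_pulses <- function(trace, min_prominence = 7) {
  check_trace(trace$time_min, trace$value)
  y <- trace$value
  t <- trace$time_min
  n <- length(y)
  if (n < 3) return(pulse_tibble(NULL))
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  rows <- list()
  for (p in is_peak) {
    # descend left/right to the nearest strictly higher point (or the end)
    left <- if (any(y[seq_len(p - 1)] > y[p])) {
      lo <- max(which(y[seq_len(p - 1)] > y[p]))
      min(y[(lo + 1):(p - 1)])
    } else min(y[seq_len(p - 1)])
    right <- if (p < n && any(y[(p + 1):n] > y[p])) {
      hi <- p + min(which(y[(p + 1):n] > y[p]))
      min(y[(p + 1):(hi - 1)])
    } else min(y[(p + 1):n])
    prom <- y[p] - max(left, right)
    if (prom < min_prominence) next
    half <- y[p] - prom / 2
    wl <- cross_time(t, y, p, half, -1L)
    wr <- cross_time(t, y, p, half, +1L)
    rows[[length(rows) + 1]] <- tibble(
      t_peak = t[p], index = p, height = y[p],
      a_peak = prom, prominence = prom, w_peak = wr - wl)
  }
  pulse_tibble(rows)
}

pulse_tibble <- function(rows) {
  if (is.null(rows) || length(rows) == 0) {
    return(tibble(t_peak = double(), index = integer(), height = double(),
                  a_peak = double(), prominence = double(), w_peak = double()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$t_peak)
}

# interpolated time where the trace crosses `level` walking from peak p
cross_time <- function(t, y, p, level, dir) {
  i <- p
  while (i + dir >= 1 && i + dir <= length(y) && y[i + dir] > level) i <- i + dir
  j <- i + dir
  if (j < 1 || j > length(y)) return(t[i])
  # linear interpolation between samples i and j
  t[i] + (t[j] - t[i]) * (y[i] - level) / (y[i] - y[j])
}

#' Pulse frequency before and after the constriction onset
#'
#' @param pulses A [detect_pulses()] table.
#' @param onset_time Onset time in minutes.
#' @param trace_span Length-2 vector, the trace's first and last time.
#' @return A one-row tibble: `n_before`, `n_after`, `freq_before`,
#'   `freq_after` (per minute). A zero-length window yields `NA` with a
#'   warning.
#' @export
pulse_frequency <- function(pulses, onset_time, trace_span) {
  if (onset_time < trace_span[1] || onset_time > trace_span[2]) {
    abort("onset outside the trace span", class = "extrudr_parameter_error")
  }
  before <- onset_time - trace_span[1]
  after <- trace_span[2] - onset_time
  nb <- sum(pulses$t_peak < onset_time)
  na_ <- sum(pulses$t_peak >= onset_time)
  fb <- if (before > 0) nb / before else { warn("zero-length pre-onset window"); NA_real_ }
  fa <- if (after > 0) na_ / after else { warn("zero-length post-onset window"); NA_real_ }
  tibble(n_before = nb, n_after = na_, freq_before = fb, freq_after = fa)
}

#' Contraction yield at contraction peaks
#'
#' Detects peaks of the contraction-rate series (see [contraction_rate()])
#' and computes, for each, the yield: contraction rate at the peak divided
#' by the myosin intensity there (myosin linearly interpolated to the peak
#' time). Peaks are assigned to `bin_width`-minute windows relative to the
#' onset.
#'
#' @param perimeter,myosin Co-registered trace data frames.
#' @param onset_time Constriction onset (minutes), from [detect_onset()] on
#'   the perimeter.
#' @param bin_width Bin width in minutes (default 5).
#' @param min_prominence Prominence threshold for contraction peaks
#'   (default 7; use a scale appropriate to the rate units).
#' @param cell_id Optional cell identifier carried into the output.
#' @return A tibble with one row per contraction peak: `cell_id` (if given),
#'   `t_peak`, `rel_time`, `bin` (left edge of the bin, minutes relative to
#'   onset), `contraction`, `myosin`, `yield`. Peaks with zero myosin are
#'   skipped with a warning.
#' @export
contraction_yield <- function(perimeter, myosin, onset_time, bin_width = 5,
                              min_prominence = 7, cell_id = NULL) {
  cr <- contraction_rate(perimeter)
  peaks <- detect_pulses(tibble(time_min = cr$time_min, value = cr$rate),
                         min_prominence = min_prominence)
  if (nrow(peaks) == 0) {
    out <- tibble(t_peak = double(), rel_time = double(), bin = double(),
                  contraction = double(), myosin = double(), yield = double())
    if (!is.null(cell_id)) out <- dplyr::mutate(out, cell_id = cell_id, .before = 1)
    return(out)
  }
  myo_at <- approx(myosin$time_min, myosin$value, xout = peaks$t_peak,
                   rule = 2)$y
  contr_at <- approx(cr$time_min, cr$rate, xout = peaks$t_peak)$y
  keep <- myo_at != 0
  if (any(!keep)) warn(sprintf("%d peak(s) skipped: zero myosin", sum(!keep)))
  rel <- peaks$t_peak[keep] - onset_time
  out <- tibble(t_peak = peaks$t_peak[keep], rel_time = rel,
                bin = floor(rel / bin_width) * bin_width,
                contraction = contr_at[keep], myosin = myo_at[keep],
                yield = contr_at[keep] / myo_at[keep])
  if (!is.null(cell_id)) out <- dplyr::mutate(out, cell_id = cell_id, .before = 1)
  out
}

#' Summarise yields per time bin across cells
#'
#' @param yields Row-bound [contraction_yield()] tables from several cells.
#' @return Per-bin `mean`, `sem`, `n`.
#' @export
yield_by_bin <- function(yields) {
  yields |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$yield),
                     sem = sd(.data$yield) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Perimeter fold change
#'
#' @param perimeter_t0,perimeter_t1 Perimeters at the two time points
#'   (vectorised).
#' @return `perimeter_t1 / perimeter_t0`; a zero baseline gives `NA` with a
#'   warning.
#' @export
perimeter_fold_change <- function(perimeter_t0, perimeter_t1) {
  out <- perimeter_t1 / perimeter_t0
  bad <- !is.finite(perimeter_t0) | perimeter_t0 == 0
  if (any(bad)) {
    warn("zero or undefined baseline perimeter; returning NA")
    out[bad] <- NA_real_
  }
  out
}

#' Extrusion duration and cohort histogram
#'
#' The duration of an extrusion is the time from the constriction onset
#' (inflection point) to the end of extrusion.
#'
#' @param onset_time,end_time Times in minutes (vectorised; `onset_time <
#'   end_time`).
#' @return Durations in minutes.
#' @export
extrusion_duration <- function(onset_time, end_time) {
  if (any(onset_time >= end_time)) {
    abort("`onset_time` must precede `end_time`", class = "extrudr_ordering_error")
  }
  end_time - onset_time
}

#' @rdname extrusion_duration
#' @param durations Cohort of durations (minutes).
#' @param bin_width Histogram bin width in minutes (default 10).
#' @return `duration_histogram()`: a tibble with `bin` (left edge), `count`
#'   and `fraction` (normalised by the number of observed extrusions, so the
#'   fractions sum to 1).
#' @export
duration_histogram <- function(durations, bin_width = 10) {
  bin <- floor(durations / bin_width) * bin_width
  tibble(bin = sort(unique(bin))) |>
    dplyr::mutate(count = vapply(.data$bin, function(b) sum(bin == b), 0L),
                  fraction = .data$count / length(durations))
}

#' Cell-elimination proportions, confidence intervals and Fisher tests
#'
#' For each compartment, the proportion of eliminated (extruded) cells with
#' a binomial confidence interval; for each pair of compartments, the
#' two-sided Fisher exact p-value computed by hypergeometric enumeration
#' (summing the probabilities of all tables with the same margins that are
#' no more probable than the observed one).
#'
#' @param counts Tibble with columns `compartment`, `extrusions`, `cells`.
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return A list: `$proportions` (per-compartment `proportion`, `ci_lo`,
#'   `ci_hi`) and `$tests` (pairwise `p_value`).
#' @export
elimination_stats <- function(counts, conf_level = 0.95,
                              ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (any(counts$extrusions < 0 | counts$cells < 0 |
          counts$extrusions > counts$cells) ||
      any(counts$extrusions != round(counts$extrusions)) ||
      any(counts$cells != round(counts$cells))) {
    abort("counts must be integers with 0 <= extrusions <= cells",
          class = "extrudr_parameter_error")
  }
  props <- counts |>
    dplyr::rowwise() |>
    dplyr::mutate(
      proportion = if (.data$cells > 0) .data$extrusions / .data$cells else {
        NA_real_
      },
      ci = list(binom_ci(.data$extrusions, .data$cells, conf_level, ci_method)),
      ci_lo = .data$ci[1], ci_hi = .data$ci[2]) |>
    dplyr::ungroup() |>
    dplyr::select(-"ci")
  if (any(counts$cells == 0)) warn("compartment with zero cells: proportion undefined")
  pairs <- utils::combn(seq_len(nrow(counts)), 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tibble(compartment_a = counts$compartment[i1],
           compartment_b = counts$compartment[i2],
           p_value = fisher_exact_2x2(
             counts$extrusions[i1], counts$cells[i1] - counts$extrusions[i1],
             counts$extrusions[i2], counts$cells[i2] - counts$extrusions[i2]))
  })
  list(proportions = props, tests = tests)
}

binom_ci <- function(x, n, conf_level, method) {
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "clopper-pearson") {
    as.double(binom.test(x, n, conf.level = conf_level)$conf.int)
  } else {
    z <- qnorm(1 - (1 - conf_level) / 2)
    p <- x / n
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, centre - half), min(1, centre + half))
  }
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins and sums the probabilities of tables no more probable
#' than the observed one.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m1 <- a + b          # row 1 total
  n1 <- a + c          # column 1 total
  N <- a + b + c + d
  k <- max(0, n1 - (N - m1)):min(n1, m1)
  probs <- dhyper(k, m1, N - m1, n1)
  p_obs <- dhyper(a, m1, N - m1, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Normality-dispatched two-group comparison
#'
#' Runs the Shapiro-Wilk normality check on both samples; if both pass at
#' the 0.05 level the comparison is a t test (paired or unpaired per
#' `design`), otherwise a rank-based test (Mann-Whitney for unpaired,
#' Wilcoxon signed-rank for paired).
#'
#' @param sample_a,sample_b Numeric samples (>= 3 values each).
#' @param design `"unpaired"` (default) or `"paired"`.
#' @return A one-row tibble: `test` (which test fired), `p_value`,
#'   `shapiro_p_a`, `shapiro_p_b`, `degenerate` (constant input flag).
#' @export
compare_groups <- function(sample_a, sample_b,
                           design = c("unpaired", "paired")) {
  design <- match.arg(design)
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    abort("each sample needs at least 3 values", class = "extrudr_parameter_error")
  }
  degenerate <- sd(sample_a) == 0 || sd(sample_b) == 0
  sw <- function(x) {
    if (sd(x) == 0) return(0)  # constant: certainly not Gaussian-dispatched
    shapiro.test(x)$p.value
  }
  pa <- sw(sample_a); pb <- sw(sample_b)
  paired <- design == "paired"
  if (pa > 0.05 && pb > 0.05) {
    test <- if (paired) "paired t" else "t"
    p <- t.test(sample_a, sample_b, paired = paired)$p.value
  } else {
    test <- if (paired) "wilcoxon signed-rank" else "mann-whitney"
    p <- suppressWarnings(
      wilcox.test(sample_a, sample_b, paired = paired, exact = FALSE)$p.value)
  }
  tibble(test = test, p_value = p, shapiro_p_a = pa, shapiro_p_b = pb,
         degenerate = degenerate)
}
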