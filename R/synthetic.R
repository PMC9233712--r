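#' Specification for a synthetic extrusion cohort
#'
#' Parameters of the synthetic traces the analysis pipeline is validated
#' against: a perimeter plateau followed by a linear constriction to zero at
#' a known onset, Poisson-timed Gaussian myosin pulses driving the
#' contraction rate with a known gain and lag, a yield change at the onset,
#' and additive Gaussian noise.
#'
#' @param n_cells Number of cells in a cohort.
#' @param frame_interval Frame interval in minutes (1 or 5 in practice).
#' @param duration Trace span in minutes.
#' @param plateau Pre-onset perimeter level.
#' @param onset_min,onset_max Uniform support of the constriction onset
#'   (minutes).
#' @param slope Post-onset perimeter slope (units/min; negative).
#' @param pulse_rate Myosin pulse rate (per minute).
#' @param pulse_amplitude Pulse amplitude (intensity units).
#' @param pulse_sigma Pulse width parameter sigma (minutes).
#' @param baseline Myosin baseline intensity.
#' @param gain Myosin-to-contraction coupling gain.
#' @param lag Coupling lag in frames (integer).
#' @param yield_multiplier Factor applied to the gain after the onset.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed; all generators are deterministic per seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_cells = 50L, frame_interval = 1, duration = 200,
                       plateau = 100, onset_min = 60, onset_max = 140,
                       slope = -2, pulse_rate = 0.05, pulse_amplitude = 10,
                       pulse_sigma = 2, baseline = 5, gain = 0.02, lag = 3L,
                       yield_multiplier = 1, noise_sd = 0, seed = 1L) {
  if (pulse_rate < 0 || noise_sd < 0 || pulse_sigma <= 0) {
    abort("rates and spreads must be non-negative", class = "extrudr_spec_error")
  }
  if (lag != round(lag)) {
    abort("`lag` must be an integer number of frames", class = "extrudr_spec_error")
  }
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate one perimeter trace with a known constriction onset
#'
#' Perimeter = plateau + noise before the onset, then a linear decline at
#' `slope` until it reaches 0 (the end of extrusion), where the trace stops.
#'
#' @param spec A [synth_spec()].
#' @param onset Onset time in minutes (default: drawn uniformly from the
#'   spec's onset window).
#' @param seed Optional seed override.
#' @return A list: `trace` (tibble `time_min`, `value`) and `truth`
#'   (tibble `onset`, `end`, `duration`, `slope`, `plateau`).
#' @export
gen_extrusion_trace <- function(spec = synth_spec(), onset = NULL,
                                seed = spec$seed) {
  if (spec$slope == 0) {
    abort("zero slope cannot reach the end of extrusion",
          class = "extrudr_spec_error")
  }
  set.seed(seed)
  dt <- spec$frame_interval
  if (is.null(onset)) onset <- runif(1, spec$onset_min, spec$onset_max)
  # end of extrusion = first frame with no apical perimeter left
  end <- ceiling((onset + spec$plateau / abs(spec$slope)) / dt) * dt
  t <- seq(0, end, by = dt)
  clean <- ifelse(t < onset, spec$plateau,
                  pmax(0, spec$plateau + spec$slope * (t - onset)))
  value <- clean + rnorm(length(t), 0, spec$noise_sd) * (clean > 0)
  list(trace = tibble(time_min = t, value = value),
       truth = tibble(onset = onset, end = end, duration = end - onset,
                      slope = spec$slope, plateau = spec$plateau))
}

#' Generate a coupled myosin/perimeter pair
#'
#' Myosin is a baseline plus Poisson-timed Gaussian pulses plus noise. The
#' contraction rate is `gain * myosin(t - lag)` (with the gain multiplied by
#' `yield_multiplier` from the onset on), and the perimeter integrates the
#' negative contraction rate from the plateau.
#'
#' @param spec A [synth_spec()].
#' @param onset Onset time (default: middle of the spec's onset window).
#' @param seed Optional seed override.
#' @return A list: `myosin` and `perimeter` trace tibbles and `truth`
#'   (pulse times/amplitudes, `lag_frames`, `lag_min`, `gain`,
#'   `yield_multiplier`, `onset`).
#' @export
gen_pulsatile_pair <- function(spec = synth_spec(),
                               onset = (spec$onset_min + spec$onset_max) / 2,
                               seed = spec$seed) {
  set.seed(seed)
  dt <- spec$frame_interval
  t <- seq(0, spec$duration, by = dt)
  n <- length(t)
  if (spec$lag >= n) {
    abort("lag exceeds the trace length", class = "extrudr_spec_error")
  }
  n_pulses <- rpois(1, spec$pulse_rate * spec$duration)
  pulse_times <- sort(runif(n_pulses, 0, spec$duration))
  clean <- rep(spec$baseline, n)
  for (pt in pulse_times) {
    clean <- clean + spec$pulse_amplitude * exp(-(t - pt)^2 / (2 * spec$pulse_sigma^2))
  }
  myosin <- clean + rnorm(n, 0, spec$noise_sd)
  lagged <- dplyr::lag(clean, spec$lag, default = spec$baseline)
  gain_t <- spec$gain * ifelse(t >= onset, spec$yield_multiplier, 1)
  contraction <- gain_t * lagged
  # forward-Euler integration, so finite differences recover the planted
  # contraction rate (and its lag) exactly
  perimeter <- spec$plateau - cumsum(c(0, contraction[-n])) * dt
  list(myosin = tibble(time_min = t, value = myosin),
       perimeter = tibble(time_min = t, value = perimeter),
       truth = list(pulse_times = pulse_times,
                    pulse_amplitude = spec$pulse_amplitude,
                    lag_frames = spec$lag, lag_min = spec$lag * dt,
                    gain = spec$gain, yield_multiplier = spec$yield_multiplier,
                    onset = onset))
}

#' Generate a synthetic two-channel radial image stack
#'
#' Per frame: a bright ring (junction channel) at the scheduled radius and a
#' medial disk (signal channel) at the scheduled level, plus optional
#' Gaussian noise. Emulates a constricting junctional contour with a
#' medio-apical pool whose level can drop at a known time.
#'
#' @param ring_radius Per-frame ring radius in pixels (vector).
#' @param medial_level Per-frame medial intensity (vector, recycled).
#' @param image_size Square image side in pixels (default 64).
#' @param ring_value Junction intensity on the ring (default 10).
#' @param ring_thickness Radial thickness of the ring in px (default 2).
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param seed Integer seed.
#' @return A list: `junction` and `signal` (3D arrays `[row, col, frame]`),
#'   `centre` (image centre), and `truth` (per-frame `radius`,
#'   `medial_level`).
#' @export
gen_radial_stack <- function(ring_radius, medial_level = 5, image_size = 64,
                             ring_value = 10, ring_thickness = 2,
                             noise_sd = 0, seed = 1L) {
  if (any(!is.finite(ring_radius))) {
    abort("ring radius schedule must be finite", class = "extrudr_spec_error")
  }
  if (any(ring_radius >= image_size / 2)) {
    abort("ring radius must fit inside the image", class = "extrudr_spec_error")
  }
  set.seed(seed)
  nt <- length(ring_radius)
  medial_level <- rep_len(medial_level, nt)
  centre <- (image_size + 1) / 2
  xg <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
  yg <- matrix(seq_len(image_size), image_size, image_size)
  d <- sqrt((xg - centre)^2 + (yg - centre)^2)
  junction <- array(0, c(image_size, image_size, nt))
  signal <- array(0, c(image_size, image_size, nt))
  for (f in seq_len(nt)) {
    ring <- abs(d - ring_radius[f]) <= ring_thickness / 2
    disk <- d < ring_radius[f]
    junction[, , f] <- ring * ring_value + rnorm(length(d), 0, noise_sd)
    signal[, , f] <- disk * medial_level[f] + rnorm(length(d), 0, noise_sd)
  }
  list(junction = junction, signal = signal, centre = c(centre, centre),
       truth = tibble(frame = seq_len(nt), radius = ring_radius,
                      medial_level = medial_level))
}

#' Generate a cohort of extrusion traces with jittered onsets
#'
#' Draws `spec$n_cells` i.i.d. traces from [gen_extrusion_trace()], each
#' with its own onset (and hence end), and returns the long trace table plus
#' a per-cell ground-truth table.
#'
#' @param spec A [synth_spec()].
#' @param duration_multiplier Multiplies every extrusion duration (slows the
#'   post-onset slope), emulating e.g. a drug-slowed cohort.
#' @param seed Optional seed override.
#' @return A list: `traces` (long tibble `cell_id`, `time_min`, `value`) and
#'   `truth` (one row per cell: `cell_id`, `onset`, `end`, `duration`).
#' @export
gen_cohort <- function(spec = synth_spec(), duration_multiplier = 1,
                       seed = spec$seed) {
  set.seed(seed)
  onsets <- runif(spec$n_cells, spec$onset_min, spec$onset_max)
  cell_seeds <- sample.int(.Machine$integer.max, spec$n_cells)
  spec2 <- spec
  spec2$slope <- spec$slope / duration_multiplier
  out <- purrr::map(seq_len(spec$n_cells), function(i) {
    gen_extrusion_trace(spec2, onset = onsets[i], seed = cell_seeds[i])
  })
  traces <- purrr::map_dfr(seq_along(out), function(i) {
    dplyr::mutate(out[[i]]$trace, cell_id = i, .before = 1)
  })
  truth <- purrr::map_dfr(seq_along(out), function(i) {
    dplyr::mutate(out[[i]]$truth, cell_id = i, .before = 1)
  })
  list(traces = traces, truth = truth)
}
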