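#' Simulation configuration presets
#'
#' Bundles every knob of a simulation run. The `"paper"` preset is the
#' full-scale experiment (1141 cells, 130000 iterations per sts, 50 sts,
#' ramps from sts 20, 10 tracked cells); the `"small"` preset is a
#' desk-scale variant (300 cells, 13000 iterations per sts) used for fast
#' property checks, with ramp rates rescaled to the same per-sts factor via
#' [scale_rate()].
#'
#' The default `initial_area_ratio` of 3.7 starts the tissue pre-stretched:
#' the reported initial tracked-cell shape (perimeter 7.58 at circularity
#' 0.81) implies a mean initial area of about `C P^2 / 4 pi ~ 3.7`
#' resting-area units. The pre-stretch is what lets a contractility ramp
#' round cells up (perimeter drops while the stretched neighbourhood holds
#' the area); a tissue started at its resting area relaxes to near-regular
#' polygons whose circularity barely responds.
#'
#' @param preset `"paper"` or `"small"`.
#' @param ... Named overrides of any configuration field.
#' @return A list of class `sim_config` with fields `n_cells`, `n_tracked`,
#'   `min_boundary_distance`, `lloyd_steps`, `initial_area_ratio`, the
#'   [model_params()] fields, `ramp_start_sts`, `total_sts`.
#' @export
sim_config <- function(preset = c("paper", "small"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_cells = 1141L, n_tracked = 10L, min_boundary_distance = 3L,
    lloyd_steps = 3L, initial_area_ratio = 3.7,
    line_tension_tilde = 0.06, contractility_tilde = 0.02,
    boundary_tension_factor = 1.6, p_accept = 0.05, delta_max = 0.005,
    d_min = 0.2, iterations_per_sts = 130000L, a0_min = 1e-3,
    t1_new_length = 0.21, t1_check_interval = 100L,
    proposal_mode = "symmetric",
    ramp_start_sts = 20L, total_sts = 50L)
  if (preset == "small") {
    cfg$n_cells <- 300L
    cfg$iterations_per_sts <- 13000L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")),
          class = "extrudr_parameter_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

#' Model parameters of a configuration
#'
#' @param cfg A [sim_config()].
#' @return The corresponding [model_params()].
#' @export
config_params <- function(cfg) {
  model_params(
    line_tension_tilde = cfg$line_tension_tilde,
    contractility_tilde = cfg$contractility_tilde,
    boundary_tension_factor = cfg$boundary_tension_factor,
    p_accept = cfg$p_accept, delta_max = cfg$delta_max, d_min = cfg$d_min,
    iterations_per_sts = cfg$iterations_per_sts, a0_min = cfg$a0_min,
    t1_new_length = cfg$t1_new_length,
    t1_check_interval = cfg$t1_check_interval,
    proposal_mode = cfg$proposal_mode)
}

#' Build and track the initial tissue of a configuration
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (drives both the tessellation and the tracked-cell
#'   draw).
#' @return A `tissue_mesh` with `n_tracked` interior cells flagged.
#' @export
config_tissue <- function(cfg, seed) {
  mesh <- build_initial_tissue(cfg$n_cells, seed = seed,
                               initial_area_ratio = cfg$initial_area_ratio,
                               lloyd_steps = cfg$lloyd_steps,
                               params = config_params(cfg))
  select_tracked_cells(mesh, cfg$n_tracked, seed = seed + 1L,
                       min_boundary_distance = cfg$min_boundary_distance)
}

#' Run a condition/rate/seed sweep
#'
#' Runs one simulation per (condition, rate, seed) combination. For a given
#' seed, every condition starts from the *same* initial mesh and tracked-cell
#' set and consumes the same random stream (a paired design), so trajectories
#' are identical up to the ramp start. Ramp rates are given on the reference
#' clock (130000 iterations/sts) and rescaled to the configured clock so the
#' per-sts ramp factor matches.
#'
#' @param cfg A [sim_config()].
#' @param conditions Character vector of conditions to run
#'   (`"contractility"`, `"resting_area"`; `"control"` is the rate-0 member
#'   of either grid).
#' @param rates Numeric vector of per-iteration rates on the reference clock,
#'   or a named list with one rate vector per condition.
#' @param seeds Integer vector of seeds.
#' @param rates_reference_iters Clock the rates refer to (default 130000).
#' @return A `sweep_result`: a tibble with one row per (condition, rate,
#'   seed, sts) carrying `mean_P`, `sem_P`, `mean_C`, `sem_C`, `n`, `status`.
#'   Failed runs are recorded with `status = "error"` and the sweep
#'   continues.
#' @export
run_sweep <- function(cfg = sim_config("small"),
                      conditions = c("contractility", "resting_area"),
                      rates = list(contractility = c(0, 1, 2.5, 5, 7.5) * 1e-7,
                                   resting_area = c(0, 0.5, 1, 2.5, 3.5) * 1e-4),
                      seeds = 1:5,
                      rates_reference_iters = 130000) {
  if (!is.list(rates)) {
    rates <- stats::setNames(rep(list(rates), length(conditions)), conditions)
  }
  grids <- purrr::map_dfr(conditions, function(cond) {
    tibble(condition = cond, rate_ref = rates[[cond]])
  })
  out <- purrr::map_dfr(seeds, function(seed) {
    mesh <- config_tissue(cfg, seed)
    purrr::map_dfr(seq_len(nrow(grids)), function(i) {
      cond <- grids$condition[i]
      rate_ref <- grids$rate_ref[i]
      rate <- if (rate_ref == 0) 0 else {
        scale_rate(rate_ref, condition = cond,
                   from_iters = rates_reference_iters,
                   to_iters = cfg$iterations_per_sts)
      }
      sched <- rate_schedule(
        condition = if (rate_ref == 0) "control" else cond,
        rate = rate, ramp_start_sts = cfg$ramp_start_sts,
        total_sts = cfg$total_sts)
      res <- tryCatch(
        run_simulation(mesh, config_params(cfg), sched, seed = seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        tibble(condition = cond, rate_ref = rate_ref, rate = rate,
               seed = seed, sts = NA_real_, mean_P = NA_real_,
               sem_P = NA_real_, mean_C = NA_real_, sem_C = NA_real_,
               n = NA_integer_, status = paste("error:", conditionMessage(res)))
      } else {
        dplyr::mutate(res$summary, condition = cond, rate_ref = rate_ref,
                      rate = rate, seed = seed, status = "ok",
                      .before = 1)
      }
    })
  })
  class(out) <- c("sweep_result", class(out))
  out
}

#' Classify the extrusion regime of a run
#'
#' Compares tracked-cell perimeter and circularity between the start and end
#' of an observation window (defaults: sts 20 to 40). A run is
#' `"tension-like"` if the perimeter decreases while circularity rises
#' (purse-string signature), `"resting-area-like"` if the perimeter
#' decreases while circularity falls, and `"none"` otherwise. The
#' circularity change must exceed `sem_factor` times its SEM to count.
#'
#' @param summary A per-sts summary tibble for one run (columns `sts`,
#'   `mean_P`, `mean_C`, `sem_C`), e.g. `run_simulation(...)$summary` or one
#'   group of a [run_sweep()] result.
#' @param window Length-2 sts window (default `c(20, 40)`).
#' @param sem_factor Threshold on `|delta C| / SEM(C)` (default 2).
#' @return A one-row tibble: `delta_P`, `delta_C`, `sem_C`, `regime`.
#' @export
regime_signature <- function(summary, window = c(20, 40), sem_factor = 2) {
  if (!all(window %in% summary$sts)) {
    abort("observation window outside the available sts range",
          class = "extrudr_range_error")
  }
  s0 <- summary[summary$sts == window[1], ]
  s1 <- summary[summary$sts == window[2], ]
  dP <- s1$mean_P - s0$mean_P
  dC <- s1$mean_C - s0$mean_C
  sem <- sqrt(s0$sem_C^2 + s1$sem_C^2)
  regime <- if (dP < 0 && dC > sem_factor * sem) "tension-like"
  else if (dP < 0 && dC < -sem_factor * sem) "resting-area-like"
  else "none"
  tibble(delta_P = dP, delta_C = dC, sem_C = sem, regime = regime)
}

#' Classify every run of a sweep
#'
#' @param sweep A [run_sweep()] result.
#' @inheritParams regime_signature
#' @return A tibble with one row per (condition, rate, seed) and the
#'   [regime_signature()] columns.
#' @export
classify_sweep <- function(sweep, window = c(20, 40), sem_factor = 2) {
  sweep |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$condition, .data$rate_ref, .data$seed) |>
    dplyr::group_modify(~ regime_signature(.x, window, sem_factor)) |>
    dplyr::ungroup()
}

#' @export
autoplot.sweep_result <- function(object, observable = c("mean_P", "mean_C"),
                                  ...) {
  observable <- match.arg(observable)
  ok <- dplyr::filter(object, .data$status == "ok")
  ggplot2::ggplot(ok, ggplot2::aes(.data$sts, .data[[observable]],
                                   colour = factor(.data$rate_ref),
                                   group = interaction(.data$rate_ref, .data$seed))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(colour = "rate (reference clock)",
                  x = "simulation time step",
                  y = if (observable == "mean_P") "mean tracked perimeter"
                  else "mean tracked circularity")
}
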