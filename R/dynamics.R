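#' Extrusion protocol (parameter-ramp schedule)
#'
#' Defines which per-cell parameter is ramped during a run, at what
#' per-iteration rate, and over which window. Under the `"contractility"`
#' condition the tracked cells' contractility grows geometrically,
#' \eqn{\tilde\Gamma \leftarrow \tilde\Gamma (1 + c)} per iteration
#' (purse-string-like constriction); under `"resting_area"` their resting
#' area shrinks, \eqn{A^{(0)} \leftarrow A^{(0)} (1 - r)} per iteration.
#' `"control"` ramps nothing.
#'
#' @param condition One of `"control"`, `"contractility"`, `"resting_area"`.
#' @param rate Per-iteration rate (`c` or `r`; ignored for control). Must be
#'   non-negative.
#' @param ramp_start_sts Simulation time step at which the ramp switches on
#'   (default 20).
#' @param total_sts Total run length in simulation time steps (default 50).
#' @return A list of class `rate_schedule`.
#' @export
rate_schedule <- function(condition = c("control", "contractility", "resting_area"),
                          rate = 0, ramp_start_sts = 20L, total_sts = 50L) {
  condition <- match.arg(condition)
  if (!is.finite(rate) || rate < 0) {
    abort("`rate` must be non-negative", class = "extrudr_parameter_error")
  }
  if (ramp_start_sts >= total_sts) {
    abort("`ramp_start_sts` must be below `total_sts`",
          class = "extrudr_parameter_error")
  }
  structure(list(condition = condition, rate = rate,
                 ramp_start_sts = as.integer(ramp_start_sts),
                 total_sts = as.integer(total_sts)),
            class = "rate_schedule")
}

schedule_for_cpp <- function(schedule, mesh, params, sts_offset = 0) {
  cond <- match(schedule$condition, c("control", "contractility", "resting_area")) - 1L
  list(condition = cond, rate = schedule$rate,
       ramp_start_iter = as.double(schedule$ramp_start_sts) *
         as.double(params$iterations_per_sts),
       targets = which(mesh$tracked))
}

#' Apply one iteration of the parameter ramp
#'
#' Updates the tracked cells' parameters for a single global iteration:
#' geometric growth of contractility or geometric decay of resting area (see
#' [rate_schedule()]). After `n` update iterations the closed forms are
#' \eqn{\tilde\Gamma_0 (1+c)^n} and \eqn{A^{(0)}_0 (1-r)^n}.
#'
#' @param mesh A `tissue_mesh` with tracked cells flagged.
#' @param schedule A [rate_schedule()].
#' @param iteration Zero-based global iteration index; no update happens
#'   before `ramp_start_sts * iterations_per_sts`.
#' @param params A [model_params()] (supplies `iterations_per_sts`).
#' @return The updated mesh.
#' @export
apply_ramps <- function(mesh, schedule, iteration, params = model_params()) {
  if (schedule$condition == "control") return(mesh)
  start <- as.double(schedule$ramp_start_sts) * as.double(params$iterations_per_sts)
  if (iteration < start) return(mesh)
  targets <- which(mesh$tracked)
  if (schedule$condition == "contractility") {
    mesh$contractility[targets] <- mesh$contractility[targets] * (1 + schedule$rate)
  } else {
    mesh$resting_area[targets] <- mesh$resting_area[targets] * (1 - schedule$rate)
  }
  mesh
}

#' Closed-form ramp factor
#'
#' Multiplicative factor applied to the ramped parameter after `n` update
#' iterations: `(1 + rate)^n` for contractility, `(1 - rate)^n` for resting
#' area.
#'
#' @param rate Per-iteration rate.
#' @param n Number of update iterations.
#' @param condition `"contractility"` or `"resting_area"`.
#' @return The multiplicative factor.
#' @export
ramp_factor <- function(rate, n, condition = c("contractility", "resting_area")) {
  condition <- match.arg(condition)
  sgn <- if (condition == "contractility") 1 else -1
  exp(n * log1p(sgn * rate))
}

#' Convert a ramp rate between simulation clocks
#'
#' Ramp rates are defined per vertex iteration; runs with a different number
#' of iterations per simulation time step (e.g. the desk-scale preset) use
#' the rate giving the *same per-sts ramp factor* as the reference clock.
#'
#' @param rate Per-iteration rate on the reference clock.
#' @param condition `"contractility"` or `"resting_area"`.
#' @param from_iters Iterations per sts of the reference clock
#'   (default 130000).
#' @param to_iters Iterations per sts of the target clock.
#' @return The equivalent per-iteration rate on the target clock.
#' @export
scale_rate <- function(rate, condition = c("contractility", "resting_area"),
                       from_iters = 130000, to_iters) {
  condition <- match.arg(condition)
  ratio <- from_iters / to_iters
  if (condition == "contractility") expm1(ratio * log1p(rate))
  else -expm1(ratio * log1p(-rate))
}

#' One Metropolis vertex move
#'
#' Picks one vertex uniformly at random, draws a trial displacement (see
#' `proposal_mode` in [model_params()]), and applies the Metropolis rule:
#' moves that lower the energy are always accepted; moves that raise it are
#' accepted with probability `p_accept`; proposals that would make an
#' incident face non-simple or non-positive in area are rejected outright.
#' Uses R's RNG, so call `set.seed()` for reproducibility.
#'
#' @param state A simulation state from [simulation_state()].
#' @param params A [model_params()].
#' @return The updated state; `state$last_accepted` reports the outcome.
#' @export
metropolis_step <- function(state, params = model_params()) {
  res <- cpp_run(unclass(state$mesh), unclass(params),
                 list(condition = 0L, rate = 0, ramp_start_iter = Inf,
                      targets = integer()),
                 n_iterations = 1L, iterations_per_sts = 0L,
                 sts_offset = 0L, enable_t1 = FALSE, record = FALSE)
  state$mesh <- restore_mesh(res$mesh, state$mesh)
  state$iteration <- state$iteration + 1L
  state$accepted <- state$accepted + res$accepted
  state$rejected <- state$rejected + res$rejected + res$rejected_geometry
  state$delta_sum <- state$delta_sum + res$delta_sum
  state$last_accepted <- res$accepted > 0
  state
}

#' Create a simulation state
#'
#' Bundles a mesh with the iteration/time-step counters and move statistics
#' carried through a run.
#'
#' @param mesh A `tissue_mesh`.
#' @return A list of class `simulation_state`.
#' @export
simulation_state <- function(mesh) {
  structure(list(mesh = mesh, iteration = 0L, sts = 0L,
                 accepted = 0, rejected = 0, t1_count = 0, delta_sum = 0,
                 last_accepted = NA),
            class = "simulation_state")
}

restore_mesh <- function(mesh_list, template) {
  m <- template
  m$vertices <- mesh_list$vertices
  colnames(m$vertices) <- c("x", "y")
  m$faces <- lapply(mesh_list$faces, as.integer)
  m$resting_area <- mesh_list$resting_area
  m$contractility <- mesh_list$contractility
  m
}

#' T1 neighbour exchanges on short edges
#'
#' Sweeps all internal edges shorter than `d_min` and rewires each
#' energetically admissible one in the standard T1 way: the two cells
#' sharing the edge lose their adjacency, the two cells at its endpoints
#' become neighbours, and the new junction opens orthogonally to the old one
#' at length `t1_new_length`. A rewiring that raises the energy is performed
#' with probability `p_accept` (same rule as vertex moves); one that would
#' create a face with fewer than 3 vertices is skipped. Face count and disk
#' topology are preserved.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A [model_params()].
#' @return A list: `mesh` (updated), `n_rewired`, `n_skipped` and
#'   `energy_delta`.
#' @export
t1_transitions <- function(mesh, params = model_params()) {
  res <- cpp_t1_sweep(unclass(mesh), unclass(params), params$d_min,
                      params$t1_new_length, params$p_accept)
  list(mesh = restore_mesh(res$mesh, mesh),
       n_rewired = res$n_rewired, n_skipped = res$n_skipped,
       energy_delta = res$energy_delta)
}

#' Run a vertex-model simulation
#'
#' Executes `total_sts * iterations_per_sts` Metropolis vertex iterations
#' with periodic T1 sweeps and the per-iteration parameter ramps of the
#' schedule, recording the tracked cells' perimeter, area and circularity
#' once per simulation time step (sts). Deterministic for a fixed seed.
#'
#' @param mesh A `tissue_mesh` with tracked cells flagged (see
#'   [select_tracked_cells()]).
#' @param params A [model_params()].
#' @param schedule A [rate_schedule()].
#' @param seed Integer seed.
#' @param enable_t1 Perform T1 transitions (default `TRUE`)?
#' @return An object of class `extr_sim`: observables tibble (`sts`, `cell`,
#'   `perimeter`, `area`, `circularity`), summary tibble (per-sts mean and
#'   SEM over tracked cells), counters, the final mesh, and the energy
#'   bookkeeping (initial/final energy and the running sum of applied energy
#'   changes).
#' @export
run_simulation <- function(mesh, params = model_params(),
                           schedule = rate_schedule(), seed = 1L,
                           enable_t1 = TRUE) {
  if (!any(mesh$tracked) && schedule$condition != "control") {
    abort("schedule requires tracked target cells", class = "extrudr_parameter_error")
  }
  set.seed(seed)
  n_iter <- as.double(schedule$total_sts) * as.double(params$iterations_per_sts)
  res <- cpp_run(unclass(mesh), unclass(params),
                 schedule_for_cpp(schedule, mesh, params),
                 n_iterations = as.integer(n_iter),
                 iterations_per_sts = params$iterations_per_sts,
                 sts_offset = 0L, enable_t1 = enable_t1, record = TRUE)
  final_mesh <- restore_mesh(res$mesh, mesh)
  obs <- as_tibble(res$observables)
  structure(
    list(observables = obs,
         summary = summarize_tracked(obs),
         counters = tibble(
           accepted = res$accepted, rejected = res$rejected,
           rejected_geometry = res$rejected_geometry,
           acceptance_rate = res$accepted /
             (res$accepted + res$rejected + res$rejected_geometry),
           t1_count = res$t1_count, t1_skipped = res$t1_skipped,
           max_displacement = res$max_displacement),
         energy = tibble(initial = res$energy_initial, final = res$energy_final,
                         delta_sum = res$delta_sum),
         final_mesh = final_mesh,
         params = params, schedule = schedule, seed = seed),
    class = "extr_sim")
}

#' Per-sts mean and SEM over tracked cells
#'
#' @param observables Tibble with columns `sts`, `cell`, `perimeter`,
#'   `circularity` (as produced by [run_simulation()]).
#' @return A tibble with per-sts `mean_P`, `sem_P`, `mean_C`, `sem_C`, `n`.
#' @export
summarize_tracked <- function(observables) {
  observables |>
    dplyr::group_by(.data$sts) |>
    dplyr::summarise(
      mean_P = mean(.data$perimeter),
      sem_P = sd(.data$perimeter) / sqrt(dplyr::n()),
      mean_C = mean(.data$circularity),
      sem_C = sd(.data$circularity) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
}

#' @export
print.extr_sim <- function(x, ...) {
  cat(sprintf("<extr_sim> %s run, rate %.3g, %d sts x %d iterations, seed %d\n",
              x$schedule$condition, x$schedule$rate, x$schedule$total_sts,
              x$params$iterations_per_sts, x$seed))
  cat(sprintf("  acceptance rate %.3f, %d T1 transitions\n",
              x$counters$acceptance_rate, as.integer(x$counters$t1_count)))
  invisible(x)
}

#' @export
tidy.extr_sim <- function(x, ...) x$observables

#' @export
glance.extr_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble(condition = x$schedule$condition, rate = x$schedule$rate,
           seed = x$seed, total_sts = x$schedule$total_sts),
    x$counters, x$energy)
}

#' @export
autoplot.extr_sim <- function(object, ...) {
  long <- object$summary |>
    tidyr::pivot_longer(c("mean_P", "mean_C"), names_to = "observable",
                        values_to = "value") |>
    dplyr::mutate(observable = dplyr::recode(.data$observable,
                                             mean_P = "perimeter",
                                             mean_C = "circularity"))
  ggplot2::ggplot(long, ggplot2::aes(.data$sts, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$schedule$ramp_start_sts,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "simulation time step", y = NULL)
}
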