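#' Mechanical parameters of the dimensionless vertex model
#'
#' Collects the parameters of the dimensionless tissue energy
#' \deqn{E = \sum_\alpha \tfrac12 (A_\alpha/A_\alpha^{(0)} - 1)^2
#'       + \sum_{(i,j)} \tilde\Lambda_{ij}\, l_{ij}
#'       + \sum_\alpha \tfrac{\tilde\Gamma_\alpha}{2} L_\alpha^2}
#' together with the Monte-Carlo move parameters. Lengths are measured in
#' units of the square root of the initial resting area, so the area
#' elasticity modulus is fixed to 1 by the nondimensionalisation.
#'
#' @param line_tension_tilde Dimensionless line tension of internal edges
#'   (default 0.06).
#' @param contractility_tilde Dimensionless perimeter contractility used for
#'   every cell at initialisation (default 0.02).
#' @param boundary_tension_factor Multiplier on the line tension of edges on
#'   the external tissue boundary (default 1.6), which stiffens the boundary
#'   against buckling.
#' @param p_accept Probability of accepting an energy-increasing trial move
#'   (default 0.05).
#' @param delta_max Maximum trial displacement per coordinate, in units of
#'   the cell-length scale (default 0.005).
#' @param d_min Edge length below which a T1 neighbour exchange may trigger
#'   (default 0.2). Must exceed `delta_max`.
#' @param iterations_per_sts Number of vertex iterations per simulation time
#'   step (default 130000).
#' @param a0_min Resting-area floor below which the relative elastic term
#'   \eqn{\frac12 (A/A^{(0)} - 1)^2} (which diverges as \eqn{A^{(0)} \to 0})
#'   switches to the dimensional form \eqn{\frac12 (A - A^{(0)})^2}
#'   (default 1e-3).
#' @param t1_new_length Length of the re-opened junction after a T1
#'   transition (default `1.05 * d_min`, preventing immediate re-triggering).
#' @param t1_check_interval T1 eligibility is swept once every this many
#'   vertex iterations (default 100).
#' @param proposal_mode `"symmetric"` (default): the two displacement
#'   components are drawn independently and uniformly from
#'   `[-delta_max, delta_max]`. `"literal"`: a single displacement
#'   `d ~ U[0, delta_max]` is added to both coordinates, which biases motion
#'   along the (+x, +y) diagonal and is kept only for comparison.
#' @return A list of class `model_params`.
#' @export
model_params <- function(line_tension_tilde = 0.06,
                         contractility_tilde = 0.02,
                         boundary_tension_factor = 1.6,
                         p_accept = 0.05,
                         delta_max = 0.005,
                         d_min = 0.2,
                         iterations_per_sts = 130000L,
                         a0_min = 1e-3,
                         t1_new_length = 1.05 * d_min,
                         t1_check_interval = 100L,
                         proposal_mode = c("symmetric", "literal")) {
  proposal_mode <- match.arg(proposal_mode)
  p <- list(line_tension_tilde = line_tension_tilde,
            contractility_tilde = contractility_tilde,
            boundary_tension_factor = boundary_tension_factor,
            p_accept = p_accept, delta_max = delta_max, d_min = d_min,
            iterations_per_sts = as.integer(iterations_per_sts),
            a0_min = a0_min, t1_new_length = t1_new_length,
            t1_check_interval = as.integer(t1_check_interval),
            proposal_mode = proposal_mode)
  num <- vapply(p[setdiff(names(p), "proposal_mode")], as.double, 0)
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("all numeric model parameters must be strictly positive",
          class = "extrudr_parameter_error")
  }
  if (p$p_accept > 1) {
    abort("`p_accept` must lie in (0, 1]", class = "extrudr_parameter_error")
  }
  if (p$d_min <= p$delta_max) {
    abort("`d_min` must exceed `delta_max`", class = "extrudr_parameter_error")
  }
  structure(p, class = "model_params")
}

#' Total mechanical energy of a tissue
#'
#' Evaluates the dimensionless vertex-model energy: an area-elastic term
#' \eqn{\frac12 (A_\alpha/A_\alpha^{(0)} - 1)^2} per cell, a line-tension
#' term per edge (counted once per edge; boundary edges use
#' `boundary_tension_factor` times the internal tension), and a perimeter
#' contractility term \eqn{\frac{\tilde\Gamma_\alpha}{2} L_\alpha^2} per
#' cell. Cells whose resting area has fallen below `a0_min` use the
#' dimensional elastic form (see [model_params()]).
#'
#' @param mesh A `tissue_mesh`.
#' @param params A [model_params()] object.
#' @return The total energy (finite scalar).
#' @export
tissue_energy <- function(mesh, params = model_params()) {
  E <- cpp_tissue_energy(unclass(mesh), unclass(params))
  if (!is.finite(E)) {
    abort("tissue energy is not finite", class = "extrudr_energy_error")
  }
  E
}

#' Energy change of a single vertex move
#'
#' Computes `tissue_energy(after) - tissue_energy(before)` for moving one
#' vertex to a new position, using only the faces and edges incident to that
#' vertex. This is the quantity the Metropolis acceptance rule evaluates.
#'
#' @param mesh A `tissue_mesh`.
#' @param vertex Vertex index.
#' @param new_position Numeric length-2 vector, the trial position.
#' @param params A [model_params()] object.
#' @return The energy difference.
#' @export
local_energy_delta <- function(mesh, vertex, new_position,
                               params = model_params()) {
  stopifnot(length(new_position) == 2, all(is.finite(new_position)))
  vertex <- as.integer(vertex)
  if (vertex < 1 || vertex > nrow(mesh$vertices)) {
    abort("vertex index out of range", class = "extrudr_parameter_error")
  }
  if (!cpp_move_valid(unclass(mesh), unclass(params), vertex,
                      new_position[1], new_position[2])) {
    abort("move would make an incident face degenerate or non-simple",
          class = "extrudr_rejected_move")
  }
  cpp_local_energy_delta(unclass(mesh), unclass(params), vertex,
                         new_position[1], new_position[2])
}
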