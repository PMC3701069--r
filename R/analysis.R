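#' Conduction velocity between adjacent nodes
#'
#' Velocity is internodal distance divided by the activation-time
#' difference of two adjacent nodes,
#' \eqn{v = L / (\tau_{j+1} - \tau_j)}, reported in metres per second.
#' The reference measurement in a 21-node chain uses nodes 4 and 5 (normal
#' region, after the wave has stabilised over a few nodes) and nodes 15
#' and 16 inside an injured region.
#'
#' @param sim An [simulate_axon()] result.
#' @param j_from,j_to Adjacent node indices (0-based), `j_to = j_from + 1`.
#' @param L Internodal distance, cm; defaults to the chain's geometry.
#' @return Velocity in m/s.  If either node never activated a condition of
#'   class `rnv_block` is raised (the wave never arrived: velocity is
#'   undefined there).
#' @examples
#' sim <- simulate_axon(node_chain(), t_max = 1e-3)
#' conduction_velocity(sim, 4, 5)
#' @export
conduction_velocity <- function(sim, j_from, j_to, L = sim$chain$geometry$L) {
  stopifnot(inherits(sim, "axon_sim"))
  if (j_to != j_from + 1L)
    stop("'j_to' must be 'j_from' + 1 (adjacent nodes)", call. = FALSE)
  i <- .node_idx(sim$chain, c(j_from, j_to))
  tau <- sim$tau[i]
  if (any(is.na(tau)))
    stop(errorCondition(
      sprintf("node %d never reached threshold; conduction is blocked",
              c(j_from, j_to)[which(is.na(tau))[1L]]),
      class = c("rnv_block", "error", "condition")))
  (L / 100) / (tau[2L] - tau[1L])
}

#' Detect conduction block
#'
#' The wave is blocked when any interior node never reaches threshold
#' within the simulated window.  Also reports the largest activated node
#' index (the front's furthest advance).  If the last activation falls in
#' the final 10% of the window a warning is issued: a longer `t_max` is
#' needed to classify block reliably.
#'
#' @param sim An [simulate_axon()] result.
#' @return A list with `blocked` (logical) and `last_activated_node`
#'   (0-based index).
#' @export
detect_block <- function(sim) {
  stopifnot(inherits(sim, "axon_sim"))
  n <- sim$chain$n_nodes
  interior <- seq_len(n - 1L)   # nodes 0 .. n-2 (boundary node excluded)
  act <- sim$activated[interior]
  tau <- sim$tau[interior]
  last <- if (any(act)) max(which(act)) - 1L else -1L
  if (any(act) && max(tau, na.rm = TRUE) > 0.9 * sim$t_max)
    warning("last activation within 10% of t_max; ",
            "increase t_max to classify block reliably")
  list(blocked = !all(act), last_activated_node = last)
}

#' Action potential amplitude at a node
#'
#' Peak membrane potential above rest, \eqn{\max_t V_j(t) - V_{rest}}.
#' Crush injury reduces it: the stretched node's larger capacitance is
#' discharged by an unchanged sodium-current source, so the rising phase
#' is slower and the peak lower.
#'
#' @param sim An [simulate_axon()] result.
#' @param j Node index, 0-based.
#' @return Amplitude in volts.  Raises a condition of class `rnv_block`
#'   for a node that never activated (no action potential occurred there).
#' @export
action_potential_amplitude <- function(sim, j) {
  stopifnot(inherits(sim, "axon_sim"))
  i <- .node_idx(sim$chain, j)
  if (!sim$activated[i])
    stop(errorCondition(
      sprintf("node %d never activated; amplitude undefined", j),
      class = c("rnv_block", "error", "condition")))
  sim$amplitude[i]
}

#' Closed-form conduction velocity approximation
#'
#' After an upstream node opens, the next node's capacitance discharges
#' toward it with time constant \eqn{R_a C = 4 \rho_a L C_m (s/d)}; the
#' time to reach threshold is approximately \eqn{\alpha R_a C} with
#' \eqn{\alpha} a constant near 0.5, giving
#' \deqn{v \approx \frac{L}{\alpha R_a C}
#'        = \frac{r_a}{2 \alpha \rho_a C_m s},}
#' independent of the internodal distance `L` and exactly inversely
#' proportional to the node width `s` (hyperbolic law).  This is a
#' trend-level approximation: it ignores potassium current and the finite
#' rise time of the sodium conductance, and in full simulations the
#' effective \eqn{\alpha} drifts with `s`.
#'
#' @param geom An [axon_geometry].
#' @param elec An [electrical_params].
#' @param alpha Dimensionless threshold-crossing fraction, `> 0`;
#'   default 0.5.
#' @return Estimated velocity, m/s.
#' @examples
#' analytic_velocity_estimate(axon_geometry(), electrical_params())
#' @export
analytic_velocity_estimate <- function(geom, elec, alpha = 0.5) {
  stopifnot(inherits(geom, "axon_geometry"),
            inherits(elec, "electrical_params"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  (geom$L / 100) / (alpha * discharge_time_constant(geom, elec))
}

#' Latency at a node
#'
#' Activation clock time \eqn{\tau_j}: the first time the node's membrane
#' potential reaches threshold.
#'
#' @inheritParams action_potential_amplitude
#' @return Latency in seconds (`NA` if the node never activated).
#' @export
latency_at_node <- function(sim, j) {
  stopifnot(inherits(sim, "axon_sim"))
  sim$tau[.node_idx(sim$chain, j)]
}
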