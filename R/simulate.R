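#' Ionic currents at a node
#'
#' Instantaneous transmembrane currents at node `j` (0-based index) of a
#' [node_chain], given the node's membrane potential and the time since
#' its activation.
#'
#' Sodium current flows through the bare nodal membrane where sodium
#' channels are concentrated (span `s_star_j`):
#' \deqn{i_{Na} = 2\pi r_a s^*_j \, G_{Na}(t') (E_{Na} - V_j),}
#' positive inward (depolarising) while \eqn{V_j < E_{Na}}.
#'
#' Potassium current originates in the juxtaparanodal membrane (span
#' `lam_j`) and must traverse the paranodal resistance `R_p_j` in series to
#' reach the node.  With membrane conductance
#' \eqn{g_K = 2\pi r_a \lambda_j G_K(t')} the series combination gives
#' \deqn{i_K = (V_j - E_K) \frac{g_K}{1 + g_K R_p},}
#' positive outward (repolarising) while \eqn{V_j > E_K}.  At `R_p = 0`
#' this reduces to the same form as the sodium current; as
#' `R_p` grows without bound the potassium current vanishes.
#'
#' @param chain A [node_chain].
#' @param j Node index, 0-based (0 ... n_nodes-1).
#' @param V_j Membrane potential at the node, volts.
#' @param t_prime Time since the node's activation, seconds; `<= 0` (node
#'   not yet active) gives zero current.
#' @return Current in amperes.
#' @name ionic_currents
NULL

#' @rdname ionic_currents
#' @export
sodium_current <- function(chain, j, V_j, t_prime) {
  stopifnot(inherits(chain, "node_chain"))
  i <- .node_idx(chain, j)
  2 * pi * chain$geometry$r_a * chain$s_star_j[i] *
    conductance(chain$kinetics_na, t_prime) * (chain$electrical$E_Na - V_j)
}

#' @rdname ionic_currents
#' @export
potassium_current <- function(chain, j, V_j, t_prime) {
  stopifnot(inherits(chain, "node_chain"))
  i <- .node_idx(chain, j)
  g_k <- 2 * pi * chain$geometry$r_a * chain$lam_j[i] *
    conductance(chain$kinetics_k, t_prime)
  ifelse(g_k == 0, 0,
         (V_j - chain$electrical$E_K) * g_k / (1 + g_k * chain$R_p_j[i]))
}

.node_idx <- function(chain, j) {
  j <- as.integer(j)
  if (any(is.na(j)) || any(j < 0L) || any(j >= chain$n_nodes))
    stop(sprintf("node index must be in 0..%d", chain$n_nodes - 1L),
         call. = FALSE)
  j + 1L
}

#' Rate of change of membrane potential at one node
#'
#' The governing ordinary differential equation of the discrete cable.
#' For an interior node: net current onto the nodal capacitance is sodium
#' inflow, minus potassium outflow, plus axial inflow from the left
#' neighbour, minus axial outflow to the right neighbour, divided by the
#' local capacitance:
#' \deqn{\frac{dV_j}{dt} = \frac{i_{Na,j} - i_{K,j}
#'   + (V_{j-1}-V_j)/R_a - (V_j-V_{j+1})/R_a}{C_j}.}
#' Node 0 has no left neighbour (the axial inflow term is absent); the
#' last node is clamped at rest as a boundary condition and returns 0.
#'
#' @inheritParams ionic_currents
#' @param V Vector of membrane potentials for all nodes, volts.
#' @param t_prime Vector of per-node times since activation, seconds
#'   (non-positive for inactive nodes).
#' @return dV/dt at node `j`, volts per second.
#' @export
dVdt <- function(chain, j, V, t_prime) {
  stopifnot(inherits(chain, "node_chain"),
            length(V) == chain$n_nodes, length(t_prime) == chain$n_nodes)
  i <- .node_idx(chain, j)
  n <- chain$n_nodes
  if (i == n) return(0)
  i_na <- sodium_current(chain, j, V[i], t_prime[i])
  i_k <- potassium_current(chain, j, V[i], t_prime[i])
  inflow <- if (i > 1L) (V[i - 1L] - V[i]) / chain$R_a else 0
  outflow <- (V[i] - V[i + 1L]) / chain$R_a
  (i_na - i_k + inflow - outflow) / chain$C_j[i]
}

#' Simulate saltatory conduction along the chain
#'
#' Integrates the nodal membrane potentials with the explicit Euler method
#' on a fixed grid: \eqn{V_j(t+\Delta t) = V_j(t) + \Delta t \, dV_j/dt}.
#' All nodes start at the resting potential.  Node 0 is activated at time
#' zero (its conductance clocks start immediately; no current is injected
#' — the sodium waveform itself depolarises it).  After each step, any
#' not-yet-active node whose potential has reached the threshold `V_th` is
#' marked active at the current clock time \eqn{\tau_j}; its conductance
#' waveforms then run on the local time \eqn{t' = t - \tau_j}.  The last
#' node is clamped at rest and never activates.  Nodes activate at most
#' once (single-pulse model, no refractory machinery).
#'
#' @param chain A [node_chain].
#' @param dt Integration time step, seconds.  Default 1e-7 (0.1 us), fine
#'   enough that halving it moves activation times by well under 1%.
#' @param t_max Simulated duration, seconds.  Default 2e-3 (2 ms), ample
#'   for a wave at >= 6 m/s to traverse the default 2 cm segment.
#' @param trace Keep the full membrane-potential matrix?  `FALSE` stores
#'   only activation times and per-node extrema (memory-light mode for
#'   parameter sweeps).
#' @param V0 Optional initial potentials (length `n_nodes`, volts) in
#'   place of the uniform resting state; used e.g. to observe passive
#'   discharge of a perturbed node.
#'
#' @return An object of class `axon_sim`:
#' \describe{
#'   \item{`times`}{time grid, seconds (length `n_steps + 1`).}
#'   \item{`V`}{matrix `n_nodes` x `length(times)` of potentials, volts
#'     (`NULL` when `trace = FALSE`).}
#'   \item{`tau`}{per-node activation clock times, seconds; `NA` for nodes
#'     that never reached threshold.}
#'   \item{`activated`}{logical per node.}
#'   \item{`V_peak`, `amplitude`}{per-node maximum potential and its height
#'     above rest, volts.}
#'   \item{`dt`, `t_max`, `chain`}{the integration settings and inputs.}
#' }
#' @examples
#' sim <- simulate_axon(node_chain(), dt = 1e-7, t_max = 1.5e-3)
#' summary(sim)
#' @export
simulate_axon <- function(chain, dt = 1e-7, t_max = 2e-3,
                          trace = TRUE, V0 = NULL) {
  stopifnot(inherits(chain, "node_chain"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0)
    stop("'t_max' must be a single positive number", call. = FALSE)
  n <- chain$n_nodes
  el <- chain$electrical
  kin_na <- chain$kinetics_na
  kin_k <- chain$kinetics_k
  c_na <- 2 * pi * chain$geometry$r_a * chain$s_star_j
  c_k <- 2 * pi * chain$geometry$r_a * chain$lam_j
  R_a <- chain$R_a
  C_j <- chain$C_j
  R_p <- chain$R_p_j
  if (is.null(V0)) {
    V <- rep(el$V_rest, n)
  } else {
    stopifnot(is.numeric(V0), length(V0) == n)
    V <- as.numeric(V0)
  }
  V[n] <- el$V_rest  # boundary node clamped at rest throughout
  n_steps <- as.integer(round(t_max / dt))
  tau <- rep(Inf, n)
  tau[1L] <- 0
  Vmat <- if (trace) matrix(NA_real_, n, n_steps + 1L) else NULL
  if (trace) Vmat[, 1L] <- V
  V_peak <- V
  bf_na <- kin_na$block_factor * kin_na$a
  bf_k <- kin_k$block_factor * kin_k$a
  b_na <- kin_na$b
  b_k <- kin_k$b
  for (k in seq_len(n_steps)) {
    t <- (k - 1L) * dt
    tp <- t - tau
    on <- which(tp > 0)          # active nodes with running clocks
    g_na <- numeric(n)
    g_k <- numeric(n)
    if (length(on)) {
      tpo <- tp[on]
      g_na[on] <- bf_na * tpo^2 * exp(-b_na * tpo)
      g_k[on] <- c_k[on] * bf_k * tpo^2 * exp(-b_k * tpo)
    }
    i_na <- c_na * g_na * (el$E_Na - V)
    i_k <- (V - el$E_K) * g_k / (1 + g_k * R_p)
    dV <- (i_na - i_k + c(0, V[-n] - V[-1L]) / R_a -
             c(V[-n] - V[-1L], 0) / R_a) / C_j
    dV[n] <- 0
    V <- V + dt * dV
    if (any(abs(V) > 1))
      stop("numerical instability (|V| > 1 V); use a smaller dt",
           call. = FALSE)
    hit <- which(is.infinite(tau) & V >= el$V_th)
    hit <- hit[hit < n]          # boundary node never activates
    if (length(hit)) tau[hit] <- k * dt
    if (trace) Vmat[, k + 1L] <- V
    V_peak <- pmax(V_peak, V)
  }
  tau[is.infinite(tau)] <- NA_real_
  structure(
    list(times = seq(0, by = dt, length.out = n_steps + 1L),
         V = Vmat, tau = tau, activated = !is.na(tau),
         V_peak = V_peak, amplitude = V_peak - el$V_rest,
         dt = dt, t_max = t_max, chain = chain),
    class = "axon_sim"
  )
}

#' @export
print.axon_sim <- function(x, ...) {
  n <- x$chain$n_nodes
  cat(sprintf("<axon_sim> %d nodes, dt = %.3g s, t_max = %.3g s\n",
              n, x$dt, x$t_max))
  act <- which(x$activated) - 1L
  cat(sprintf("  activated nodes: %d of %d interior (last: node %d)\n",
              sum(x$activated), n - 1L,
              if (length(act)) max(act) else -1L))
  if (sum(x$activated) > 1L) {
    tau <- x$tau[x$activated]
    cat(sprintf("  tau range: %.4g-%.4g ms\n",
                min(tau) * 1e3, max(tau) * 1e3))
  }
  invisible(x)
}

#' Conduction metrics of a simulation
#'
#' Condenses an [simulate_axon()] result into the standard report:
#' conduction velocity in a reference (uninjured) internode and in an
#' injured internode, block status, last activated node, and per-node
#' activation times and action-potential amplitudes.
#'
#' @param object An `axon_sim`.
#' @param normal_pair Nodes (0-based, adjacent) across which the normal
#'   region's velocity is measured; default `c(4, 5)`.
#' @param injured_pair Nodes across which the injured region's velocity is
#'   measured; default `c(15, 16)`.
#' @param ... Unused.
#' @return An object of class `summary.axon_sim` with fields `v_normal`,
#'   `v_injured` (m/s, `NA` if either node never activated), `blocked`,
#'   `last_activated_node`, `tau` (s), `amplitude` (V).
#' @export
summary.axon_sim <- function(object, normal_pair = c(4L, 5L),
                             injured_pair = c(15L, 16L), ...) {
  cv_or_na <- function(pair) {
    if (pair[2L] >= object$chain$n_nodes - 1L) return(NA_real_)
    tryCatch(conduction_velocity(object, pair[1L], pair[2L]),
             rnv_block = function(e) NA_real_)
  }
  blk <- detect_block(object)
  structure(
    list(v_normal = cv_or_na(normal_pair),
         v_injured = cv_or_na(injured_pair),
         normal_pair = normal_pair, injured_pair = injured_pair,
         blocked = blk$blocked,
         last_activated_node = blk$last_activated_node,
         tau = object$tau, amplitude = object$amplitude,
         n_nodes = object$chain$n_nodes),
    class = "summary.axon_sim"
  )
}

#' @export
print.summary.axon_sim <- function(x, ...) {
  fmt_v <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f m/s", v)
  cat(sprintf("Conduction velocity, nodes %d-%d: %s\n",
              x$normal_pair[1L], x$normal_pair[2L], fmt_v(x$v_normal)))
  cat(sprintf("Conduction velocity, nodes %d-%d: %s\n",
              x$injured_pair[1L], x$injured_pair[2L], fmt_v(x$v_injured)))
  cat(sprintf("Conduction block: %s (last activated node %d)\n",
              if (x$blocked) "yes" else "no", x$last_activated_node))
  amp <- x$amplitude[x$last_activated_node + 1L]
  cat(sprintf("Amplitude at node %d: %.1f mV\n",
              x$last_activated_node, amp * 1e3))
  invisible(x)
}

#' Plot membrane-potential traces
#'
#' Overlaid action potentials at successive nodes, with the threshold
#' potential as a dotted horizontal line.
#'
#' @param x An `axon_sim` run with `trace = TRUE`.
#' @param nodes 0-based node indices to draw; default all interior nodes.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.axon_sim <- function(x, nodes = seq_len(x$chain$n_nodes - 1L) - 1L, ...) {
  if (is.null(x$V))
    stop("simulation was run with trace = FALSE; no traces to plot",
         call. = FALSE)
  i <- .node_idx(x$chain, nodes)
  graphics::matplot(x$times * 1e3, t(x$V[i, , drop = FALSE]), type = "l",
                    lty = 1, col = grDevices::hcl.colors(length(i), "Zissou 1"),
                    xlab = "time (ms)", ylab = "membrane potential (V)", ...)
  graphics::abline(h = x$chain$electrical$V_th, lty = 3)
  invisible(x)
}
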