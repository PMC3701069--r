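#' Injury / treatment scenario specification
#'
#' Describes how a baseline chain is modified to emulate paranodal injury
#' and drug treatment:
#' \describe{
#'   \item{nodal stretch}{myelin retracts, widening the bare membrane of
#'     the injured nodes by `stretch_factor` (capacitance rises in
#'     proportion) while the sodium-channel span `s_star` keeps its
#'     pre-injury value.}
#'   \item{paranodal detachment}{myelin separates radially from the
#'     axolemma, multiplying the injured nodes' paranodal resistance by
#'     `rp_factor` (< 1) and exposing juxtaparanodal potassium current to
#'     the node.}
#'   \item{potassium blockade}{4-aminopyridine-like treatment scales the
#'     peak potassium conductance of every node by `k_block_factor`.}
#' }
#' The named presets fix the canonical combinations on a 21-node chain
#' with nodes 8-20 injured: `"normal"` (no change), `"crush"` (stretch x3),
#' `"crush_detach"` (stretch x3, R_p x0.1), `"block"` (stretch x3,
#' R_p x0.01), `"treated"` (block plus 80% potassium blockade), `"sweep"`
#' (uniform node-width sweep, see [sweep_node_width()]).
#'
#' @param name One of `"normal"`, `"crush"`, `"crush_detach"`, `"block"`,
#'   `"treated"`, `"sweep"`.  Choosing a preset sets the factors below to
#'   its canonical values; explicitly supplied factors override them.
#' @param injured_nodes Integer vector of 0-based injured node indices
#'   (interior nodes only).  Default `8:20`.
#' @param stretch_factor Multiplier on the bare node width of injured
#'   nodes.  Default per preset (3 for all injury presets).
#' @param rp_factor Multiplier on the paranodal resistance of injured
#'   nodes (1, 0.1 or 0.01 in the presets).
#' @param k_block_factor Multiplier on peak potassium conductance at all
#'   nodes (1, or 0.2 under treatment).
#' @param sweep_values Optional numeric vector of node widths (cm) for the
#'   `"sweep"` preset.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("crush_detach")
#' @export
scenario_spec <- function(name = c("normal", "crush", "crush_detach",
                                   "block", "treated", "sweep"),
                          injured_nodes = 8:20,
                          stretch_factor = NULL,
                          rp_factor = NULL,
                          k_block_factor = NULL,
                          sweep_values = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    normal       = list(stretch = 1, rp = 1,    kb = 1),
    crush        = list(stretch = 3, rp = 1,    kb = 1),
    crush_detach = list(stretch = 3, rp = 0.1,  kb = 1),
    block        = list(stretch = 3, rp = 0.01, kb = 1),
    treated      = list(stretch = 3, rp = 0.01, kb = 0.2),
    sweep        = list(stretch = 1, rp = 1,    kb = 1))
  stretch_factor <- if (is.null(stretch_factor)) preset$stretch else stretch_factor
  rp_factor <- if (is.null(rp_factor)) preset$rp else rp_factor
  k_block_factor <- if (is.null(k_block_factor)) preset$kb else k_block_factor
  fac <- c(stretch_factor = stretch_factor, rp_factor = rp_factor,
           k_block_factor = k_block_factor)
  if (any(!is.finite(fac)) || any(fac <= 0))
    stop("scenario factors must be positive and finite", call. = FALSE)
  if (k_block_factor > 1)
    stop("'k_block_factor' cannot exceed 1 (blockade only)", call. = FALSE)
  injured_nodes <- sort(unique(as.integer(injured_nodes)))
  structure(
    list(name = name, injured_nodes = injured_nodes,
         stretch_factor = stretch_factor, rp_factor = rp_factor,
         k_block_factor = k_block_factor, sweep_values = sweep_values),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s\n", x$name))
  cat(sprintf("  injured nodes %s: s x%g (s* fixed), R_p x%g; K peak x%g everywhere\n",
              if (length(x$injured_nodes))
                paste0(min(x$injured_nodes), "-", max(x$injured_nodes))
              else "none",
              x$stretch_factor, x$rp_factor, x$k_block_factor))
  invisible(x)
}

#' Apply a scenario to a baseline chain
#'
#' Returns a new [node_chain] in which the injured nodes have their bare
#' width multiplied by `stretch_factor` (sodium span `s_star` left at the
#' baseline value) and their paranodal resistance multiplied by
#' `rp_factor`; `k_block_factor` is applied to the potassium kinetics of
#' the whole chain.  Uninjured nodes are untouched; the builder is pure
#' (the same spec and base always give the same chain).
#'
#' @param spec A [scenario_spec].
#' @param base A baseline [node_chain].
#' @return A modified `node_chain`.
#' @examples
#' crushed <- build_scenario(scenario_spec("crush"), node_chain())
#' @export
build_scenario <- function(spec, base = node_chain()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(base, "node_chain"))
  inj <- spec$injured_nodes
  if (length(inj) &&
      (min(inj) < 1L || max(inj) > base$n_nodes - 1L))
    stop(sprintf("injured nodes must lie in 1..%d", base$n_nodes - 1L),
         call. = FALSE)
  s_j <- base$s_j
  R_p_j <- base$R_p_j
  s_j[inj + 1L] <- spec$stretch_factor * base$s_j[inj + 1L]
  R_p_j[inj + 1L] <- spec$rp_factor * base$R_p_j[inj + 1L]
  kin_k <- base$kinetics_k
  kin_k$block_factor <- spec$k_block_factor * kin_k$block_factor
  node_chain(n_nodes = base$n_nodes, geometry = base$geometry,
             electrical = base$electrical,
             kinetics_na = base$kinetics_na, kinetics_k = kin_k,
             s_j = s_j, s_star_j = base$s_star_j,
             R_p_j = R_p_j, lam_j = base$lam_j)
}

#' Conduction velocity as a function of node width
#'
#' For each width `s` (applied uniformly to every node, with the sodium
#' span following: `s_star = s`), simulates the chain and records the
#' conduction velocity across `pair`.  Velocity decreases monotonically
#' with node width; see [analytic_velocity_estimate()] for the hyperbolic
#' trend.
#'
#' @param widths Node widths, cm (positive).
#' @param base Baseline [node_chain] supplying everything except the node
#'   width.
#' @param dt,t_max Integration settings, passed to [simulate_axon()].
#' @param pair Adjacent 0-based nodes across which velocity is measured;
#'   default `c(4, 5)`.
#' @return A data frame with columns `node_width_um`, `velocity_m_per_s`
#'   (`NA` where conduction fails at that width) and `blocked` (true when
#'   the wave never reached the measurement pair within `t_max`).
#' @examples
#' \donttest{
#' sweep_node_width(c(0.5, 1, 2) * 1e-4)
#' }
#' @export
sweep_node_width <- function(widths, base = node_chain(),
                             dt = 1e-7, t_max = 2e-3, pair = c(4L, 5L)) {
  stopifnot(is.numeric(widths), all(is.finite(widths)), all(widths > 0))
  rows <- lapply(widths, function(w) {
    geom <- base$geometry
    geom$s <- w
    geom$s_star <- w
    ch <- node_chain(n_nodes = base$n_nodes, geometry = geom,
                     electrical = base$electrical,
                     kinetics_na = base$kinetics_na,
                     kinetics_k = base$kinetics_k)
    sim <- simulate_axon(ch, dt = dt, t_max = t_max, trace = FALSE)
    v <- tryCatch(conduction_velocity(sim, pair[1L], pair[2L]),
                  rnv_block = function(e) NA_real_)
    # per-row failure: the wave never reached the measurement pair
    data.frame(node_width_um = w * 1e4, velocity_m_per_s = v,
               blocked = !all(sim$activated[seq_len(pair[2L] + 1L)]))
  })
  do.call(rbind, rows)
}
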