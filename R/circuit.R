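#' Myelinated axon geometry
#'
#' Anatomical dimensions of a uniformly myelinated axon segment.  All
#' lengths are in centimetres (the model's internal unit system is
#' cm / s / ohm / farad / volt so every circuit formula is transcribable
#' without conversion factors); the configuration layer accepts micrometre /
#' millimetre keys and converts at the boundary (see [read_axon_config()]).
#'
#' Defaults are the textbook-normal axon used throughout: diameter 1.0 um,
#' node width 0.65 um, juxtaparanodal span 5.0 um (both sides of the node,
#' ten times the axon radius), internodal distance 1 mm, endoneurial sheath
#' of mean radius 6 um and thickness 2 um.
#'
#' @param d Axon diameter, cm.
#' @param s Width of the bare (unmyelinated) node of Ranvier along the
#'   axial dimension, cm.
#' @param s_star Axial span over which sodium channels are concentrated,
#'   cm.  Equals `s` in an uninjured axon; after nodal stretch the bare
#'   membrane widens but the sodium channels stay put, so `s_star` keeps
#'   the pre-injury value.
#' @param lam Total juxtaparanodal length (both sides of the node) where
#'   potassium channels reside, cm.
#' @param L Internodal distance (node centre to node centre), cm.
#' @param r_e Mean radius of the endoneurial sheath, cm.
#' @param h Thickness of the endoneurial sheath, cm.
#'
#' @return An object of class `axon_geometry` with fields `r_a` (radius),
#'   `d`, `s`, `s_star`, `lam`, `L`, `r_e`, `h`.
#' @examples
#' geom <- axon_geometry()           # textbook-normal axon
#' geom$r_a * 1e4                    # radius in micrometres
#' @export
axon_geometry <- function(d = 1.0e-4, s = 0.65e-4, s_star = s,
                          lam = 5.0e-4, L = 0.1,
                          r_e = 6e-4, h = 2e-4) {
  vals <- c(d = d, s = s, s_star = s_star, lam = lam, L = L, r_e = r_e, h = h)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be positive and finite", call. = FALSE)
  if (L / s < 10)
    warning("internodal distance L is less than 10 node widths; ",
            "the lumped-node approximation assumes L >> s")
  structure(
    list(r_a = d / 2, d = d, s = s, s_star = s_star, lam = lam,
         L = L, r_e = r_e, h = h),
    class = "axon_geometry"
  )
}

#' Electrical parameters of the axon model
#'
#' Passive electrical constants and the fixed membrane potentials.  Units
#' are ohm-cm, F/cm^2, ohm and volts.  Defaults are the textbook-normal
#' values: axoplasm resistivity 200 ohm-cm, specific membrane capacitance
#' 1 uF/cm^2, paranodal resistance 3.2e10 ohm, resting potential -85 mV,
#' threshold -50 mV, sodium equilibrium potential +67 mV, potassium
#' equilibrium potential -95 mV.  The extracellular resistivity is only
#' used to verify that the extracellular return path is negligible
#' (see [extracellular_resistance()]); it defaults to the axoplasmic value.
#'
#' @param rho_a Axoplasm resistivity, ohm-cm.
#' @param rho_e Extracellular fluid resistivity, ohm-cm.
#' @param C_m Specific membrane capacitance, farad/cm^2.
#' @param R_p Paranodal resistance, ohms: the resistance of the thin sleeve
#'   between axolemma and paranodal myelin through which juxtaparanodal
#'   potassium current must flow to reach the node.
#' @param V_rest Resting membrane potential, volts.
#' @param V_th Threshold potential for node activation, volts.
#' @param E_Na Sodium equilibrium potential, volts.
#' @param E_K Potassium equilibrium potential, volts.
#'
#' @return An object of class `electrical_params`.
#' @examples
#' electrical_params()
#' @export
electrical_params <- function(rho_a = 200, rho_e = 200, C_m = 1e-6,
                              R_p = 3.2e10,
                              V_rest = -0.085, V_th = -0.050,
                              E_Na = 0.067, E_K = -0.095) {
  if (!all(is.finite(c(rho_a, rho_e, C_m, R_p))) ||
      rho_a <= 0 || rho_e <= 0 || C_m <= 0 || R_p <= 0)
    stop("rho_a, rho_e, C_m and R_p must be positive and finite",
         call. = FALSE)
  if (!(E_K < V_rest && V_rest < V_th && V_th < E_Na))
    stop("potentials must be ordered E_K < V_rest < V_th < E_Na",
         call. = FALSE)
  structure(
    list(rho_a = rho_a, rho_e = rho_e, C_m = C_m, R_p = R_p,
         V_rest = V_rest, V_th = V_th, E_Na = E_Na, E_K = E_K),
    class = "electrical_params"
  )
}

#' Axonal (intracellular) resistance between adjacent nodes
#'
#' Resistance of the axoplasmic cylinder of length `L` and radius `r_a`:
#' \deqn{R_a = \rho_a L / (\pi r_a^2).}
#'
#' @param geom An [axon_geometry].
#' @param elec An [electrical_params].
#' @return Resistance in ohms.
#' @examples
#' axonal_resistance(axon_geometry(), electrical_params())  # ~2.5e9 ohm
#' @export
axonal_resistance <- function(geom, elec) {
  stopifnot(inherits(geom, "axon_geometry"), inherits(elec, "electrical_params"))
  elec$rho_a * geom$L / (pi * geom$r_a^2)
}

#' Extracellular resistance between adjacent nodes
#'
#' Resistance of the annular sleeve of extracellular fluid (thickness `h`,
#' mean radius `r_e`) that closes the circuit between nodes:
#' \deqn{R_e = \rho_e L / (2 \pi r_e h).}
#' Because the sleeve's cross-section is about two orders of magnitude
#' larger than the axon's, \eqn{R_e \ll R_a}; the network therefore
#' neglects it (the compact model), and this function exists to check that
#' the neglect is justified for a given geometry.
#'
#' @inheritParams axonal_resistance
#' @return Resistance in ohms.
#' @export
extracellular_resistance <- function(geom, elec) {
  stopifnot(inherits(geom, "axon_geometry"), inherits(elec, "electrical_params"))
  elec$rho_e * geom$L / (2 * pi * geom$r_e * geom$h)
}

#' Capacitance of the bare nodal membrane
#'
#' The exposed axolemma at a node is a cylinder of radius `r_a` and axial
#' width `s_local`, so \deqn{C = C_m \, 2 \pi r_a \, s_local.}
#' Nodal stretch injury widens the bare span and increases this capacitance
#' proportionally.
#'
#' @inheritParams axonal_resistance
#' @param s_local Bare membrane width to use, cm; defaults to the
#'   geometry's node width `s`.
#' @return Capacitance in farads.
#' @export
nodal_capacitance <- function(geom, elec, s_local = geom$s) {
  stopifnot(inherits(geom, "axon_geometry"), inherits(elec, "electrical_params"))
  if (!is.numeric(s_local) || any(!is.finite(s_local)) || any(s_local <= 0))
    stop("'s_local' must be positive and finite", call. = FALSE)
  elec$C_m * 2 * pi * geom$r_a * s_local
}

#' Nodal discharge time constant
#'
#' The product \eqn{R_a C} governing how fast an upstream node discharges
#' the next node's capacitance toward threshold.  Algebraically
#' \deqn{R_a C = 4 \rho_a L C_m (s/d),}
#' i.e. it depends on anatomy only through the internodal distance and the
#' nodal ratio `s/d`.  Computed as the literal product of
#' [axonal_resistance()] and [nodal_capacitance()], to which the closed
#' form is identical.
#'
#' @inheritParams nodal_capacitance
#' @return Time constant in seconds.
#' @examples
#' discharge_time_constant(axon_geometry(), electrical_params())  # ~52 us
#' @export
discharge_time_constant <- function(geom, elec, s_local = geom$s) {
  axonal_resistance(geom, elec) * nodal_capacitance(geom, elec, s_local)
}

#' @export
print.axon_geometry <- function(x, ...) {
  cat("<axon_geometry> (cm)\n")
  cat(sprintf("  diameter d = %.3g (radius %.3g), node width s = %.3g, Na span s* = %.3g\n",
              x$d, x$r_a, x$s, x$s_star))
  cat(sprintf("  juxtaparanode lambda = %.3g, internode L = %.3g\n", x$lam, x$L))
  cat(sprintf("  sheath r_e = %.3g, h = %.3g\n", x$r_e, x$h))
  invisible(x)
}

#' @export
print.electrical_params <- function(x, ...) {
  cat("<electrical_params>\n")
  cat(sprintf("  rho_a = %g ohm-cm, rho_e = %g ohm-cm, C_m = %.3g F/cm^2, R_p = %.3g ohm\n",
              x$rho_a, x$rho_e, x$C_m, x$R_p))
  cat(sprintf("  V_rest = %g mV, V_th = %g mV, E_Na = %g mV, E_K = %g mV\n",
              x$V_rest * 1e3, x$V_th * 1e3, x$E_Na * 1e3, x$E_K * 1e3))
  invisible(x)
}
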