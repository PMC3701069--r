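# Configuration I/O.  Configs are flat YAML with unit-suffixed keys
# (micrometres, millimetres, millivolts, microseconds) converted to the
# internal cm/s/ohm/farad/volt system at this boundary only.

.config_defaults <- function() {
  list(
    n_nodes = 21L,
    axon_diameter_um = 1.0,
    node_width_um = 0.65,
    na_span_um = 0.65,
    juxtaparanode_um = 5.0,
    internode_mm = 1.0,
    sheath_radius_um = 6.0,
    sheath_thickness_um = 2.0,
    axoplasm_resistivity_ohm_cm = 200,
    extracellular_resistivity_ohm_cm = 200,
    membrane_capacitance_uF_cm2 = 1.0,
    paranodal_resistance_ohm = 3.2e10,
    v_rest_mV = -85,
    v_threshold_mV = -50,
    e_na_mV = 67,
    e_k_mV = -95,
    na_peak_time_us = 100,
    na_peak_conductance_S_cm2 = 0.028,
    k_peak_time_us = 500,
    k_peak_conductance_S_cm2 = 0.013,
    scenario = "normal",
    injured_nodes = 8:20,
    stretch_factor = 1,
    rp_factor = 1,
    k_block_factor = 1,
    dt_us = 0.1,
    tmax_ms = 2.0
  )
}

#' Build an axon model configuration
#'
#' A configuration is a flat named list with explicit unit suffixes in the
#' key names (`_um` micrometres, `_mm` millimetres, `_mV` millivolts,
#' `_us` microseconds, `_ms` milliseconds); it fully determines a
#' simulation and round-trips losslessly through YAML.  Kinetics may
#' alternatively be given as raw waveform constants via the optional keys
#' `na_a`, `na_b`, `k_a`, `k_b` (ohm^-1 cm^-2 s^-2 and s^-1), which then
#' take precedence over the peak-coordinate keys.
#'
#' @param scenario Scenario preset name (see [scenario_spec()]); fills the
#'   scenario factor keys with the preset's canonical values.
#' @param ... Key overrides of the defaults (see
#'   [read_axon_config()] for the full key list, or call
#'   `axon_config()` and inspect the result).
#' @return An object of class `axon_config` (a named list).
#' @examples
#' cfg <- axon_config("crush")
#' cfg$stretch_factor
#' @export
axon_config <- function(scenario = "normal", ...) {
  cfg <- .config_defaults()
  sp <- scenario_spec(scenario)
  cfg$scenario <- sp$name
  cfg$stretch_factor <- sp$stretch_factor
  cfg$rp_factor <- sp$rp_factor
  cfg$k_block_factor <- sp$k_block_factor
  if (identical(scenario, "sweep"))
    cfg$sweep_widths_um <- c(0.3, 0.5, 0.65, 0.8, 1.0, 1.5, 2.0)
  dots <- list(...)
  known <- c(names(.config_defaults()), "sweep_widths_um",
             "na_a", "na_b", "k_a", "k_b")
  bad <- setdiff(names(dots), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "axon_config")
}

#' Read / write a configuration file
#'
#' Configurations are stored as flat YAML.  `read_axon_config()` applies
#' defaults for missing keys, so a file need only list deviations;
#' `write_axon_config()` writes every key, so saved files are
#' self-contained and `read(write(cfg))` reproduces `cfg` exactly.
#'
#' @param path File path.
#' @param cfg An [axon_config()] object.
#' @return `read_axon_config()` returns an `axon_config`;
#'   `write_axon_config()` returns `path` invisibly.
#' @export
read_axon_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file is not a YAML mapping", call. = FALSE)
  do.call(axon_config,
          c(list(scenario = if (is.null(raw$scenario)) "normal" else raw$scenario),
            raw[setdiff(names(raw), "scenario")]))
}

#' @rdname read_axon_config
#' @export
write_axon_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "axon_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' `build_chain()` converts a configuration into a scenario-applied
#' [node_chain]; `run_axon_config()` additionally simulates it and returns
#' the [simulate_axon()] result (or, for the `"sweep"` scenario, the
#' [sweep_node_width()] table).
#'
#' @param cfg An [axon_config()] object.
#' @param trace Passed to [simulate_axon()].
#' @return `build_chain()`: a `node_chain`.  `run_axon_config()`: an
#'   `axon_sim`, or a data frame for sweep configurations.
#' @examples
#' \donttest{
#' sim <- run_axon_config(axon_config("crush"))
#' summary(sim)
#' }
#' @export
build_chain <- function(cfg) {
  stopifnot(inherits(cfg, "axon_config"))
  um <- 1e-4; mm <- 0.1; mV <- 1e-3; us <- 1e-6
  geom <- axon_geometry(
    d = cfg$axon_diameter_um * um,
    s = cfg$node_width_um * um,
    s_star = cfg$na_span_um * um,
    lam = cfg$juxtaparanode_um * um,
    L = cfg$internode_mm * mm,
    r_e = cfg$sheath_radius_um * um,
    h = cfg$sheath_thickness_um * um)
  elec <- electrical_params(
    rho_a = cfg$axoplasm_resistivity_ohm_cm,
    rho_e = cfg$extracellular_resistivity_ohm_cm,
    C_m = cfg$membrane_capacitance_uF_cm2 * 1e-6,
    R_p = cfg$paranodal_resistance_ohm,
    V_rest = cfg$v_rest_mV * mV, V_th = cfg$v_threshold_mV * mV,
    E_Na = cfg$e_na_mV * mV, E_K = cfg$e_k_mV * mV)
  kin_na <- if (!is.null(cfg$na_a) && !is.null(cfg$na_b))
    channel_kinetics("Na", a = cfg$na_a, b = cfg$na_b)
  else
    fit_kinetics(cfg$na_peak_time_us * us, cfg$na_peak_conductance_S_cm2, "Na")
  kin_k <- if (!is.null(cfg$k_a) && !is.null(cfg$k_b))
    channel_kinetics("K", a = cfg$k_a, b = cfg$k_b)
  else
    fit_kinetics(cfg$k_peak_time_us * us, cfg$k_peak_conductance_S_cm2, "K")
  base <- node_chain(n_nodes = cfg$n_nodes, geometry = geom,
                     electrical = elec,
                     kinetics_na = kin_na, kinetics_k = kin_k)
  sp <- scenario_spec(cfg$scenario,
                      injured_nodes = cfg$injured_nodes,
                      stretch_factor = cfg$stretch_factor,
                      rp_factor = cfg$rp_factor,
                      k_block_factor = cfg$k_block_factor,
                      sweep_values = if (!is.null(cfg$sweep_widths_um))
                        cfg$sweep_widths_um * 1e-4)
  build_scenario(sp, base)
}

#' @rdname build_chain
#' @export
run_axon_config <- function(cfg, trace = TRUE) {
  stopifnot(inherits(cfg, "axon_config"))
  dt <- cfg$dt_us * 1e-6
  t_max <- cfg$tmax_ms * 1e-3
  if (identical(cfg$scenario, "sweep")) {
    widths <- if (is.null(cfg$sweep_widths_um))
      c(0.3, 0.5, 0.65, 0.8, 1.0, 1.5, 2.0) else cfg$sweep_widths_um
    return(sweep_node_width(widths * 1e-4, base = build_chain(cfg),
                            dt = dt, t_max = t_max))
  }
  simulate_axon(build_chain(cfg), dt = dt, t_max = t_max, trace = trace)
}

#' Emit the canonical scenario configurations
#'
#' Writes one YAML configuration per canonical experiment — `normal`,
#' `crush`, `crush_detach`, `block`, `treated` and the node-width `sweep`
#' — into `dir`.  These are the fixture inputs for the reproduction tests.
#'
#' @param dir Output directory (created if absent).
#' @return Named character vector of the file paths written, invisibly.
#' @export
generate_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  names <- c("normal", "crush", "crush_detach", "block", "treated", "sweep")
  paths <- vapply(names, function(nm) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    write_axon_config(axon_config(nm), p)
    p
  }, character(1))
  invisible(paths)
}

#' Export simulation results
#'
#' `write_trace_csv()` writes the membrane-potential matrix as CSV with
#' header `time_s, V_node0, ..., V_node<n-1>` (volts).
#' `write_summary_json()` writes the activation times, per-node peaks and
#' amplitudes, activation flags, block status, velocities and a parameter
#' echo as JSON.
#'
#' @param sim An [simulate_axon()] result (with `trace = TRUE` for the CSV).
#' @param path Output file path.
#' @param ... Passed to [summary.axon_sim()] (measurement node pairs).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  stopifnot(inherits(sim, "axon_sim"))
  if (is.null(sim$V))
    stop("simulation was run with trace = FALSE; no trace to write",
         call. = FALSE)
  df <- data.frame(time_s = sim$times, t(sim$V))
  names(df) <- c("time_s", paste0("V_node", seq_len(nrow(sim$V)) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_summary_json <- function(sim, path, ...) {
  stopifnot(inherits(sim, "axon_sim"))
  s <- summary(sim, ...)
  ch <- sim$chain
  out <- list(
    dt_s = sim$dt, t_max_s = sim$t_max, n_nodes = ch$n_nodes,
    tau_s = as.list(sim$tau), activated = as.list(sim$activated),
    peak_potential_V = as.list(sim$V_peak),
    amplitude_V = as.list(sim$amplitude),
    v_normal_m_per_s = s$v_normal, v_injured_m_per_s = s$v_injured,
    blocked = s$blocked, last_activated_node = s$last_activated_node,
    parameters = list(
      R_a_ohm = ch$R_a, C_j_farad = as.list(ch$C_j),
      s_j_cm = as.list(ch$s_j), s_star_j_cm = as.list(ch$s_star_j),
      R_p_j_ohm = as.list(ch$R_p_j), lam_j_cm = as.list(ch$lam_j)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
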