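#' Chain of nodes of Ranvier
#'
#' Assembles the discrete cable: `n_nodes` nodal capacitances (indexed
#' 0 ... n_nodes-1) joined by equal axonal resistances, sharing one
#' geometry, one set of electrical parameters and one pair of conductance
#' waveforms, with optional per-node overrides of the quantities that
#' injury changes.  The last node in the chain is the resting-clamped
#' boundary and never activates.
#'
#' Per-node overrides take a full vector of length `n_nodes`:
#' \describe{
#'   \item{`s_j`}{bare-membrane (capacitance) width per node, cm.  Stretch
#'     injury widens it.}
#'   \item{`s_star_j`}{sodium-channel span per node, cm.  Unchanged by
#'     stretch (channels stay where they were).}
#'   \item{`R_p_j`}{paranodal resistance per node, ohm.  Myelin detachment
#'     lowers it.}
#'   \item{`lam_j`}{juxtaparanodal span per node, cm.}
#' }
#'
#' @param n_nodes Number of nodes including the clamped boundary node;
#'   at least 2.  Default 21 (nodes 0-20).
#' @param geometry An [axon_geometry]; supplies the default per-node values.
#' @param electrical An [electrical_params].
#' @param kinetics_na,kinetics_k [channel_kinetics] for the sodium and
#'   potassium waveforms; default to the textbook Table-of-constants fits.
#' @param s_j,s_star_j,R_p_j,lam_j Optional per-node override vectors (see
#'   Details).
#'
#' @return An object of class `node_chain`: the inputs plus the derived
#'   internodal resistance `R_a` (ohm) and per-node capacitances `C_j`
#'   (farad).
#' @examples
#' ch <- node_chain()
#' ch$R_a          # ~2.5e9 ohm
#' ch$C_j[1]       # ~2e-14 F
#' @export
node_chain <- function(n_nodes = 21,
                       geometry = axon_geometry(),
                       electrical = electrical_params(),
                       kinetics_na = fit_kinetics(1e-4, 0.028, "Na"),
                       kinetics_k = fit_kinetics(5e-4, 0.013, "K"),
                       s_j = NULL, s_star_j = NULL,
                       R_p_j = NULL, lam_j = NULL) {
  stopifnot(inherits(geometry, "axon_geometry"),
            inherits(electrical, "electrical_params"),
            inherits(kinetics_na, "channel_kinetics"),
            inherits(kinetics_k, "channel_kinetics"))
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L)
    stop("'n_nodes' must be at least 2", call. = FALSE)
  fill <- function(x, default, name) {
    if (is.null(x)) return(rep(default, n_nodes))
    if (length(x) != n_nodes)
      stop(sprintf("'%s' must have length n_nodes (%d)", name, n_nodes),
           call. = FALSE)
    if (any(!is.finite(x)) || any(x <= 0))
      stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
    x
  }
  s_j <- fill(s_j, geometry$s, "s_j")
  s_star_j <- fill(s_star_j, geometry$s_star, "s_star_j")
  R_p_j <- fill(R_p_j, electrical$R_p, "R_p_j")
  lam_j <- fill(lam_j, geometry$lam, "lam_j")
  structure(
    list(n_nodes = n_nodes, geometry = geometry, electrical = electrical,
         kinetics_na = kinetics_na, kinetics_k = kinetics_k,
         s_j = s_j, s_star_j = s_star_j, R_p_j = R_p_j, lam_j = lam_j,
         R_a = axonal_resistance(geometry, electrical),
         C_j = nodal_capacitance(geometry, electrical, s_j)),
    class = "node_chain"
  )
}

#' @export
print.node_chain <- function(x, ...) {
  cat(sprintf("<node_chain> %d nodes (0-%d; node %d clamped at rest)\n",
              x$n_nodes, x$n_nodes - 1L, x$n_nodes - 1L))
  cat(sprintf("  R_a = %.4g ohm, C = %.4g-%.4g F\n",
              x$R_a, min(x$C_j), max(x$C_j)))
  mod <- which(x$s_j != x$geometry$s | x$R_p_j != x$electrical$R_p |
                 x$s_star_j != x$geometry$s_star | x$lam_j != x$geometry$lam) - 1L
  if (length(mod))
    cat("  per-node overrides at nodes:", paste(mod, collapse = " "), "\n")
  if (x$kinetics_k$block_factor < 1 || x$kinetics_na$block_factor < 1)
    cat(sprintf("  blockade: Na x%.2f, K x%.2f\n",
                x$kinetics_na$block_factor, x$kinetics_k$block_factor))
  invisible(x)
}
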