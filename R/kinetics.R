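#' Time-varying ion channel kinetics
#'
#' A `channel_kinetics` object describes the stereotyped time course of an
#' ion-specific membrane conductance per unit area after a node of Ranvier
#' activates,
#' \deqn{G(t') = a \, t'^2 e^{-b t'},}
#' where \eqn{t'} is the time elapsed since the node crossed threshold.
#' The waveform rises from zero, peaks at \eqn{t^* = 2/b} with value
#' \eqn{G^* = a t^{*2} e^{-2}}, and decays back to zero.  It is a
#' phenomenological description of the classical conductance transients of
#' excitable membrane; there is no voltage-dependent (Hodgkin-Huxley style)
#' gating.
#'
#' Either the peak coordinates `(t_star, G_star)` or the raw constants
#' `(a, b)` may be given; each pair determines the other uniquely
#' (see [fit_kinetics()]).
#'
#' @param species Label for the carried ion, `"Na"` or `"K"`.
#' @param t_star Time of peak conductance after activation, seconds.
#' @param G_star Peak conductance per unit membrane area,
#'   ohm^-1 cm^-2 (S/cm^2).
#' @param a Waveform amplitude constant, ohm^-1 cm^-2 s^-2.
#' @param b Waveform rate constant, s^-1.
#' @param block_factor Dimensionless multiplier in `[0, 1]` applied to the
#'   peak conductance; models pharmacological channel blockade (e.g. an 80%
#'   potassium blockade by 4-aminopyridine is `block_factor = 0.2`).
#'   Default 1 (no blockade).
#'
#' @return An object of class `channel_kinetics`: a list with fields
#'   `species`, `t_star`, `G_star`, `a`, `b`, `block_factor`.
#' @seealso [fit_kinetics()], [conductance()]
#' @examples
#' k_na <- channel_kinetics("Na", t_star = 1e-4, G_star = 0.028)
#' conductance(k_na, 1e-4)   # == 0.028 at the peak
#' @export
channel_kinetics <- function(species = c("Na", "K"),
                             t_star = NULL, G_star = NULL,
                             a = NULL, b = NULL,
                             block_factor = 1) {
  species <- match.arg(species)
  from_peak <- !is.null(t_star) || !is.null(G_star)
  from_ab <- !is.null(a) || !is.null(b)
  if (from_peak && from_ab)
    stop("give either (t_star, G_star) or (a, b), not both", call. = FALSE)
  if (from_ab) {
    stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
    if (b <= 0) stop("rate constant 'b' must be positive", call. = FALSE)
    if (a < 0) stop("amplitude constant 'a' must be non-negative", call. = FALSE)
    t_star <- 2 / b
    G_star <- a * t_star^2 * exp(-2)
  } else {
    if (is.null(t_star) || is.null(G_star))
      stop("both t_star and G_star are required", call. = FALSE)
    stopifnot(is.numeric(t_star), is.numeric(G_star),
              length(t_star) == 1L, length(G_star) == 1L)
    if (t_star <= 0)
      stop("peak time 't_star' must be positive", call. = FALSE)
    if (G_star < 0)
      stop("peak conductance 'G_star' must be non-negative", call. = FALSE)
    b <- 2 / t_star
    a <- exp(2) * G_star / t_star^2
  }
  if (!is.numeric(block_factor) || length(block_factor) != 1L ||
      block_factor < 0 || block_factor > 1)
    stop("'block_factor' must be a single number in [0, 1]", call. = FALSE)
  structure(
    list(species = species, t_star = t_star, G_star = G_star,
         a = a, b = b, block_factor = block_factor),
    class = "channel_kinetics"
  )
}

#' Fit conductance waveform constants from the peak coordinates
#'
#' Given the time `t_star` and height `G_star` of the conductance peak,
#' returns the unique constants for which \eqn{G(t') = a t'^2 e^{-b t'}}
#' attains its maximum `G_star` at `t' = t_star`:
#' \deqn{b = 2 / t^*, \qquad a = e^2 G^* / t^{*2}.}
#' For the textbook peak coordinates (Na: \eqn{t^*} = 0.1 ms,
#' \eqn{G^*} = 0.028 S/cm^2; K: \eqn{t^*} = 0.5 ms,
#' \eqn{G^*} = 0.013 S/cm^2) this gives
#' a = 2.07e7, b = 2e4 and a = 3.84e5, b = 4e3 respectively.
#'
#' @inheritParams channel_kinetics
#' @return A [channel_kinetics] object.
#' @examples
#' fit_kinetics(1e-4, 0.028, species = "Na")
#' @export
fit_kinetics <- function(t_star, G_star, species = c("Na", "K"),
                         block_factor = 1) {
  channel_kinetics(species = match.arg(species), t_star = t_star,
                   G_star = G_star, block_factor = block_factor)
}

#' Evaluate a conductance waveform
#'
#' Membrane conductance per unit area at time `t_prime` after node
#' activation.  Returns 0 for `t_prime <= 0` (the node has not yet
#' activated, or is at the instant of activation); otherwise
#' `block_factor * a * t_prime^2 * exp(-b * t_prime)`.  Vectorised over
#' `t_prime`; non-finite entries (the `-Inf` sentinel of a never-activated
#' node) yield 0.
#'
#' @param kin A [channel_kinetics] object.
#' @param t_prime Time(s) since node activation, seconds.  May be any real.
#' @return Conductance(s) per unit area, ohm^-1 cm^-2; never negative.
#' @export
conductance <- function(kin, t_prime) {
  stopifnot(inherits(kin, "channel_kinetics"))
  g <- numeric(length(t_prime))
  on <- which(is.finite(t_prime) & t_prime > 0)
  if (length(on))
    g[on] <- kin$block_factor * kin$a * t_prime[on]^2 * exp(-kin$b * t_prime[on])
  g
}

#' @export
print.channel_kinetics <- function(x, ...) {
  cat(sprintf("<channel_kinetics> %s\n", x$species))
  cat(sprintf("  peak: G* = %.4g S/cm^2 at t* = %.4g s\n", x$G_star, x$t_star))
  cat(sprintf("  constants: a = %.4g S cm^-2 s^-2, b = %.4g s^-1\n", x$a, x$b))
  if (x$block_factor < 1)
    cat(sprintf("  blockade: peak scaled by %.2f\n", x$block_factor))
  invisible(x)
}
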