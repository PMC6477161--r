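#' Spoiled gradient-echo steady-state signal
#'
#' Classic spoiled GE steady state: `m0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)`
#' with `E1 = exp(-tr / t1)`. In the limit `tr >> t1` this reduces to
#' `m0 * sin(a)`, the approximation under which the downstream dual-angle B1
#' map and the transmit/receive correction are exact.
#'
#' @param m0 Equilibrium magnetization (arbitrary units; proportional to
#'   sodium concentration). Vectorised.
#' @param alpha Flip angle in radians. Vectorised.
#' @param tr Repetition time (ms).
#' @param t1 Longitudinal relaxation time (ms).
#' @return Signal in the units of `m0`.
#' @export
#' @examples
#' geSignal(1, pi / 2, tr = 100, t1 = 40)   # (1 - exp(-2.5))
geSignal <- function(m0, alpha, tr, t1) {
  if (any(tr <= 0) || any(t1 <= 0))
    stop("geSignal: tr and t1 must be positive")
  e1 <- exp(-tr / t1)
  m0 * sin(alpha) * (1 - e1) / (1 - cos(alpha) * e1)
}

#' Inversion-recovery gradient-echo steady-state signal
#'
#' Longitudinal magnetization at time `ti` after an ideal (adiabatic,
#' B1-insensitive) inversion, read out with flip `alpha`, in cyclic steady
#' state with repetition time `tr`. Solving the steady state of
#' invert -> recover `ti` -> excite(`alpha`) -> recover `tr - ti` gives
#'
#' `Mz(ti) = m0 * (1 - (2 - Ed) * Eti) / (1 + cos(a) * Ed * Eti)`
#'
#' with `Eti = exp(-ti/t1)`, `Ed = exp(-(tr - ti)/t1)`. The returned signal is
#' `sin(a) * Mz(ti)`; magnitude is not taken, so a pool that has not yet
#' recovered through zero contributes with negative sign (pools in a voxel add
#' coherently before the magnitude image is formed). A pool with
#' `t1 = ti / log(2)` is nulled when `tr >> t1`.
#'
#' @param m0 Equilibrium magnetization (a.u.). Vectorised.
#' @param ti Inversion time (ms).
#' @param t1 Longitudinal relaxation time (ms).
#' @param tr Repetition time (ms); `Inf` gives the full-recovery limit.
#' @param alpha Readout flip angle in radians.
#' @param efficiency Inversion efficiency in `[0, 1]`; 1 = ideal 180 degrees.
#' @param exact_steady_state If `FALSE`, use the full-recovery approximation
#'   `1 - 2 * Eti` regardless of `tr`.
#' @return Signed signal in units of `m0`.
#' @export
#' @examples
#' irSignal(1, ti = 30, t1 = 30 / log(2), tr = Inf, alpha = pi / 2)  # ~0
irSignal <- function(m0, ti, t1, tr = Inf, alpha = pi / 2,
                     efficiency = 1, exact_steady_state = TRUE) {
  if (any(ti <= 0) || any(t1 <= 0) || any(tr <= 0))
    stop("irSignal: ti, t1 and tr must be positive")
  eti <- exp(-ti / t1)
  if (!exact_steady_state || all(is.infinite(tr))) {
    mz <- 1 - (1 + efficiency) * eti
  } else {
    ed <- exp(-(tr - ti) / t1)
    # efficiency e: inversion maps Mz -> -e * Mz
    mz <- (1 - (1 + efficiency - efficiency * ed) * eti) /
      (1 + efficiency * cos(alpha) * ed * eti)
  }
  m0 * sin(alpha) * mz
}
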