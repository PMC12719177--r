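# Lumped-element model of the sensor: LC tank resonance, equivalent parallel
# resistance (Rp) under transformer coupling to a conductive target, and
# converter-range quantization.

#' Sensor tank circuit
#'
#' The primary side of the transformer model: the sensing coil (inductance
#' `L1`, series resistance `R1`) resonating with the tank capacitor `C1`.
#' At resonance the converter reports the equivalent *parallel* resistance
#' `Rp = L1 / (R1 C1)` of this tank; a conductive target lowers it (see
#' [rp_equivalent()]).
#'
#' @param L1 Primary inductance in henry (e.g. `3.3e-6`).
#' @param R1 Primary series resistance in ohm.
#' @param C1 Tank capacitance in farad (e.g. `853e-12`).
#' @return An object of class `ecd_tank`.
#' @examples
#' tk <- tank_circuit(3.3e-6, 0.5, 853e-12)
#' resonant_frequency(tk$L1, tk$C1)  # about 3 MHz
#' @export
tank_circuit <- function(L1, R1, C1) {
  for (nm in c("L1", "R1", "C1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single finite positive number.", nm))
    }
  }
  structure(list(L1 = L1, R1 = R1, C1 = C1), class = "ecd_tank")
}

#' @export
print.ecd_tank <- function(x, ...) {
  cat(sprintf(
    "<ecd_tank> L1 = %.4g uH, R1 = %.4g ohm, C1 = %.4g pF (f0 = %.4g MHz, Rp0 = %.4g kOhm)\n",
    x$L1 * 1e6, x$R1, x$C1 * 1e12,
    resonant_frequency(x$L1, x$C1) / 1e6, x$L1 / (x$R1 * x$C1) / 1e3
  ))
  invisible(x)
}

#' Reflected (secondary) load seen by the sensor coil
#'
#' The conductive target acts as the secondary winding of a loosely coupled
#' transformer: an equivalent loop with inductance `L2`, resistance `R2` and
#' mutual inductance `M` to the primary. Fields may be equal-length vectors,
#' representing a superposition of independent eddy loops (one per scene
#' voxel).
#'
#' @param L2 Secondary inductance, henry.
#' @param R2 Secondary resistance, ohm.
#' @param M Mutual inductance to the primary coil, henry (`>= 0`).
#' @return An object of class `ecd_load`.
#' @export
reflected_load <- function(L2, R2, M) {
  n <- length(M)
  if (length(L2) == 1L) L2 <- rep(L2, n)
  if (length(R2) == 1L) R2 <- rep(R2, n)
  if (length(L2) != n || length(R2) != n) {
    abort("`L2`, `R2` and `M` must have matching lengths.")
  }
  if (n > 0 && (any(!is.finite(L2)) || any(L2 <= 0))) abort("`L2` must be finite and > 0.")
  if (n > 0 && (any(!is.finite(R2)) || any(R2 <= 0))) abort("`R2` must be finite and > 0.")
  if (n > 0 && (any(!is.finite(M)) || any(M < 0))) abort("`M` must be finite and >= 0.")
  structure(list(L2 = L2, R2 = R2, M = M), class = "ecd_load")
}

#' Resonant frequency of an LC pair
#'
#' @param L Inductance, henry.
#' @param C Capacitance, farad.
#' @return Frequency in hertz, `1 / (2 pi sqrt(L C))`. Vectorized.
#' @examples
#' resonant_frequency(3.3e-6, 853e-12) / 1e6  # 3.00 MHz
#' resonant_frequency(6e-6, 469e-12) / 1e6    # 3.00 MHz
#' @export
resonant_frequency <- function(L, C) {
  if (any(!is.finite(L)) || any(L <= 0)) abort("`L` must be finite and > 0.")
  if (any(!is.finite(C)) || any(C <= 0)) abort("`C` must be finite and > 0.")
  1 / (2 * pi * sqrt(L * C))
}

#' Equivalent parallel resistance under transformer coupling
#'
#' Evaluates the tank's equivalent parallel resistance with a reflected load:
#' the eddy loop reflects an impedance `w^2 M^2 / (R2 + i w L2)` into the
#' primary, lowering the effective inductance and raising the effective series
#' resistance, so with `x = w^2 M^2 / (R2^2 + (w L2)^2)`
#'
#' \deqn{Rp = \frac{L_1 - x L_2}{R_1 + x R_2} \cdot \frac{1}{C_1}.}
#'
#' At `M = 0` this reduces to the bare tank value `L1 / (R1 C1)`; Rp is
#' strictly decreasing in `M`. When the load fields are vectors the result is
#' a vector (each loop evaluated alone, for weak-coupling superposition).
#'
#' @param tank An [tank_circuit()] object.
#' @param load A [reflected_load()] object.
#' @param omega Angular drive frequency, rad/s.
#' @return Rp in ohm (vector if the load is vectorized).
#' @examples
#' tk <- tank_circuit(3.3e-6, 1, 853e-12)
#' rp_equivalent(tk, reflected_load(1e-7, 0.05, 0), 2 * pi * 3e6)  # = L1/(R1 C1)
#' @export
rp_equivalent <- function(tank, load, omega) {
  stopifnot(inherits(tank, "ecd_tank"), inherits(load, "ecd_load"))
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0) {
    abort("`omega` must be a single positive number (rad/s).")
  }
  if (length(load$M) == 0L) return(numeric(0))
  k <- load$M / sqrt(tank$L1 * load$L2)
  if (any(k > 1 + 1e-12)) {
    abort(sprintf(
      "Unphysical coupling: coefficient M/sqrt(L1 L2) = %.4g exceeds 1.", max(k)
    ))
  }
  x <- omega^2 * load$M^2 / (load$R2^2 + (omega * load$L2)^2)
  num <- tank$L1 - x * load$L2
  den <- tank$R1 + x * load$R2
  bad <- num <= 0 | den <= 0
  if (any(bad)) {
    abort(sprintf(
      "Rp is non-positive for coupling coefficient %.4g: coupling too strong for the lumped model.",
      max(k[bad])
    ))
  }
  num / den / tank$C1
}

#' Converter output range
#'
#' The measurement range of the inductance-to-digital converter. The sensor
#' firmware reports Rp over a fixed span (6-24 kOhm for the small coil,
#' 12-48 kOhm for the large coil) discretized into `n_levels` uniform steps.
#'
#' @param lo_kohm,hi_kohm Range endpoints in kOhm, `0 < lo < hi`.
#' @param n_levels Number of representable levels (default 65536, a 16-bit
#'   converter word; the register width is not part of the lumped model and is
#'   configurable).
#' @return An object of class `ecd_rp_range`.
#' @export
rp_range <- function(lo_kohm, hi_kohm, n_levels = 65536L) {
  if (!is.numeric(lo_kohm) || !is.numeric(hi_kohm) || lo_kohm <= 0 || hi_kohm <= lo_kohm) {
    abort("Need 0 < lo_kohm < hi_kohm.")
  }
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) abort("`n_levels` must be >= 2.")
  structure(list(lo_kohm = lo_kohm, hi_kohm = hi_kohm, n_levels = n_levels),
            class = "ecd_rp_range")
}

#' Quantize an Rp reading to the converter range
#'
#' Clamps to the range and rounds to the nearest of `n_levels` uniformly
#' spaced values (half-way cases round up). Idempotent.
#'
#' @param rp Rp values in ohm (vectorized).
#' @param range An [rp_range()] object.
#' @return Quantized Rp in ohm.
#' @export
quantize_rp <- function(rp, range) {
  stopifnot(inherits(range, "ecd_rp_range"))
  lo <- range$lo_kohm * 1e3
  hi <- range$hi_kohm * 1e3
  step <- (hi - lo) / (range$n_levels - 1L)
  x <- pmin(pmax(rp, lo), hi)
  # the 1e-9 guard keeps exact midpoints rounding up under floating point
  lo + pmin(floor((x - lo) / step + 0.5 + 1e-9), range$n_levels - 1L) * step
}
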