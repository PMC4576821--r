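#' Monophasic (single-exponential) progress curve
#'
#' Closed form `offset + A * (1 - exp(-kobs * t))`, the progress curve of a
#' single rate-limiting first-order step. Used both as a fitting model and
#' as the pseudo-first-order limit of the mechanistic scheme.
#'
#' @param t time in minutes (non-negative)
#' @param A amplitude (signal units)
#' @param kobs observed first-order rate (min^-1, >= 0)
#' @param offset baseline signal
#' @return signal values, same length as `t`
#' @seealso [biphasic_curve()], [fit_curve()]
#' @export
monophasic_curve <- function(t, A, kobs, offset = 0) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (kobs < 0) stop("kobs must be >= 0", call. = FALSE)
  offset + A * (1 - exp(-kobs * t))
}

#' Biphasic (double-exponential, burst) progress curve
#'
#' Closed form `offset + A1 (1 - exp(-kobs1 t)) + A2 (1 - exp(-kobs2 t))`.
#' A fast phase of amplitude `A1` (the burst: acylation of enzyme present
#' at mixing) followed by a slower phase (rate-limiting breakdown of the
#' acyl-enzyme intermediate). Reduces to [monophasic_curve()] when
#' `A2 = 0`.
#'
#' @param t time in minutes (non-negative)
#' @param A1,kobs1 amplitude and observed rate of the fast phase
#' @param A2,kobs2 amplitude and observed rate of the slow phase
#' @param offset baseline signal
#' @return signal values, same length as `t`
#' @export
biphasic_curve <- function(t, A1, kobs1, A2, kobs2, offset = 0) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (kobs1 < 0 || kobs2 < 0) stop("rates must be >= 0", call. = FALSE)
  offset + A1 * (1 - exp(-kobs1 * t)) + A2 * (1 - exp(-kobs2 * t))
}

#' Convert an observed first-order rate to a second-order constant
#'
#' Under the equimolar single-turnover-like assay ([E] = [S]), observed
#' first-order rates are normalised by the total enzyme concentration to
#' give second-order constants comparable across variants (for a
#' monophasic fit this is kcat/KM). The convention divides by total,
#' not free, enzyme.
#'
#' @param kobs observed rate (min^-1)
#' @param E0_uM total enzyme concentration in uM (> 0)
#' @return second-order rate constant in min^-1 M^-1
#' @examples
#' to_second_order(0.007, E0_uM = 1)  # 7e3 min^-1 M^-1
#' @export
to_second_order <- function(kobs, E0_uM) {
  if (!is.finite(E0_uM) || E0_uM <= 0) {
    stop("E0_uM must be > 0", call. = FALSE)
  }
  if (any(kobs < 0)) stop("kobs must be >= 0", call. = FALSE)
  kobs / (E0_uM * 1e-6)
}
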