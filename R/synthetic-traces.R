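#' Generate a noisy synthetic progress curve
#'
#' Produces the noiseless curve from either the mechanistic ODE scheme
#' (when `generator` is a [rate_constants()] object) or the phenomenological
#' closed form (when `generator` is a list of phase parameters `A1, kobs1`
#' and optionally `A2, kobs2`, plus `offset`), then adds i.i.d. Gaussian
#' noise. Reproducible given the seed; `noise_sd = 0` returns the
#' deterministic curve exactly.
#'
#' @param generator a [rate_constants()] object, or a named list of
#'   phenomenological parameters (`A1`, `kobs1`, optional `A2`, `kobs2`,
#'   optional `offset`)
#' @param cond an [assay_conditions()] object
#' @param n_points number of time points (default 60)
#' @param t_max last time point in minutes
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (signal units, >= 0)
#' @param seed integer seed
#' @param times optional explicit time grid (minutes); overrides
#'   `n_points`/`t_max`. Useful for burst-resolving designs that sample
#'   the fast and slow phases each on their own timescale.
#' @param variant_id,replicate labels stored on the trace
#' @return a [progress_curve()]; the noiseless signal is attached as
#'   attribute `"noiseless"`.
#' @export
generate_trace <- function(generator, cond = assay_conditions(),
                           n_points = 60, t_max = 100, noise_sd = 0, seed = 1,
                           times = NULL,
                           variant_id = "synthetic", replicate = "1") {
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (is.null(times)) {
    if (n_points < 2) stop("need n_points >= 2", call. = FALSE)
    times <- seq(0, t_max, length.out = n_points)
  }
  n_points <- length(times)

  if (inherits(generator, "rate_constants")) {
    clean <- simulate_full_scheme(generator, cond, times)$signal
  } else if (is.list(generator) && all(c("A1", "kobs1") %in% names(generator))) {
    g <- generator
    off <- g$offset %||% 0
    clean <- if (!is.null(g$A2) && !is.null(g$kobs2)) {
      biphasic_curve(times, g$A1, g$kobs1, g$A2, g$kobs2, off)
    } else {
      monophasic_curve(times, g$A1, g$kobs1, off)
    }
  } else {
    stop("generator must be rate_constants or a list with A1, kobs1",
         call. = FALSE)
  }

  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  } else {
    numeric(n_points)
  }
  pc <- progress_curve(times, clean + noise, cond,
                       variant_id = variant_id, replicate = replicate)
  attr(pc, "noiseless") <- clean
  pc
}
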