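#' Rate constants of the two-step covalent mechanism
#'
#' Bundles the four microscopic rate constants of the minimal covalent
#' protease mechanism E + S <-> ES -> EA + Pc -> E + Pn: reversible
#' substrate binding, acylation of the bound substrate (which ejects the
#' C-terminal product and forms the acyl-enzyme EA), and hydrolytic
#' deacylation that regenerates free enzyme.
#'
#' @param k_on bimolecular association rate (uM^-1 min^-1)
#' @param k_off dissociation rate of ES (min^-1)
#' @param k_acyl acylation rate of bound substrate (min^-1)
#' @param k_deacyl deacylation (hydrolysis) rate of the acyl-enzyme (min^-1)
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(k_on = 10, k_off = 100, k_acyl = 5, k_deacyl = 0.1)
#' @export
rate_constants <- function(k_on, k_off, k_acyl, k_deacyl) {
  r <- c(k_on = k_on, k_off = k_off, k_acyl = k_acyl, k_deacyl = k_deacyl)
  if (any(!is.finite(r))) {
    stop("all rate constants must be finite", call. = FALSE)
  }
  if (any(r < 0)) {
    stop("rate constants must be non-negative; got ",
         paste(names(r)[r < 0], collapse = ", "), call. = FALSE)
  }
  structure(as.list(r), class = "rate_constants")
}

#' Assay conditions for a progress curve
#'
#' @param E0 total enzyme concentration (uM), must be > 0
#' @param S0 total substrate concentration (uM), must be >= 0
#' @param pH assay pH (metadata only; default 8)
#' @param temperature assay temperature in degrees C (metadata only; default 25)
#' @return An object of class `assay_conditions`.
#' @examples
#' assay_conditions(E0 = 1, S0 = 1)  # the equimolar 1 uM assay
#' @export
assay_conditions <- function(E0 = 1, S0 = 1, pH = 8, temperature = 25) {
  if (!is.finite(E0) || E0 <= 0) stop("E0 must be > 0 (uM)", call. = FALSE)
  if (!is.finite(S0) || S0 < 0) stop("S0 must be >= 0 (uM)", call. = FALSE)
  structure(list(E0 = E0, S0 = S0, pH = pH, temperature = temperature),
            class = "assay_conditions")
}

#' A timestamped fluorescence progress curve
#'
#' The unit of kinetic analysis: a vector of times (minutes, strictly
#' increasing, starting at or after zero) and the matching signal
#' (arbitrary fluorescence units, proportional to cleaved substrate),
#' together with the assay conditions and identifying labels.
#'
#' @param times time points in minutes; strictly increasing, `times[1] >= 0`
#' @param signal fluorescence signal, same length as `times`
#' @param conditions an [assay_conditions()] object
#' @param variant_id variant label
#' @param replicate replicate label
#' @return A data frame of class `progress_curve` with columns `time` and
#'   `signal` and attributes `conditions`, `variant_id`, `replicate`.
#' @export
progress_curve <- function(times, signal, conditions = assay_conditions(),
                           variant_id = "variant", replicate = "1") {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal)) {
    stop("times and signal must have the same length", call. = FALSE)
  }
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  if (any(!is.finite(times))) stop("times must be finite", call. = FALSE)
  if (times[1] < 0) stop("times must start at >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!inherits(conditions, "assay_conditions")) {
    stop("conditions must be an assay_conditions object", call. = FALSE)
  }
  structure(data.frame(time = times, signal = signal),
            conditions = conditions,
            variant_id = as.character(variant_id),
            replicate = as.character(replicate),
            class = c("progress_curve", "data.frame"))
}

#' @export
print.progress_curve <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("progress_curve: %s (rep %s), %d points, t = [%g, %g] min\n",
              attr(x, "variant_id"), attr(x, "replicate"), nrow(x),
              min(x$time), max(x$time)))
  cat(sprintf("  conditions: E0 = %g uM, S0 = %g uM, pH %g, %g degC\n",
              cond$E0, cond$S0, cond$pH, cond$temperature))
  invisible(x)
}
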