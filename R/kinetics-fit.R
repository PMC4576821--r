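#' Fit a mono- or biphasic model to a progress curve
#'
#' Multi-start bounded Levenberg-Marquardt least squares. Rate starting
#' values are drawn log-uniformly over `[1e-4, 1e2]` min^-1; amplitude and
#' offset starts are data-driven (total signal rise split at random between
#' the two phases for the biphasic model). The best-of-starts fit is
#' returned, with the phase labels canonicalised so `kobs1 >= kobs2`.
#' Amplitudes smaller than three times the residual noise estimate flag the
#' corresponding rate as unidentifiable rather than trusting its value.
#'
#' @param trace a [progress_curve()] (>= 5 points monophasic, >= 7 biphasic)
#' @param model `"monophasic"` or `"biphasic"`
#' @param n_starts number of random restarts (default 20)
#' @param seed integer seed; the fit is deterministic given the seed
#' @return an object of class `phase_fit`: a list with elements `model`,
#'   `A1`, `kobs1`, `A2`, `kobs2` (`NA` for monophasic), `offset`,
#'   `r_squared`, `residual_ss`, `n_points`, `sigma_hat`,
#'   `unidentifiable` (character vector of flagged parameters), `seed`.
#' @examples
#' tr <- progress_curve(0:40, monophasic_curve(0:40, A = 1, kobs = 0.2))
#' fit_curve(tr, "monophasic", seed = 1)
#' @export
fit_curve <- function(trace, model = c("monophasic", "biphasic"),
                      n_starts = 20, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!inherits(trace, "progress_curve")) {
    stop("trace must be a progress_curve", call. = FALSE)
  }
  n_min <- if (model == "monophasic") 5L else 7L
  if (nrow(trace) < n_min) {
    stop(sprintf("%s fit needs >= %d points, got %d",
                 model, n_min, nrow(trace)), call. = FALSE)
  }

  t <- trace$time
  y <- trace$signal
  n <- length(y)
  rise <- max(y) - min(y)
  amp0 <- max(rise, 1e-12)

  resid_fn <- if (model == "monophasic") {
    function(p) y - monophasic_curve(t, p[1], p[2], p[3])
  } else {
    function(p) y - biphasic_curve(t, p[1], p[2], p[3], p[4], p[5])
  }
  n_par <- if (model == "monophasic") 3L else 5L
  lower <- c(rep(0, n_par - 1L), -Inf)   # amplitudes/rates >= 0, offset free
  upper <- rep(Inf, n_par)

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      k <- 10^stats::runif(if (model == "monophasic") 1 else 2, -4, 2)
      if (model == "monophasic") {
        c(A = amp0, kobs = k, offset = y[1])
      } else {
        f <- stats::runif(1, 0.1, 0.9)
        k <- sort(k, decreasing = TRUE)
        c(A1 = f * amp0, kobs1 = k[1], A2 = (1 - f) * amp0, kobs2 = k[2],
          offset = y[1])
      }
    })
  })

  best <- NULL
  diag_log <- character(0)
  for (i in seq_along(starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[[i]], lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      diag_log <- c(diag_log, sprintf("start %d: %s", i,
                                      conditionMessage(attr(fit, "condition"))))
      next
    }
    if (!fit$info %in% 1:4) {
      diag_log <- c(diag_log, sprintf("start %d: info=%d (%s)", i, fit$info,
                                      fit$message))
      next
    }
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) {
    stop("all ", n_starts, " starts failed to converge:\n",
         paste(diag_log, collapse = "\n"), call. = FALSE)
  }

  p <- best$fit$par
  ss <- best$ss
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - ss / sst)) else 1
  df <- max(n - n_par, 1L)
  sigma_hat <- sqrt(ss / df)

  if (model == "monophasic") {
    out <- list(model = "monophasic", A1 = unname(p[1]), kobs1 = unname(p[2]),
                A2 = NA_real_, kobs2 = NA_real_, offset = unname(p[3]))
  } else {
    if (p[4] > p[2]) p <- p[c(3, 4, 1, 2, 5)]  # relabel so kobs1 >= kobs2
    out <- list(model = "biphasic", A1 = unname(p[1]), kobs1 = unname(p[2]),
                A2 = unname(p[3]), kobs2 = unname(p[4]), offset = unname(p[5]))
  }

  flagged <- character(0)
  if (out$A1 < 3 * sigma_hat) flagged <- c(flagged, "kobs1")
  if (model == "biphasic" && out$A2 < 3 * sigma_hat) {
    flagged <- c(flagged, "kobs2")
  }

  structure(c(out, list(r_squared = r2, residual_ss = ss, n_points = n,
                        sigma_hat = sigma_hat, unidentifiable = flagged,
                        seed = seed)),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("phase_fit (%s): ", x$model))
  if (x$model == "monophasic") {
    cat(sprintf("A = %.4g, kobs = %.4g min^-1", x$A1, x$kobs1))
  } else {
    cat(sprintf("A1 = %.4g, kobs1 = %.4g | A2 = %.4g, kobs2 = %.4g min^-1",
                x$A1, x$kobs1, x$A2, x$kobs2))
  }
  cat(sprintf(", offset = %.4g\n  R^2 = %.5f, SS = %.4g, n = %d\n",
              x$offset, x$r_squared, x$residual_ss, x$n_points))
  if (length(x$unidentifiable)) {
    cat("  unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

aicc <- function(ss, n, n_par) {
  k <- n_par + 1  # + residual variance
  n * log(ss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Choose between mono- and biphasic fits by extra-sum-of-squares F-test
#'
#' Fits both nested models and accepts the biphasic one iff the F-test
#' p-value is below `alpha`. When the biphasic fit does not improve the
#' residual sum of squares the monophasic model is returned by parsimony.
#' Small-sample corrected AIC for both fits is reported alongside.
#'
#' @inheritParams fit_curve
#' @param alpha significance level of the F-test (default 0.05)
#' @return list with elements `model` (the selected one), `F`, `p_value`,
#'   `alpha`, `fit_mono`, `fit_bi`, `aicc_mono`, `aicc_bi`.
#' @export
select_model <- function(trace, alpha = 0.05, n_starts = 20, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  fm <- fit_curve(trace, "monophasic", n_starts = n_starts, seed = seed)
  fb <- fit_curve(trace, "biphasic", n_starts = n_starts, seed = seed)
  n <- fm$n_points
  df_bi <- n - 5L
  ss_m <- fm$residual_ss
  ss_b <- fb$residual_ss

  if (ss_b >= ss_m || df_bi < 1L) {
    # biphasic no better (or unfittable df): parsimony
    Fstat <- 0
    p <- 1
  } else {
    Fstat <- ((ss_m - ss_b) / 2) / (ss_b / df_bi)
    p <- stats::pf(Fstat, 2, df_bi, lower.tail = FALSE)
  }
  model <- if (p < alpha) "biphasic" else "monophasic"
  list(model = model, F = Fstat, p_value = p, alpha = alpha,
       fit_mono = fm, fit_bi = fb,
       aicc_mono = aicc(ss_m, n, 3), aicc_bi = aicc(ss_b, n, 5))
}

#' Summarise a variant's kinetics as second-order constants
#'
#' Converts a selected fit into the per-variant record used for
#' cross-variant comparison: two second-order constants (fast/slow phase)
#' for a biphasic fit, or a single kcat/KM for a monophasic fit, plus the
#' burst amplitude.
#'
#' @param fit a `phase_fit` (or the list returned by [select_model()], in
#'   which case the selected fit is used)
#' @param E0_uM total enzyme concentration in uM
#' @param variant_id label
#' @return list of class `variant_kinetics` with `variant_id`, `k2_obs1`,
#'   `k2_obs2`, `kcat_over_KM` (exclusive by `source_model`),
#'   `burst_amplitude`, `source_model`.
#' @export
variant_kinetics <- function(fit, E0_uM, variant_id = "variant") {
  if (!inherits(fit, "phase_fit") && is.list(fit) && !is.null(fit$model)) {
    fit <- if (fit$model == "biphasic") fit$fit_bi else fit$fit_mono
  }
  if (!inherits(fit, "phase_fit")) stop("fit must be a phase_fit",
                                        call. = FALSE)
  if (fit$model == "biphasic") {
    out <- list(variant_id = variant_id,
                k2_obs1 = to_second_order(fit$kobs1, E0_uM),
                k2_obs2 = to_second_order(fit$kobs2, E0_uM),
                kcat_over_KM = NA_real_,
                burst_amplitude = fit$A1,
                source_model = "biphasic")
  } else {
    out <- list(variant_id = variant_id,
                k2_obs1 = NA_real_, k2_obs2 = NA_real_,
                kcat_over_KM = to_second_order(fit$kobs1, E0_uM),
                burst_amplitude = fit$A1,
                source_model = "monophasic")
  }
  structure(out, class = "variant_kinetics")
}
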