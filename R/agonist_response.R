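# three-parameter dose-response model, Hill slope fixed at 1:
# Y = bottom + (top - bottom) / (1 + 10^(log10(EC50) - X)), X = log10(conc)
.dose_response_model <- function(conc, bottom, top, log_ec50) {
  x <- log10(conc)
  bottom + (top - bottom) / (1 + 10^(log_ec50 - x))
}

#' Normalise peak currents to a reference response
#'
#' Current amplitudes are expressed relative to the current elicited by a
#' near-saturating reference application (canonically 10 mM l-glutamate),
#' so the reference response is 1 by construction.  Negative peak values
#' (inward currents) are taken as absolute amplitudes.
#'
#' @param currents numeric peak currents.
#' @param reference_current the reference peak current; must be non-zero.
#' @return numeric vector of relative responses.
#' @export
normalize_responses <- function(currents, reference_current) {
  if (length(reference_current) != 1 || reference_current == 0 ||
      !is.finite(reference_current))
    stop("reference current must be a single non-zero value")
  abs(currents) / abs(reference_current)
}

#' Fit a three-parameter dose-response curve
#'
#' Least-squares fit of
#' `Y = bottom + (top - bottom) / (1 + 10^(log10(EC50) - X))`,
#' `X = log10(concentration)`, with Hill slope fixed at 1 — three free
#' parameters (bottom, top, log10 EC50), or two with `fix_bottom = TRUE`
#' (bottom constrained to 0).  The optimiser (Levenberg-Marquardt)
#' restarts from three deterministic initial EC50 guesses — the geometric
#' mean, minimum and maximum of the tested concentrations — and keeps the
#' best fit, so the result is reproducible without a seed.
#'
#' @param concentrations_mM agonist concentrations in mM (>= 4 distinct
#'   values spanning the transition).
#' @param responses relative responses (same length).
#' @param fix_bottom constrain bottom = 0?
#' @return A `dose_response_fit` list: `ec50_mM`, `top`, `bottom`,
#'   `residual_ss`, `converged`, `fitted` (function of concentration).
#'   On non-convergence the estimates are `NA` with `converged = FALSE`.
#' @export
fit_dose_response <- function(concentrations_mM, responses,
                              fix_bottom = FALSE) {
  conc <- as.numeric(concentrations_mM)
  y <- as.numeric(responses)
  if (length(conc) != length(y)) stop("lengths differ")
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(conc <= 0)) stop("concentrations must be positive")
  dat <- data.frame(conc = conc, y = y)
  starts <- log10(c(exp(mean(log(conc))), min(conc), max(conc)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch({
      if (fix_bottom) {
        minpack.lm::nlsLM(
          y ~ top / (1 + 10^(log_ec50 - log10(conc))),
          data = dat,
          start = list(top = max(y), log_ec50 = s),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^(log_ec50 - log10(conc))),
          data = dat,
          start = list(bottom = min(y), top = max(y), log_ec50 = s),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) {
    return(structure(list(ec50_mM = NA_real_, top = NA_real_,
                          bottom = NA_real_, residual_ss = NA_real_,
                          converged = FALSE, fitted = NULL),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(best$fit)
  bottom <- if (fix_bottom) 0 else unname(cf["bottom"])
  top <- unname(cf["top"])
  log_ec50 <- unname(cf["log_ec50"])
  structure(list(
    ec50_mM = 10^log_ec50, top = top, bottom = bottom,
    residual_ss = best$ss, converged = TRUE,
    fitted = function(c_mM) .dose_response_model(c_mM, bottom, top,
                                                 log_ec50)),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Dose-response fit did not converge\n")
  } else {
    cat(sprintf(
      "Dose-response fit: EC50 = %.4g mM, top = %.3g, bottom = %.3g (residual SS %.3g)\n",
      x$ec50_mM, x$top, x$bottom, x$residual_ss))
  }
  invisible(x)
}

#' Kainate/glutamate peak-response ratio
#'
#' The ratio of peak currents evoked by the partial agonist kainate and
#' the full agonist glutamate, expressed as a percentage — an index of
#' agonist efficacy for AMPA-type receptors.
#'
#' @param peak_kainate,peak_glutamate non-negative peak currents;
#'   glutamate peak must be positive.
#' @return percentage, `100 * peak_kainate / peak_glutamate`.
#' @export
ka_glu_ratio <- function(peak_kainate, peak_glutamate) {
  if (any(peak_glutamate <= 0)) stop("glutamate peak must be positive")
  if (any(peak_kainate < 0)) stop("peaks must be non-negative")
  100 * peak_kainate / peak_glutamate
}
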