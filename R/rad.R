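# Rank-abundance distribution model comparison. Four models are fitted to the
# ranked counts of one community by maximum Poisson likelihood with a log link
# (the vegan radfit framework, which the fits delegate to) and compared by
# AIC: geometric-series preemption (1 parameter), broken stick (0), lognormal
# (2) and Zipf-Mandelbrot (3).

RAD_MODELS <- c("preemption", "broken_stick", "lognormal", "zipf_mandelbrot")

#' Closed-form broken-stick expected abundances
#'
#' Expected abundance at rank r for S taxa and N individuals:
#' (N / S) * sum_{k=r}^{S} 1/k. Exposed separately because it is defined for
#' any S >= 2, while [fit_rad()] requires >= 4 taxa.
#'
#' @param N total individuals.
#' @param S number of taxa.
#' @return numeric vector of length S, non-increasing.
#' @export
broken_stick_expected <- function(N, S) {
  vapply(seq_len(S), function(r) N / S * sum(1 / (r:S)), numeric(1))
}

#' Fit one rank-abundance model to a community
#'
#' @param abundances nonzero counts of one sample (>= 4 taxa); sorted
#'   descending internally.
#' @param model one of preemption, broken_stick, lognormal, zipf_mandelbrot.
#' @return list of class `rad_fit`: model, parameters, fitted (expected
#'   abundance per rank), logLik, AIC, n_params, converged.
#' @export
fit_rad <- function(abundances, model = RAD_MODELS) {
  model <- match.arg(model)
  x <- sort(as.numeric(abundances[abundances > 0]), decreasing = TRUE)
  if (length(x) < 4) stopf("need >= 4 nonzero abundances")
  fit <- switch(model,
    preemption = vegan::rad.preempt(x),
    broken_stick = vegan::rad.null(x),
    lognormal = vegan::rad.lognormal(x),
    zipf_mandelbrot = suppressWarnings(vegan::rad.zipfbrot(x)))
  npar <- length(stats::coef(fit)[!is.na(stats::coef(fit))])
  ll <- as.numeric(stats::logLik(fit))
  converged <- is.finite(ll) && all(is.finite(stats::fitted(fit)))
  structure(list(model = model,
                 parameters = stats::coef(fit),
                 fitted = as.numeric(stats::fitted(fit)),
                 deviance = stats::deviance(fit),
                 logLik = ll,
                 AIC = 2 * npar - 2 * ll,
                 n_params = npar,
                 converged = converged),
            class = "rad_fit")
}

#' @export
print.rad_fit <- function(x, ...) {
  cat(sprintf("RAD fit: %s (k = %d)  AIC = %.2f%s\n", x$model, x$n_params,
              x$AIC, if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Fit and rank all four rank-abundance models
#'
#' @param abundances nonzero counts of one sample.
#' @return data.frame sorted by AIC with columns model, n_params, AIC,
#'   delta_AIC, converged; fits attached as the "fits" attribute.
#' @export
compare_rads <- function(abundances) {
  fits <- lapply(RAD_MODELS, function(m) {
    tryCatch(fit_rad(abundances, m), error = function(e) NULL)
  })
  names(fits) <- RAD_MODELS
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stopf("all RAD fits failed")
  tab <- data.frame(model = RAD_MODELS[ok],
                    n_params = vapply(fits[ok], `[[`, numeric(1), "n_params"),
                    AIC = vapply(fits[ok], `[[`, numeric(1), "AIC"),
                    converged = vapply(fits[ok], `[[`, logical(1), "converged"),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  attr(tab, "fits") <- fits
  tab
}
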