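# MST trace reduction and one-site binding-isotherm fitting.

#' Temperature-jump Delta F_norm from an MST trace
#'
#' `F_norm` is the mean fluorescence over `(laser_on + 0.5 s,
#' laser_on + 1.5 s]` divided by the mean over the last second before the
#' laser; `Delta F_norm` is the difference to the ligand-free baseline
#' trace evaluated the same way.
#'
#' @param trace Data frame with columns `time` (s) and `fluorescence`.
#' @param baseline_trace Same format, measured at ligand concentration 0.
#' @param laser_on_time Laser-on time, s.
#' @return Single Delta F_norm value (dimensionless).
#' @export
delta_fnorm_from_trace <- function(trace, baseline_trace, laser_on_time = 5) {
  fnorm <- function(tr) {
    hot <- tr$time > laser_on_time + 0.5 & tr$time <= laser_on_time + 1.5
    cold <- tr$time > laser_on_time - 1 & tr$time <= laser_on_time
    if (!any(hot) || !any(cold)) {
      abort("trace does not cover the evaluation windows")
    }
    mean(tr$fluorescence[hot]) / mean(tr$fluorescence[cold])
  }
  fnorm(trace) - fnorm(baseline_trace)
}

#' Bound fraction under the one-site ligand-depletion model
#'
#' Solves the quadratic mass balance for the fraction of labelled protein
#' bound: `fb = ((P + c + Kd) - sqrt((P + c + Kd)^2 - 4 P c)) / (2 P)`.
#' As `P -> 0` this tends to the hyperbola `c / (c + Kd)`, used directly
#' below `P = 1e-6` nM.
#'
#' @param conc Ligand concentration(s), nM.
#' @param kd Dissociation constant, nM (> 0).
#' @param protein_conc Labelled protein concentration, nM.
#' @return Bound fraction(s) in [0, 1].
#' @export
fraction_bound <- function(conc, kd, protein_conc) {
  stopifnot(kd > 0, protein_conc >= 0, all(conc >= 0))
  if (protein_conc < 1e-6) return(conc / (conc + kd))
  s <- protein_conc + conc + kd
  disc <- pmax(s^2 - 4 * protein_conc * conc, 0)
  (s - sqrt(disc)) / (2 * protein_conc)
}

#' Fit a one-site binding isotherm
#'
#' Least-squares fit of `Delta F_norm(c) = offset + amplitude * fb(c; Kd,
#' P)` with the labelled protein concentration P fixed. `fb` is the
#' depletion model by default ([fraction_bound()]); `model = "hyperbolic"`
#' ignores depletion. The fit is multistarted over a decade-spaced Kd grid
#' spanning the nonzero concentration range; standard errors come from the
#' Jacobian-based covariance of the converged fit. The no-binding flag is
#' set when the amplitude is indistinguishable from zero
#' (|amplitude| < 2 SE).
#'
#' @param iso Data frame with columns `conc` (nM) and `delta_fnorm`
#'   (optionally `replicate`), e.g. from [generate_isotherm()].
#' @param protein_conc Labelled protein concentration, nM; defaults to the
#'   `protein_conc` attribute of `iso` when present.
#' @param model `"depletion"` (default) or `"hyperbolic"`.
#' @return Object of class `"isotherm_fit"` with elements kd, kd_se,
#'   amplitude, amplitude_se, offset, offset_se, converged,
#'   no_binding_flag, rss, n_points, model, data.
#' @export
fit_isotherm <- function(iso, protein_conc = NULL,
                         model = c("depletion", "hyperbolic")) {
  model <- match.arg(model)
  protein_conc <- protein_conc %||% attr(iso, "protein_conc")
  if (is.null(protein_conc)) {
    abort("protein_conc must be given (or attached to the isotherm)")
  }
  if (length(unique(iso$conc)) < 5) {
    abort("need at least 5 distinct concentrations to fit")
  }
  p_eff <- if (model == "hyperbolic") 0 else protein_conc
  fb_fun <- function(conc, kd) fraction_bound(conc, kd, p_eff)

  y <- iso$delta_fnorm; conc <- iso$conc
  if (stats::sd(y) == 0) {
    return(new_isotherm_fit(NA, NA, 0, NA, y[1], NA, FALSE, TRUE,
                            0, length(y), model, iso, protein_conc))
  }
  cn <- sort(unique(conc[conc > 0]))
  grid <- 10^seq(log10(min(cn)), log10(max(cn)), by = 1)
  fits <- lapply(grid, function(kd0) {
    tryCatch(
      minpack.lm::nlsLM(
        delta_fnorm ~ offset + amplitude * fb_fun(conc, kd),
        data = data.frame(conc = conc, delta_fnorm = y),
        start = list(kd = kd0, amplitude = diff(range(y)) *
                       sign(stats::cor(y, fb_fun(conc, kd0))),
                     offset = min(y)),
        lower = c(kd = 1e-9, amplitude = -Inf, offset = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
      error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) {
    return(new_isotherm_fit(NA, NA, NA, NA, NA, NA, FALSE, TRUE,
                            NA, length(y), model, iso, protein_conc))
  }
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  co <- summary(best)$coefficients
  kd <- co["kd", "Estimate"]; kd_se <- co["kd", "Std. Error"]
  amp <- co["amplitude", "Estimate"]; amp_se <- co["amplitude", "Std. Error"]
  off <- co["offset", "Estimate"]; off_se <- co["offset", "Std. Error"]
  no_binding <- is.finite(amp_se) && abs(amp) < 2 * amp_se
  new_isotherm_fit(kd, kd_se, amp, amp_se, off, off_se, TRUE, no_binding,
                   min(rss), length(y), model, iso, protein_conc)
}

new_isotherm_fit <- function(kd, kd_se, amplitude, amplitude_se, offset,
                             offset_se, converged, no_binding, rss, n,
                             model, data, protein_conc) {
  structure(list(kd = kd, kd_se = kd_se, amplitude = amplitude,
                 amplitude_se = amplitude_se, offset = offset,
                 offset_se = offset_se, converged = converged,
                 no_binding_flag = no_binding, rss = rss, n_points = n,
                 model = model, data = data, protein_conc = protein_conc),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  if (x$no_binding_flag) {
    cat("<isotherm_fit> no binding detected (amplitude ~ 0)\n")
  } else {
    cat(sprintf(
      "<isotherm_fit> Kd = %.3g +/- %.2g nM (%s model, %d points)\n",
      x$kd, x$kd_se, x$model, x$n_points))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficients of an isotherm fit
#' @param x An `isotherm_fit`.
#' @param ... Unused.
#' @return Tibble (term, estimate, std.error).
#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble(term = c("kd", "amplitude", "offset"),
         estimate = c(x$kd, x$amplitude, x$offset),
         std.error = c(x$kd_se, x$amplitude_se, x$offset_se))
}

#' One-row fit summary
#' @param x An `isotherm_fit`.
#' @param ... Unused.
#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble(kd = x$kd, kd_se = x$kd_se, rss = x$rss, n = x$n_points,
         model = x$model, converged = x$converged,
         no_binding = x$no_binding_flag)
}
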