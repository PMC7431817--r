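#' Construct a saturation-binding curve
#'
#' A binding curve is a data frame with columns `conc_nM` (strictly
#' increasing ligand concentrations), `intensity` (background-corrected mean
#' fluorescence, arbitrary units) and optionally `sem` (standard error of the
#' mean across replicates).
#'
#' @param conc_nM ligand concentrations in nM, strictly increasing.
#' @param intensity fluorescence intensities, same length.
#' @param sem optional per-point SEM in intensity units.
#' @param label free-text label stored as an attribute.
#' @return A data frame of class `binding_curve`.
#' @export
binding_data <- function(conc_nM, intensity, sem = NULL, label = "") {
  if (length(conc_nM) != length(intensity))
    stop("conc_nM and intensity must have equal length")
  if (any(!is.finite(conc_nM)) || any(diff(conc_nM) <= 0))
    stop("conc_nM must be finite and strictly increasing")
  if (!is.null(sem) && length(sem) != length(conc_nM))
    stop("sem must match conc_nM in length")
  out <- data.frame(conc_nM = as.numeric(conc_nM),
                    intensity = as.numeric(intensity),
                    sem = if (is.null(sem)) NA_real_ else as.numeric(sem))
  attr(out, "label") <- label
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' Read or write a binding curve as CSV (`conc_nM,intensity,sem`)
#'
#' @param path file path.
#' @param curve a [binding_data] object.
#' @return `read_binding_curve` returns a `binding_curve`;
#'   `write_binding_curve` returns `path` invisibly.
#' @export
read_binding_curve <- function(path) {
  x <- utils::read.csv(path)
  need <- c("conc_nM", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed binding-curve CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  binding_data(x$conc_nM, x$intensity,
               sem = if ("sem" %in% names(x)) x$sem else NULL,
               label = basename(path))
}

#' @rdname read_binding_curve
#' @export
write_binding_curve <- function(curve, path) {
  stopifnot(inherits(curve, "binding_curve"))
  utils::write.csv(as.data.frame(curve)[c("conc_nM", "intensity", "sem")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Subtract blank fluorescence from a binding curve
#'
#' Intensities are reduced by the blank reading; results that would become
#' negative are clipped to zero with a warning.
#'
#' @param raw a [binding_data] object.
#' @param blank non-negative blank intensity.
#' @return The corrected `binding_curve`.
#' @export
background_correct <- function(raw, blank) {
  stopifnot(inherits(raw, "binding_curve"))
  if (!is.finite(blank) || blank < 0) stop("blank must be >= 0")
  corr <- raw$intensity - blank
  nneg <- sum(corr < 0)
  if (nneg > 0) {
    warning(sprintf("%d intensit%s clipped to 0 after background subtraction",
                    nneg, if (nneg == 1) "y" else "ies"))
    corr <- pmax(corr, 0)
  }
  raw$intensity <- corr
  raw
}

hill_curve <- function(conc, Imin, Imax, logKd, n) {
  Imin + (Imax - Imin) / (1 + 10^(n * (logKd - log10(conc))))
}

#' Fit the Hill equation to a saturation-binding curve
#'
#' Least-squares fit of
#' `I = Imin + (Imax - Imin) / (1 + 10^(n * (log10 Kd - log10 c)))` in
#' log10-concentration space. `n` is the Hill coefficient: `n > 1` indicates
#' apparent positive, `n < 1` apparent negative cooperativity of binding.
#' A small multi-start grid (`n` in 0.5/1/2 crossed with `Kd` at the
#' concentration-grid quartiles) guards against local minima; the lowest
#' residual norm wins, ties going to the smallest `n`. `Imin` is constrained
#' to be non-negative. Reported parameter errors are asymptotic standard
#' errors from the final Jacobian.
#'
#' @param curve a [binding_data] object with at least 5 points spanning at
#'   least two decades of concentration (all concentrations > 0).
#' @param weighted if `TRUE`, weight residuals by `1/sem^2`.
#' @return An object of class `hill_fit` with components `coefficients`
#'   (`Imin`, `Imax`, `Kd`, `n`), `se`, `norm` (residual sum of squares),
#'   `curve`, `weighted`.
#' @examples
#' cc <- 10^seq(-2, 2, length.out = 9)
#' cv <- binding_data(cc, hill_curve(cc, 0, 100, log10(1), 1))
#' coef(fit_hill(cv))
#' @export
fit_hill <- function(curve, weighted = FALSE) {
  stopifnot(inherits(curve, "binding_curve"))
  conc <- curve$conc_nM; I <- curve$intensity
  if (any(conc <= 0)) stop("Hill fitting requires strictly positive concentrations")
  if (length(conc) < 5) stop("need at least 5 points for a Hill fit")
  if (log10(max(conc) / min(conc)) < 2)
    stop("concentrations must span at least two decades")
  w <- rep(1, length(I))
  if (weighted) {
    if (any(is.na(curve$sem)) || any(curve$sem <= 0))
      stop("weighted fit requires positive sem for every point")
    w <- 1 / curve$sem^2
  }
  sw <- sqrt(w)
  resid_fn <- function(p) sw * (I - hill_curve(conc, p[1], p[2], p[3], p[4]))
  lower <- c(0, 0, log10(min(conc)) - 3, 0.05)
  upper <- c(Inf, Inf, log10(max(conc)) + 3, 10)
  best <- NULL
  diags <- character(0)
  for (n0 in c(0.5, 1, 2)) {
    for (k0 in stats::quantile(log10(conc), c(0.25, 0.5, 0.75), names = FALSE)) {
      start <- c(max(min(I), 0), max(I), k0, n0)
      f <- tryCatch(
        minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) e)
      if (inherits(f, "error")) { diags <- c(diags, conditionMessage(f)); next }
      if (is.null(best) || f$deviance < best$deviance * (1 - 1e-12) ||
          (abs(f$deviance - best$deviance) <= best$deviance * 1e-12 &&
           f$par[4] < best$par[4]))
        best <- f
    }
  }
  if (is.null(best))
    stop("Hill fit failed for all starts: ", paste(diags, collapse = "; "))
  cf <- c(Imin = best$par[1], Imax = best$par[2], Kd = 10^best$par[3],
          n = best$par[4])
  # asymptotic SEs on the internal scale (Imin, Imax, log10 Kd, n), the Kd
  # error propagated through the log10 transform
  se_int <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) rep(NA_real_, 4))
  se <- c(Imin = se_int[1], Imax = se_int[2],
          Kd = unname(cf["Kd"]) * log(10) * se_int[3], n = se_int[4])
  structure(list(coefficients = cf, se = se, norm = best$deviance,
                 curve = curve, weighted = weighted),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cf <- x$coefficients; se <- x$se
  cat("Hill fit", if (x$weighted) "(1/sem^2 weighted)" else "", "\n")
  cat(sprintf("  Kd   = %.4g +/- %.2g nM\n  n    = %.4g +/- %.2g\n",
              cf["Kd"], se["Kd"], cf["n"], se["n"]))
  cat(sprintf("  Imin = %.4g, Imax = %.4g, residual norm = %.4g\n",
              cf["Imin"], cf["Imax"], x$norm))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, conc = object$curve$conc_nM, ...) {
  cf <- object$coefficients
  hill_curve(conc, cf["Imin"], cf["Imax"], log10(cf["Kd"]), cf["n"])
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$curve$intensity - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  cc <- x$curve$conc_nM
  graphics::plot(cc, x$curve$intensity, log = "x", xlab = "[EGF] (nM)",
                 ylab = "intensity", ...)
  grid <- 10^seq(log10(min(cc)), log10(max(cc)), length.out = 200)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' Scatchard transform of a binding curve
#'
#' Returns `(bound, bound/free)` pairs with bound proxied by the
#' background-corrected intensity and free ligand by the nominal
#' concentration (depletion assumed negligible). Points at zero
#' concentration are dropped. A concave-up Scatchard plot indicates apparent
#' negative cooperativity or site heterogeneity; concave-down apparent
#' positive cooperativity.
#'
#' @param curve a [binding_data] object.
#' @return Data frame with columns `bound` and `bound_over_free`.
#' @export
scatchard <- function(curve) {
  stopifnot(inherits(curve, "binding_curve"))
  keep <- curve$conc_nM > 0
  data.frame(bound = curve$intensity[keep],
             bound_over_free = curve$intensity[keep] / curve$conc_nM[keep])
}

#' @rdname write_params_json
#' @param fit a `hill_fit` object.
#' @export
write_hill_json <- function(fit, path) {
  stopifnot(inherits(fit, "hill_fit"))
  jsonlite::write_json(list(schema_version = 1L,
                            coefficients = as.list(fit$coefficients),
                            se = as.list(fit$se), norm = fit$norm,
                            weighted = fit$weighted),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
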