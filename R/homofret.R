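#' Fluorescence anisotropy from polarized intensities
#'
#' `r = (I_par - G * I_perp) / (I_par + 2 * G * I_perp)`, where `G` is the
#' detection-sensitivity factor of the instrument for the two polarization
#' channels.
#'
#' @param I_par,I_perp non-negative parallel and perpendicular emission
#'   intensities (vectorized).
#' @param G detection sensitivity factor (> 0).
#' @return Anisotropy values in `(-0.5, 1]`.
#' @export
anisotropy <- function(I_par, I_perp, G = 1) {
  if (any(G <= 0)) stop("G must be > 0")
  if (any(I_par < 0) || any(I_perp < 0)) stop("intensities must be >= 0")
  den <- I_par + 2 * G * I_perp
  if (any(den <= 0)) stop("anisotropy undefined: I_par + 2*G*I_perp must be > 0")
  (I_par - G * I_perp) / den
}

#' Anisotropy of a monomer/cluster mixture under partial photobleaching
#'
#' A fraction `mon` of fluorophores is monomeric; the rest sit in clusters of
#' `N` fluorophores at inter-fluorophore distance `1/d` in units of the
#' Forster distance. After bleaching to residual unbleached fraction `s`, a
#' cluster carries a binomial number `k ~ Binom(N, s)` of intact
#' fluorophores; energy migration among `k` fluorophores depolarizes
#' emission. The intensity-weighted mixture anisotropy is
#' \deqn{r(s) = \frac{1-mon}{N s} \sum_{k=0}^{N} \binom{N}{k} s^k (1-s)^{N-k}
#'   k \left[\frac{r_1 (1+d^6)}{1+k d^6} +
#'   \frac{r_{FRET} (k-1) d^6}{1+k d^6}\right] + mon \, r_1}
#' The prefactor `1/(N s)` normalizes the intensity weights (`E[k] = N s`),
#' so `r -> r1` as `s -> 0` (bleaching removes FRET partners) and `r = r1`
#' for `N = 1` or `mon = 1`.
#'
#' @param N cluster size, integer >= 1 (with `relaxed = TRUE` any real
#'   `N >= 1` via generalized binomial coefficients, for sensitivity
#'   analysis).
#' @param mon monomer fraction in `[0, 1]`.
#' @param s residual unbleached fraction in `[0, 1]` (vectorized); `s = 0`
#'   returns the limit `r1`.
#' @param d reciprocal normalized inter-fluorophore distance; 1 means the
#'   fluorophores sit exactly one Forster distance (4.8 nm for GFP-GFP)
#'   apart.
#' @param r1 anisotropy of an isolated fluorophore (0.34 for GFP).
#' @param rFRET anisotropy of a fluorophore excited by homo-FRET (0 assumed).
#' @param relaxed allow non-integer `N`.
#' @return Anisotropy values, one per element of `s`.
#' @export
model_anisotropy <- function(N, mon, s, d = 1, r1 = 0.34, rFRET = 0,
                             relaxed = FALSE) {
  if (!relaxed && (length(N) != 1 || N < 1 || N != round(N)))
    stop("N must be a single integer >= 1 (or use relaxed = TRUE)")
  if (relaxed && (length(N) != 1 || N < 1)) stop("N must be >= 1")
  if (mon < 0 || mon > 1) stop("mon must be in [0, 1]")
  if (any(s < 0) || any(s > 1)) stop("s must be in [0, 1]")
  if (d < 0) stop("d must be >= 0")
  # analytic limits, exact by construction: a lone fluorophore (or a fully
  # monomeric population) emits at the single-fluorophore anisotropy
  if (mon == 1 || N == 1) return(rep(r1, length(s)))
  kmax <- if (relaxed) max(1L, ceiling(N)) else as.integer(N)
  k <- seq_len(kmax)  # k = 0 carries zero intensity weight
  per_k <- r1 * (1 + d^6) / (1 + k * d^6) + rFRET * (k - 1) * d^6 / (1 + k * d^6)
  vapply(s, function(si) {
    if (si == 0) return(r1)  # analytic bleaching limit
    if (relaxed) {
      lw <- lchoose(N, k) + k * log(si) + (N - k) * log1p(-si)
      lw[!is.finite(lw)] <- -Inf
      wts <- exp(lw) * k / (N * si)
    } else {
      wts <- stats::dbinom(k, kmax, si) * k / (N * si)
    }
    (1 - mon) * sum(wts * per_k) + mon * r1
  }, numeric(1))
}

#' Construct an anisotropy photobleaching series
#'
#' @param s residual unbleached fractions, strictly decreasing from 1.
#' @param r anisotropies.
#' @param sd optional per-point anisotropy SD across images.
#' @return Data frame of class `bleach_series` with columns `s`, `r`, `sd`.
#' @export
bleach_series <- function(s, r, sd = NULL) {
  if (length(s) != length(r)) stop("s and r must have equal length")
  if (any(s <= 0) || any(s > 1)) stop("s must lie in (0, 1]")
  if (s[1] != 1) stop("the first point must have s = 1 (no bleaching)")
  if (any(diff(s) >= 0)) stop("s must be strictly decreasing")
  out <- data.frame(s = as.numeric(s), r = as.numeric(r),
                    sd = if (is.null(sd)) NA_real_ else as.numeric(sd))
  class(out) <- c("bleach_series", "data.frame")
  out
}

#' Read or write a bleach series as CSV (`s,r,sd`)
#'
#' @param path file path.
#' @param series a [bleach_series] object.
#' @export
read_bleach_series <- function(path) {
  x <- utils::read.csv(path)
  miss <- setdiff(c("s", "r"), names(x))
  if (length(miss))
    stop("malformed bleach-series CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  bleach_series(x$s, x$r, sd = if ("sd" %in% names(x)) x$sd else NULL)
}

#' @rdname read_bleach_series
#' @export
write_bleach_series <- function(series, path) {
  stopifnot(inherits(series, "bleach_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Fit cluster size and monomer fraction to a bleach series
#'
#' Least-squares fit of [model_anisotropy()] to an anisotropy-vs-residual-
#' fraction photobleaching series. The cluster size `N` is searched on an
#' integer grid; for each `N` the monomer fraction is profiled analytically:
#' the model is linear in `mon` (`r = g_N(s) + mon * (r1 - g_N(s))`), so the
#' optimal `mon` is a clipped linear least-squares coefficient. `r1`, `rFRET`
#' and `d` are treated as known constants.
#'
#' @param series a [bleach_series] with at least 6 points reaching below
#'   `s = 0.3`.
#' @param N_max largest cluster size considered.
#' @param d,r1,rFRET fixed model constants, see [model_anisotropy()].
#' @return Object of class `cluster_fit`: list with `N`, `mon`, `norm`,
#'   `profile` (norm per candidate `N`), `degenerate` flag, the constants and
#'   the series.
#' @examples
#' s <- seq(1, 0.1, by = -0.1)
#' ser <- bleach_series(s, model_anisotropy(4, 0.2, s))
#' fit_bleach_series(ser)
#' @export
fit_bleach_series <- function(series, N_max = 30L, d = 1, r1 = 0.34,
                              rFRET = 0) {
  stopifnot(inherits(series, "bleach_series"))
  if (nrow(series) < 6) stop("need at least 6 bleach points")
  if (min(series$s) >= 0.3)
    stop("series must reach below s = 0.3 to constrain the cluster size")
  s <- series$s; r <- series$r
  prof <- stats::setNames(numeric(N_max), seq_len(N_max))
  mons <- numeric(N_max)
  for (N in seq_len(N_max)) {
    g <- model_anisotropy(N, 0, s, d = d, r1 = r1, rFRET = rFRET)
    x <- r1 - g
    mon <- if (sum(x^2) > 0) sum((r - g) * x) / sum(x^2) else 1
    mon <- min(max(mon, 0), 1)
    prof[N] <- sum((r - (g + mon * x))^2)
    mons[N] <- mon
  }
  Nbest <- which.min(prof)
  mon <- mons[Nbest]
  degenerate <- FALSE
  # a flat series carries no cluster information: report the monomeric answer
  flat_norm <- sum((r - r1)^2)
  if (flat_norm <= min(prof) * (1 + 1e-9) || Nbest == 1 || mon >= 1 - 1e-12) {
    if (flat_norm <= min(prof) * (1 + 1e-9)) {
      Nbest <- 1L; mon <- 1
      warning("anisotropy series is flat at r1: cluster size unidentifiable")
    }
    degenerate <- TRUE
  }
  structure(list(N = as.integer(Nbest), mon = mon,
                 norm = unname(prof[Nbest]), profile = prof,
                 degenerate = degenerate, d = d, r1 = r1, rFRET = rFRET,
                 series = series),
            class = "cluster_fit")
}

#' @export
coef.cluster_fit <- function(object, ...) c(N = object$N, mon = object$mon)

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("Homo-FRET cluster fit: N = %d, mon = %.3f (norm %.3g)%s\n",
              x$N, x$mon, x$norm,
              if (x$degenerate) " [degenerate: no cluster signal]" else ""))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI: N in [%g, %g], mon in [%.3f, %.3f] (%d reps)\n",
                x$ci["lo", "N"], x$ci["hi", "N"],
                x$ci["lo", "mon"], x$ci["hi", "mon"], x$reps))
  }
  invisible(x)
}

#' @export
predict.cluster_fit <- function(object, s = object$series$s, ...) {
  model_anisotropy(object$N, object$mon, s, d = object$d, r1 = object$r1,
                   rFRET = object$rFRET)
}

#' @export
residuals.cluster_fit <- function(object, ...) {
  object$series$r - predict(object)
}

#' @export
plot.cluster_fit <- function(x, ...) {
  graphics::plot(x$series$s, x$series$r, xlim = c(1, 0),
                 xlab = "residual unbleached fraction s", ylab = "anisotropy r",
                 ...)
  sg <- seq(1, 0.01, length.out = 100)
  graphics::lines(sg, predict(x, sg))
  invisible(x)
}

#' Monte-Carlo confidence intervals for a cluster fit
#'
#' Generates `reps` synthetic bleach series by drawing every anisotropy from
#' `Normal(r, sd)` (using the recorded per-point SD), refits each, and
#' reports the 2.5/97.5 percentiles of the `reps` estimates of `N` and
#' `mon`.
#'
#' @param series a [bleach_series] with `sd` present on every point.
#' @param reps number of Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param ... passed to [fit_bleach_series()].
#' @return A `cluster_fit` for the original series, augmented with `ci`
#'   (matrix `lo`/`hi` x `N`/`mon`), `reps` and `draws` (the per-replicate
#'   estimates).
#' @export
mc_confidence <- function(series, reps = 500L, seed = NULL, ...) {
  stopifnot(inherits(series, "bleach_series"))
  if (any(is.na(series$sd))) stop("mc_confidence requires sd on every point")
  fit <- fit_bleach_series(series, ...)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("N", "mon")))
  for (i in seq_len(reps)) {
    r_i <- stats::rnorm(nrow(series), series$r, series$sd)
    f <- suppressWarnings(
      fit_bleach_series(bleach_series(series$s, r_i, series$sd), ...))
    draws[i, ] <- c(f$N, f$mon)
  }
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  rownames(ci) <- c("lo", "hi")
  fit$ci <- ci; fit$reps <- reps; fit$draws <- draws
  fit
}

#' @rdname write_params_json
#' @param cluster_fit_result a `cluster_fit` object.
#' @export
write_cluster_fit_json <- function(cluster_fit_result, path) {
  stopifnot(inherits(cluster_fit_result, "cluster_fit"))
  x <- cluster_fit_result
  jsonlite::write_json(
    list(schema_version = 1L, N = x$N, mon = x$mon, norm = x$norm,
         degenerate = x$degenerate, d = x$d, r1 = x$r1, rFRET = x$rFRET,
         ci = if (is.null(x$ci)) NULL else
           list(N = as.list(stats::setNames(x$ci[, "N"], rownames(x$ci))),
                mon = as.list(stats::setNames(x$ci[, "mon"], rownames(x$ci))))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
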