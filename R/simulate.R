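#' Design of a synthetic multi-condition binding experiment
#'
#' Describes the study layout the binding simulator emulates: three
#' pharmacological conditions (untreated, erlotinib, lapatinib, each with its
#' own kinase conformational constant `K1`) crossed with four expression
#' gates of known receptor number, measured over a two-fold EGF dilution
#' series in replicate.
#'
#' @param truth an [egfr_params] object holding the generating `K2`-`K9`
#'   (its `K1` entry is ignored in favour of `k1`).
#' @param k1 named vector of condition-specific `K1` values.
#' @param gates named vector of receptor numbers per cell for the expression
#'   gates.
#' @param conc_max top concentration of the two-fold dilution series (nM).
#' @param n_conc number of concentrations (>= 8).
#' @param replicates replicate measurements per point.
#' @param cv coefficient of variation of the multiplicative Gaussian
#'   intensity noise.
#' @param scales named per-condition intensity scale (arbitrary fluorescence
#'   units per bound EGF molecule); a scalar is recycled.
#' @param seed RNG seed.
#' @return List of class `binding_sim_design`.
#' @export
binding_sim_design <- function(truth = egfr_reference_params(),
                               k1 = reference_k1(),
                               gates = c(low = 390000, medium = 630000,
                                         high = 1070000, all = 560000),
                               conc_max = 260, n_conc = 14L,
                               replicates = 3L, cv = 0.05,
                               scales = 2e-3, seed = 1L) {
  validate_params(truth)
  stopifnot(length(k1) >= 1, !is.null(names(k1)), all(k1 > 0),
            all(gates > 0), !is.null(names(gates)),
            conc_max > 0, n_conc >= 8, replicates >= 1, cv >= 0)
  if (length(scales) == 1L) scales <- stats::setNames(rep(scales, length(k1)),
                                                      names(k1))
  stopifnot(all(names(k1) %in% names(scales)), all(scales > 0))
  structure(list(truth = truth, k1 = k1, gates = gates, conc_max = conc_max,
                 n_conc = as.integer(n_conc), replicates = as.integer(replicates),
                 cv = cv, scales = scales[names(k1)], seed = as.integer(seed)),
            class = "binding_sim_design")
}

#' Simulate a multi-condition flow-cytometric binding experiment
#'
#' For every condition x gate the noiseless prediction
#' `scale * bound(truth, Rtot, L)` is computed on the two-fold dilution grid
#' and measured `replicates` times with multiplicative Gaussian noise
#' (`intensity = mean * (1 + eps)`, `eps ~ N(0, cv)`); negative draws are
#' truncated at zero (rare at realistic CV and counted in the
#' `truncated` attribute). The reported intensity is the replicate mean, the
#' reported `sem` the replicate standard error. Output is deterministic
#' given the design's seed.
#'
#' @param design a [binding_sim_design].
#' @return List of [design_cell] objects (one per condition x gate), with
#'   attribute `truncated` giving the number of truncated draws.
#' @export
simulate_binding_experiment <- function(design) {
  stopifnot(inherits(design, "binding_sim_design"))
  set.seed(design$seed)
  grid <- design$conc_max / 2^((design$n_conc - 1):0)
  truncated <- 0L
  cells <- list()
  for (cn in names(design$k1)) {
    p <- unclass(design$truth)
    p["K1"] <- design$k1[[cn]]
    params <- do.call(egfr_params, as.list(p))
    for (g in names(design$gates)) {
      mu <- design$scales[[cn]] * binding_curve(params, design$gates[[g]], grid)
      reps <- matrix(mu, design$replicates, length(grid), byrow = TRUE) *
        (1 + matrix(stats::rnorm(design$replicates * length(grid), 0, design$cv),
                    design$replicates))
      truncated <- truncated + sum(reps < 0)
      reps[reps < 0] <- 0
      m <- colMeans(reps)
      sem <- if (design$replicates > 1)
        apply(reps, 2, stats::sd) / sqrt(design$replicates)
      else rep(0, length(grid))
      cells[[paste(cn, g, sep = "/")]] <-
        design_cell(cn, g, design$gates[[g]],
                    binding_data(grid, m, sem, label = paste(cn, g)))
    }
  }
  if (truncated > 0)
    message(truncated, " negative intensity draw(s) truncated at 0")
  attr(cells, "truncated") <- truncated
  cells
}

#' Design of a synthetic photobleaching homo-FRET experiment
#'
#' @param N,mon generating cluster size and monomer fraction.
#' @param s bleach schedule: residual fractions, strictly decreasing from 1.
#' @param sd Gaussian anisotropy noise SD (and the per-point SD recorded in
#'   the series).
#' @param d,r1,rFRET model constants, see [model_anisotropy()].
#' @param seed RNG seed.
#' @return List of class `fret_sim_design`.
#' @export
fret_sim_design <- function(N = 4L, mon = 0.2,
                            s = 0.85^(0:14), sd = 0.003,
                            d = 1, r1 = 0.34, rFRET = 0, seed = 1L) {
  stopifnot(N >= 1, mon >= 0, mon <= 1, sd >= 0, s[1] == 1,
            all(diff(s) < 0))
  structure(list(N = N, mon = mon, s = s, sd = sd, d = d, r1 = r1,
                 rFRET = rFRET, seed = as.integer(seed)),
            class = "fret_sim_design")
}

#' Simulate an anisotropy photobleaching series
#'
#' `r(s) = model_anisotropy(N, mon, s) + Normal(0, sd)`, with the noise SD
#' recorded per point. Deterministic given the design's seed.
#'
#' @param design a [fret_sim_design].
#' @return A [bleach_series].
#' @export
simulate_bleach_experiment <- function(design) {
  stopifnot(inherits(design, "fret_sim_design"))
  set.seed(design$seed)
  r <- model_anisotropy(design$N, design$mon, design$s, d = design$d,
                        r1 = design$r1, rFRET = design$rFRET) +
    stats::rnorm(length(design$s), 0, design$sd)
  bleach_series(design$s, r, sd = rep(design$sd, length(design$s)))
}

#' Fraction of added ligand depleted by cell-surface binding
#'
#' The binding analyses equate free with added ligand; this utility
#' quantifies the relative error of that assumption:
#' `bound_per_cell * cells / (L_total * 1e-9 * N_A * volume)`.
#'
#' @param bound_per_cell bound ligand molecules per cell.
#' @param cells number of cells in the sample.
#' @param volume sample volume in liters.
#' @param L_total added ligand concentration in nM.
#' @return Depleted fraction of the added ligand.
#' @examples
#' depletion_check(1e6, 1e5, 520e-6, 1)  # ~3e-4: depletion negligible
#' @export
depletion_check <- function(bound_per_cell, cells, volume, L_total) {
  stopifnot(bound_per_cell >= 0, cells > 0, volume > 0, L_total > 0)
  avogadro <- 6.02214076e23
  bound_per_cell * cells / (L_total * 1e-9 * avogadro * volume)
}
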