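#' @keywords internal
#' @name equilibrium-internal
#' @noRd
NULL

species_names <- function() {
  c("CI", "CA", "EI", "EA", "EIL", "EAL",
    "DES", "DESL", "DES2L", "DEA", "DEAL", "DEA2L")
}

# Coefficients of the conservation quadratic a*[EI]^2 + b*[EI] = Rtot.
# Expressing every species through [EI] via the mass-action relations:
#   monomers:  [CI]=K2[EI], [CA]=K2[EI]/K1, [EA]=[EI]/K1,
#              [EIL]=[EI]L/K3, [EAL]=[EI]L/(K1*K3)
#   dimers:    [DES]=[EI]^2/K4, [DESL]=[DES]L/K5, [DES2L]=[DESL]L/K6,
#              [DEA]=[EI]^2/(K1^2*K7), [DEAL]=[DEA]L/K8, [DEA2L]=[DEAL]L/K9
# Dimer species carry weight 2 in the receptor count. Vectorized over L.
eq_coefficients <- function(p, L) {
  K1 <- p[["K1"]]; K2 <- p[["K2"]]; K3 <- p[["K3"]]
  b <- (1 + 1 / K1) * (K2 + 1 + L / K3)
  a <- 2 * ((1 / p[["K4"]]) * (1 + L / p[["K5"]] + L^2 / (p[["K5"]] * p[["K6"]])) +
            (1 / (K1^2 * p[["K7"]])) * (1 + L / p[["K8"]] +
                                          L^2 / (p[["K8"]] * p[["K9"]])))
  list(a = a, b = b)
}

# Positive root of a*x^2 + b*x - Rtot = 0, in the cancellation-safe form
# x = 2*Rtot / (b + sqrt(b^2 + 4*a*Rtot)); exact also when a*Rtot << b^2.
ei_root <- function(p, Rtot, L) {
  ab <- eq_coefficients(p, L)
  2 * Rtot / (ab$b + sqrt(ab$b^2 + 4 * ab$a * Rtot))
}

species_from_ei <- function(p, EI, L) {
  K1 <- p[["K1"]]
  EA <- EI / K1
  DES <- EI^2 / p[["K4"]]
  DEA <- EA^2 / p[["K7"]]
  cbind(CI = p[["K2"]] * EI, CA = p[["K2"]] * EI / K1, EI = EI, EA = EA,
        EIL = EI * L / p[["K3"]], EAL = EA * L / p[["K3"]],
        DES = DES, DESL = DES * L / p[["K5"]],
        DES2L = DES * L^2 / (p[["K5"]] * p[["K6"]]),
        DEA = DEA, DEAL = DEA * L / p[["K8"]],
        DEA2L = DEA * L^2 / (p[["K8"]] * p[["K9"]]))
}

bound_from_species <- function(sp) {
  sp[, "EIL"] + sp[, "EAL"] + sp[, "DESL"] + sp[, "DEAL"] +
    2 * (sp[, "DES2L"] + sp[, "DEA2L"])
}

rtot_from_species <- function(sp) {
  rowSums(sp[, 1:6, drop = FALSE]) + 2 * rowSums(sp[, 7:12, drop = FALSE])
}

#' Solve the twelve-species receptor equilibrium
#'
#' Computes the unique non-negative equilibrium composition of the receptor
#' population at one point: total receptor number `Rtot` (receptors/cell) and
#' free EGF concentration `L` (nM). Monomeric species are `CI`, `CA`, `EI`,
#' `EA` (closed/extended extracellular domain crossed with inactive/active
#' kinase domain) plus the liganded `EIL`, `EAL`; dimeric species are `DES`,
#' `DESL`, `DES2L` (symmetric kinase dimers with 0, 1, 2 EGF) and `DEA`,
#' `DEAL`, `DEA2L` (asymmetric kinase dimers). Dimer concentrations are in
#' dimers/cell and count twice in the receptor balance.
#'
#' All species are expressed through `[EI]` by the mass-action relations, and
#' the receptor conservation law becomes a quadratic in `[EI]` whose positive
#' root is unique whenever `Rtot > 0`. The quadratic is evaluated in a
#' cancellation-safe form so that low-expression cells do not lose precision.
#' Free ligand is the added ligand: depletion is assumed negligible (see
#' [depletion_check()]).
#'
#' @param params an [egfr_params] object.
#' @param Rtot total receptor number per cell (>= 0).
#' @param L free EGF concentration in nM (>= 0).
#' @return An object of class `egfr_state`: list with `species` (named
#'   numeric, 12 species), `bound` (EGF molecules bound per cell), `Rtot`,
#'   `L`.
#' @examples
#' st <- solve_equilibrium(egfr_reference_params(), Rtot = 560000, L = 3.9)
#' st$bound
#' @export
solve_equilibrium <- function(params, Rtot, L) {
  validate_params(params)
  stopifnot(length(Rtot) == 1L, length(L) == 1L)
  if (!is.finite(Rtot) || Rtot < 0) stop("Rtot must be finite and >= 0")
  if (!is.finite(L) || L < 0) stop("L must be finite and >= 0")
  if (Rtot == 0) {
    sp <- matrix(0, 1, 12, dimnames = list(NULL, species_names()))
  } else {
    EI <- ei_root(unclass(params), Rtot, L)
    sp <- species_from_ei(unclass(params), EI, L)
  }
  structure(list(species = sp[1, ], bound = unname(bound_from_species(sp)),
                 Rtot = Rtot, L = L),
            class = "egfr_state")
}

#' @export
print.egfr_state <- function(x, ...) {
  cat(sprintf("Receptor equilibrium at Rtot = %g receptors/cell, [EGF] = %g nM\n",
              x$Rtot, x$L))
  print(signif(x$species, 4))
  cat(sprintf("Bound EGF: %g molecules/cell (%.1f%% of receptors)\n",
              x$bound, if (x$Rtot > 0) 100 * x$bound / x$Rtot else 0))
  invisible(x)
}

#' Predicted saturation-binding curve
#'
#' Bound EGF (molecules/cell, counting both ligands of doubly liganded
#' dimers) across a grid of free EGF concentrations.
#'
#' @inheritParams solve_equilibrium
#' @param L_grid non-empty, non-decreasing vector of EGF concentrations (nM).
#' @return Numeric vector of bound EGF, one value per grid point; bound is
#'   non-decreasing in `L` and never exceeds `Rtot`.
#' @export
binding_curve <- function(params, Rtot, L_grid) {
  validate_params(params)
  if (length(L_grid) == 0) stop("L_grid must not be empty")
  if (any(!is.finite(L_grid)) || any(L_grid < 0))
    stop("L_grid must be finite and non-negative")
  if (is.unsorted(L_grid)) stop("L_grid must be sorted ascending")
  if (Rtot == 0) return(rep(0, length(L_grid)))
  EI <- ei_root(unclass(params), Rtot, L_grid)
  unname(bound_from_species(species_from_ei(unclass(params), EI, L_grid)))
}

#' Receptor-species composition as fractions of total receptors
#'
#' @inheritParams solve_equilibrium
#' @return Named numeric vector over the 12 species; dimer species count two
#'   receptors, so fractions sum to one.
#' @export
species_fractions <- function(params, Rtot, L) {
  if (Rtot <= 0) stop("species fractions undefined for Rtot <= 0")
  st <- solve_equilibrium(params, Rtot, L)
  w <- c(rep(1, 6), rep(2, 6))
  st$species * w / Rtot
}

#' Fraction of receptors residing in dimers
#'
#' @inheritParams solve_equilibrium
#' @return Scalar in `[0, 1]`: `2 * (sum of dimer species) / Rtot`.
#' @export
dimer_fraction <- function(params, Rtot, L) {
  if (Rtot <= 0) stop("dimer fraction undefined for Rtot <= 0")
  st <- solve_equilibrium(params, Rtot, L)
  2 * sum(st$species[7:12]) / Rtot
}

#' @rdname write_params_json
#' @param state an `egfr_state` object from [solve_equilibrium()].
#' @export
write_state_json <- function(state, path) {
  stopifnot(inherits(state, "egfr_state"))
  jsonlite::write_json(c(list(schema_version = 1L),
                         as.list(state$species),
                         list(EGF_bound = state$bound, Rtot = state$Rtot,
                              L = state$L)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
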