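#' Equilibrium constants of the coupled conformation/dimerization/binding model
#'
#' Bundles the nine equilibrium constants describing one experimental
#' condition. `K1` and `K2` are dimensionless conformational equilibrium
#' constants (inactive/active kinase domain and closed/extended extracellular
#' domain; values above 1 favour the first-named state). `K3` is the
#' dissociation constant (nM) of EGF binding to a monomer with extended
#' extracellular domain. `K4` and `K7` are dimer dissociation constants
#' (receptors/cell) of the symmetric-kinase and asymmetric-kinase dimerization
#' pathways. `K5`, `K6` (symmetric) and `K8`, `K9` (asymmetric) are the
#' dissociation constants (nM) of the first and second EGF binding to the
#' respective dimer.
#'
#' @param K1,K2 dimensionless conformational equilibrium constants.
#' @param K3,K5,K6,K8,K9 ligand dissociation constants in nM.
#' @param K4,K7 dimer dissociation constants in receptors/cell.
#' @return An object of class `egfr_params`: a named numeric vector of the
#'   nine constants.
#' @examples
#' p <- egfr_params(K1 = 104, K2 = 2.9, K3 = 1.3, K4 = 36900, K5 = 95,
#'                  K6 = 0.45, K7 = 480, K8 = 0.1, K9 = 2.96)
#' linkage_constants(p)
#' @export
egfr_params <- function(K1, K2, K3, K4, K5, K6, K7, K8, K9) {
  p <- c(K1 = K1, K2 = K2, K3 = K3, K4 = K4, K5 = K5, K6 = K6,
         K7 = K7, K8 = K8, K9 = K9)
  validate_params(p)
  structure(p, class = "egfr_params")
}

validate_params <- function(p) {
  if (length(p) != 9L || !all(names(p) == paste0("K", 1:9)))
    stop("expected nine constants named K1..K9", call. = FALSE)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0))
    stop("all equilibrium constants must be strictly positive and finite",
         call. = FALSE)
  invisible(p)
}

#' Published reference estimates of the equilibrium constants
#'
#' Point estimates of the nine constants obtained by globally fitting the
#' model to flow-cytometric EGF saturation binding on EGFR-GFP expressing CHO
#' cells. `K2`-`K9` are shared between pharmacological conditions; `K1`, the
#' inactive/active kinase-domain equilibrium, is condition specific: erlotinib
#' stabilizes the active conformation (small `K1`), lapatinib the inactive one
#' (large `K1`).
#'
#' @param condition which kinase-inhibitor condition the `K1` value refers to.
#' @return An [egfr_params] object.
#' @seealso [reference_k1()] for the three condition-specific `K1` values.
#' @export
egfr_reference_params <- function(condition = c("untreated", "erlotinib",
                                                "lapatinib")) {
  condition <- match.arg(condition)
  egfr_params(K1 = reference_k1()[[condition]], K2 = 2.9, K3 = 1.3,
              K4 = 36900, K5 = 95, K6 = 0.45, K7 = 480, K8 = 0.1, K9 = 2.96)
}

#' Condition-specific reference values of the kinase conformational constant
#'
#' @return Named numeric vector with the inactive/active kinase-domain
#'   equilibrium constant `K1` for untreated, erlotinib- and lapatinib-treated
#'   cells.
#' @export
reference_k1 <- function() {
  c(untreated = 104, erlotinib = 25, lapatinib = 162)
}

#' Oligomerization linkage constants of the two dimerization pathways
#'
#' Thermodynamic linkage relates the two routes to a doubly liganded dimer:
#' dimerization of two liganded monomers, or dimerization followed by two
#' successive ligand bindings. The effective dissociation constant for
#' dimerization of liganded monomers is `K4*K5*K6/K3^2` on the
#' symmetric-kinase (inactive) pathway and `K7*K8*K9/K3^2` on the
#' asymmetric-kinase (active) pathway, in receptors/cell. A value larger than
#' the corresponding unliganded dimer constant (`K4` resp. `K7`) means
#' negative linkage: ligand binding opposes dimerization.
#'
#' @param params an [egfr_params] object.
#' @return Named numeric vector `c(D_inactive =, D_active =)` in
#'   receptors/cell.
#' @export
linkage_constants <- function(params) {
  validate_params(params)
  c(D_inactive = unname(params["K4"] * params["K5"] * params["K6"] /
                          params["K3"]^2),
    D_active = unname(params["K7"] * params["K8"] * params["K9"] /
                        params["K3"]^2))
}

#' @export
print.egfr_params <- function(x, ...) {
  cat("Equilibrium constants (K1,K2 dimensionless; K3,K5,K6,K8,K9 nM;",
      "K4,K7 receptors/cell)\n")
  print(signif(unclass(x), 4))
  lk <- linkage_constants(x)
  cat(sprintf("Liganded-monomer dimerization: inactive pathway %.3g, active pathway %.3g receptors/cell\n",
              lk["D_inactive"], lk["D_active"]))
  invisible(x)
}

#' Read or write equilibrium constants as JSON
#'
#' @param params an [egfr_params] object.
#' @param path file path.
#' @return `read_params_json` returns an [egfr_params] object;
#'   `write_params_json` returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(c(list(schema_version = 1L), as.list(unclass(params))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(egfr_params, as.list(unlist(x[paste0("K", 1:9)])))
}
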