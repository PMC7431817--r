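#' One cell of a multi-condition binding design
#'
#' A design cell pairs one saturation-binding curve with its metadata: the
#' pharmacological condition (which selects the condition-specific `K1`), the
#' expression gate, and the receptor number of that gated subpopulation.
#'
#' @param condition condition label, e.g. `"untreated"`, `"erlotinib"`,
#'   `"lapatinib"`.
#' @param gate expression-gate label, e.g. `"low"`, `"medium"`, `"high"`,
#'   `"all"`.
#' @param Rtot receptor number per cell for this subpopulation (> 0).
#' @param curve a [binding_data] object.
#' @return An object of class `design_cell`.
#' @export
design_cell <- function(condition, gate, Rtot, curve) {
  stopifnot(is.character(condition), is.character(gate),
            inherits(curve, "binding_curve"))
  if (!is.finite(Rtot) || Rtot <= 0) stop("Rtot must be > 0")
  structure(list(condition = condition, gate = gate, Rtot = Rtot,
                 curve = curve),
            class = "design_cell")
}

validate_design <- function(design) {
  if (!is.list(design) || length(design) < 2)
    stop("design must be a list of at least 2 design_cell objects")
  if (!all(vapply(design, inherits, logical(1), "design_cell")))
    stop("design must be a list of design_cell objects")
  keys <- vapply(design, function(d) paste(d$condition, d$gate), character(1))
  if (anyDuplicated(keys))
    stop("condition/gate combinations must be unique within a design")
  npts <- vapply(design, function(d) nrow(d$curve), integer(1))
  if (any(npts < 8)) stop("every curve needs at least 8 points")
  invisible(design)
}

#' Configuration of the global fit
#'
#' @param starts number of Latin-hypercube multi-start points (>= 1).
#' @param repeats number of bootstrap repeats for [confidence_intervals()].
#' @param seed integer RNG seed controlling starts and bootstrap draws.
#' @param bounds_decades half-width, in log10 decades, of the box bounds
#'   around the reference magnitudes of each constant.
#' @param centers named vector of reference magnitudes used as box centres;
#'   `K1` entries are taken per condition from [reference_k1()] for known
#'   condition names (unknown conditions default to the untreated value).
#' @param scale_per `"condition"` shares one nuisance intensity scale across
#'   all gates of a condition (fluorophore and instrument settings are common
#'   within a staining); `"dataset"` gives every curve its own scale.
#' @param weighted weight squared deviations by `1/sem^2`.
#' @param fix optional named numeric vector of parameters held constant
#'   during optimization (e.g. `c(K2 = 2.9, K5 = 95)`). The binding
#'   observable determines only nine independent combinations of the eleven
#'   parameters (see the methods vignette); fixing two gauge parameters makes
#'   the rest identifiable.
#' @param ci_method `"bootstrap"` perturbs intensities by their SEM and
#'   refits; `"restart"` re-runs the multi-start optimization on the original
#'   data with fresh starts and reports the spread of optima.
#' @param boot_starts number of optimizer starts per bootstrap repeat (the
#'   point estimate is always included as a start).
#' @return A list of class `global_fit_config`.
#' @export
global_fit_config <- function(starts = 40L, repeats = 100L, seed = 1L,
                              bounds_decades = 2, centers = NULL,
                              scale_per = c("condition", "dataset"),
                              weighted = FALSE, fix = NULL,
                              ci_method = c("bootstrap", "restart"),
                              boot_starts = 3L) {
  stopifnot(starts >= 1, repeats >= 1, bounds_decades > 0, boot_starts >= 1)
  structure(list(starts = as.integer(starts), repeats = as.integer(repeats),
                 seed = as.integer(seed), bounds_decades = bounds_decades,
                 centers = centers, scale_per = match.arg(scale_per),
                 weighted = weighted, fix = fix,
                 ci_method = match.arg(ci_method),
                 boot_starts = as.integer(boot_starts)),
            class = "global_fit_config")
}

# parameter vector layout: K1_<condition> for each condition, then K2..K9
param_layout <- function(design) {
  conds <- unique(vapply(design, function(d) d$condition, character(1)))
  list(conds = conds, names = c(paste0("K1_", conds), paste0("K", 2:9)))
}

default_centers <- function(layout) {
  k1ref <- reference_k1()
  k1 <- vapply(layout$conds, function(cn)
    if (cn %in% names(k1ref)) k1ref[[cn]] else k1ref[["untreated"]],
    numeric(1))
  shared <- unclass(egfr_reference_params())[2:9]
  stats::setNames(c(k1, shared), layout$names)
}

params_for_condition <- function(theta, layout, condition) {
  egfr_params(K1 = theta[[paste0("K1_", condition)]],
              K2 = theta[["K2"]], K3 = theta[["K3"]], K4 = theta[["K4"]],
              K5 = theta[["K5"]], K6 = theta[["K6"]], K7 = theta[["K7"]],
              K8 = theta[["K8"]], K9 = theta[["K9"]])
}

# bound ligand without materializing the full species matrix (fitting hot path)
bound_direct <- function(theta, condition, Rtot, L) {
  K1 <- theta[[paste0("K1_", condition)]]
  K3 <- theta[["K3"]]; K5 <- theta[["K5"]]; K6 <- theta[["K6"]]
  K8 <- theta[["K8"]]; K9 <- theta[["K9"]]
  b <- (1 + 1 / K1) * (theta[["K2"]] + 1 + L / K3)
  dS <- 1 / theta[["K4"]]; dA <- 1 / (K1^2 * theta[["K7"]])
  a <- 2 * (dS * (1 + L / K5 + L^2 / (K5 * K6)) +
            dA * (1 + L / K8 + L^2 / (K8 * K9)))
  EI <- 2 * Rtot / (b + sqrt(b^2 + 4 * a * Rtot))
  EI * L / K3 * (1 + 1 / K1) +
    EI^2 * (dS * (L / K5 + 2 * L^2 / (K5 * K6)) +
            dA * (L / K8 + 2 * L^2 / (K8 * K9)))
}

# predicted bound curves and profiled scales for a full parameter vector.
# For fixed model parameters the least-squares scale for a group of curves
# is s = sum(w*I*b) / sum(w*b^2), the closed-form minimizer of the group SSE.
global_model <- function(theta, design, layout, scale_per, w) {
  pred <- vector("list", length(design))
  for (i in seq_along(design)) {
    d <- design[[i]]
    pred[[i]] <- bound_direct(theta, d$condition, d$Rtot, d$curve$conc_nM)
  }
  groups <- if (scale_per == "condition")
    vapply(design, function(d) d$condition, character(1))
  else
    vapply(design, function(d) paste(d$condition, d$gate), character(1))
  scales <- stats::setNames(numeric(length(unique(groups))), unique(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    num <- sum(unlist(lapply(idx, function(i)
      w[[i]] * design[[i]]$curve$intensity * pred[[i]])))
    den <- sum(unlist(lapply(idx, function(i) w[[i]] * pred[[i]]^2)))
    scales[g] <- if (den > 0) num / den else 0
  }
  fitted <- lapply(seq_along(design), function(i) scales[[groups[i]]] * pred[[i]])
  list(fitted = fitted, scales = scales, groups = groups)
}

#' Globally fit the equilibrium model to a multi-condition binding design
#'
#' Minimizes the sum over all datasets of squared deviations between measured
#' intensities and `scale * bound(params, Rtot, L)`, with `K2`-`K9` shared
#' across all datasets and `K1` free per condition. Optimization runs in
#' log10 parameter space inside box bounds, from `starts` Latin-hypercube
#' start points refined by Levenberg-Marquardt least squares; nuisance
#' intensity scales are profiled out analytically at every step. Among
#' equal-norm optima the one with the smallest `K7` is returned, which makes
#' the result deterministic for a given seed.
#'
#' @param design list of [design_cell] objects (>= 2, unique
#'   condition/gate, >= 8 points per curve).
#' @param config a [global_fit_config] object.
#' @return Object of class `egfr_global_fit`: list with `par` (all model
#'   parameters on the natural scale, including any fixed ones), `k1` (per
#'   condition), `scales`, `norm`, `start_norms`, `boundary` (names of
#'   parameters that ended on a box bound), `config`, `design`, `layout`.
#' @export
fit_global <- function(design, config = global_fit_config()) {
  validate_design(design)
  stopifnot(inherits(config, "global_fit_config"))
  layout <- param_layout(design)
  centers <- config$centers
  if (is.null(centers)) centers <- default_centers(layout)
  if (!all(layout$names %in% names(centers)))
    stop("centers must name every parameter: ",
         paste(layout$names, collapse = ", "))
  centers <- centers[layout$names]

  w <- lapply(design, function(d) {
    if (!config$weighted) return(rep(1, nrow(d$curve)))
    if (any(is.na(d$curve$sem)) || any(d$curve$sem <= 0))
      stop("weighted fit requires positive sem on every curve")
    1 / d$curve$sem^2
  })

  fixed <- config$fix
  if (!is.null(fixed) && !all(names(fixed) %in% layout$names))
    stop("fix names must be among: ", paste(layout$names, collapse = ", "))
  free <- setdiff(layout$names, names(fixed))
  if (length(free) == 0) stop("no free parameters left after fixing")

  theta_full <- function(th_free) {
    th <- stats::setNames(numeric(length(layout$names)), layout$names)
    th[free] <- 10^th_free
    if (!is.null(fixed)) th[names(fixed)] <- fixed
    th
  }
  resid_fn <- function(th_free) {
    gm <- global_model(theta_full(th_free), design, layout,
                       config$scale_per, w)
    unlist(lapply(seq_along(design), function(i)
      sqrt(w[[i]]) * (design[[i]]$curve$intensity - gm$fitted[[i]])))
  }

  lo <- log10(centers[free]) - config$bounds_decades
  hi <- log10(centers[free]) + config$bounds_decades
  set.seed(config$seed)
  grid <- lhs::maximinLHS(config$starts, length(free))
  starts <- t(apply(grid, 1, function(x) lo + x * (hi - lo)))
  if (config$starts == 1L) starts <- matrix((lo + hi) / 2, 1)

  fits <- list(); msgs <- character(0)
  for (i in seq_len(config$starts)) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn, lower = lo,
                         upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) e)
    if (inherits(f, "error")) msgs <- c(msgs, conditionMessage(f))
    else fits[[length(fits) + 1]] <- f
  }
  if (length(fits) == 0)
    stop("all optimizer starts failed: ", paste(unique(msgs), collapse = "; "))
  norms <- vapply(fits, function(f) f$deviance, numeric(1))
  sumI2 <- sum(unlist(lapply(seq_along(design), function(i)
    w[[i]] * design[[i]]$curve$intensity^2)))
  # equal-norm ties (within numerical noise of the best) broken by smallest K7
  tie <- which(norms <= min(norms) + 1e-9 * sumI2)
  k7 <- vapply(fits[tie], function(f) theta_full(f$par)[["K7"]], numeric(1))
  best <- fits[[tie[which.min(k7)]]]
  # polish
  best <- minpack.lm::nls.lm(par = best$par, fn = resid_fn, lower = lo,
                             upper = hi,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  th <- theta_full(best$par)
  gm <- global_model(th, design, layout, config$scale_per, w)
  at_bound <- free[best$par <= lo + 1e-6 | best$par >= hi - 1e-6]
  if (length(at_bound))
    warning("parameter(s) at a box bound: ", paste(at_bound, collapse = ", "))
  structure(list(par = th, k1 = stats::setNames(
                   th[paste0("K1_", layout$conds)], layout$conds),
                 scales = gm$scales, norm = best$deviance,
                 start_norms = norms, boundary = at_bound,
                 free = free, fixed = fixed, bounds = cbind(lo = lo, hi = hi),
                 config = config, design = design, layout = layout,
                 weights = w),
            class = "egfr_global_fit")
}

#' @export
coef.egfr_global_fit <- function(object, ...) object$par

#' @export
print.egfr_global_fit <- function(x, ...) {
  cat(sprintf("Global equilibrium-model fit: %d datasets, %d data points\n",
              length(x$design),
              sum(vapply(x$design, function(d) nrow(d$curve), integer(1)))))
  cat(sprintf("  residual norm %.6g over %d starts (best of %d converged)\n",
              x$norm, x$config$starts, length(x$start_norms)))
  if (!is.null(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "=", signif(x$fixed, 4),
                          collapse = ", "), "\n")
  print(signif(x$par, 4))
  cat("  intensity scales:\n")
  print(signif(x$scales, 4))
  invisible(x)
}

#' @export
summary.egfr_global_fit <- function(object, ...) {
  lk <- linkage_constants(params_for_condition(object$par, object$layout,
                                               object$layout$conds[1]))
  structure(list(fit = object, linkage = lk), class = "summary.egfr_global_fit")
}

#' @export
print.summary.egfr_global_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Linkage constants: inactive pathway %.3g, active pathway %.3g receptors/cell\n",
              x$linkage["D_inactive"], x$linkage["D_active"]))
  if (length(x$fit$boundary))
    cat("  WARNING: at bound:", paste(x$fit$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Fitted intensity curves for every dataset of a design
#'
#' @param object an `egfr_global_fit`.
#' @param design a design to predict for; defaults to the fitted one.
#' @param ... unused.
#' @return Named list (condition/gate) of fitted intensity vectors,
#'   `scale * bound` on each curve's concentration grid.
#' @export
predict.egfr_global_fit <- function(object, design = object$design, ...) {
  w <- lapply(design, function(d) rep(1, nrow(d$curve)))
  gm <- global_model(object$par, design, param_layout(design),
                     object$config$scale_per, w)
  # reuse the fitted scales rather than re-profiling on new data
  groups <- gm$groups
  out <- lapply(seq_along(design), function(i) {
    sc <- if (groups[i] %in% names(object$scales))
      object$scales[[groups[i]]] else gm$scales[[groups[i]]]
    d <- design[[i]]
    sc * binding_curve(params_for_condition(object$par, object$layout,
                                            d$condition),
                       d$Rtot, d$curve$conc_nM)
  })
  names(out) <- vapply(design, function(d) paste(d$condition, d$gate, sep = "/"),
                       character(1))
  out
}

#' @export
residuals.egfr_global_fit <- function(object, ...) {
  fitted <- predict(object)
  res <- lapply(seq_along(object$design), function(i)
    object$design[[i]]$curve$intensity - fitted[[i]])
  names(res) <- names(fitted)
  res
}

#' Repeat-fit confidence intervals for the global fit
#'
#' Repeats the optimization `repeats` times and reports the 2.5 and 97.5
#' percentiles of every free parameter. With `ci_method = "bootstrap"`
#' (default) each repeat perturbs every intensity by a Gaussian draw with its
#' SEM (parametric bootstrap) and refits starting from the point estimate
#' plus `boot_starts - 1` fresh Latin-hypercube starts. With
#' `ci_method = "restart"` the original data are refitted from fresh random
#' starts and the spread of the optima is reported.
#'
#' @param fit an `egfr_global_fit`.
#' @param repeats number of repeats; defaults to the fit's config.
#' @param seed RNG seed; defaults to the fit's seed + 1.
#' @return Object of class `egfr_ci`: list with `ci` (matrix with rows
#'   `lo`/`hi`), `estimates` (repeats x parameters), `converged`.
#' @export
confidence_intervals <- function(fit, repeats = NULL, seed = NULL) {
  stopifnot(inherits(fit, "egfr_global_fit"))
  cfg <- fit$config
  if (is.null(repeats)) repeats <- cfg$repeats
  if (is.null(seed)) seed <- cfg$seed + 1L
  design <- fit$design
  sems <- lapply(design, function(d) d$curve$sem)
  if (cfg$ci_method == "bootstrap" &&
      any(vapply(sems, function(s) any(is.na(s)), logical(1))))
    stop("bootstrap confidence intervals require sem on every curve")
  set.seed(seed)
  lo <- fit$bounds[, "lo"]; hi <- fit$bounds[, "hi"]
  point <- log10(fit$par[fit$free])
  est <- matrix(NA_real_, repeats, length(fit$free),
                dimnames = list(NULL, fit$free))
  ok <- logical(repeats)
  for (r in seq_len(repeats)) {
    des_r <- design
    if (cfg$ci_method == "bootstrap") {
      for (i in seq_along(des_r)) {
        s <- sems[[i]]
        des_r[[i]]$curve$intensity <- des_r[[i]]$curve$intensity +
          stats::rnorm(length(s), 0, s)
      }
      n_extra <- cfg$boot_starts - 1L
    } else {
      n_extra <- cfg$starts
    }
    starts <- if (cfg$ci_method == "bootstrap")
      rbind(point, extra_starts(n_extra, lo, hi))
    else extra_starts(n_extra, lo, hi)
    f <- refit_from_starts(des_r, fit, starts)
    if (!is.null(f)) { est[r, ] <- 10^f$par; ok[r] <- TRUE }
  }
  if (mean(ok) < 0.5)
    stop(sprintf("unreliable confidence intervals: only %d of %d repeats converged",
                 sum(ok), repeats))
  ci <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("lo", "hi")
  structure(list(ci = ci, estimates = est[ok, , drop = FALSE],
                 converged = sum(ok), repeats = repeats,
                 method = cfg$ci_method),
            class = "egfr_ci")
}

extra_starts <- function(n, lo, hi) {
  if (n <= 0) return(matrix(numeric(0), 0, length(lo)))
  g <- lhs::randomLHS(n, length(lo))
  t(apply(g, 1, function(x) lo + x * (hi - lo)))
}

refit_from_starts <- function(design, fit, starts) {
  cfg <- fit$config
  layout <- fit$layout
  w <- fit$weights
  fixed <- fit$fixed; free <- fit$free
  theta_full <- function(th_free) {
    th <- stats::setNames(numeric(length(layout$names)), layout$names)
    th[free] <- 10^th_free
    if (!is.null(fixed)) th[names(fixed)] <- fixed
    th
  }
  resid_fn <- function(th_free) {
    gm <- global_model(theta_full(th_free), design, layout, cfg$scale_per, w)
    unlist(lapply(seq_along(design), function(i)
      sqrt(w[[i]]) * (design[[i]]$curve$intensity - gm$fitted[[i]])))
  }
  lo <- fit$bounds[, "lo"]; hi <- fit$bounds[, "hi"]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn, lower = lo,
                         upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
      best <- f
  }
  best
}

#' @export
print.egfr_ci <- function(x, ...) {
  cat(sprintf("95%% confidence intervals (%s, %d/%d repeats converged)\n",
              x$method, x$converged, x$repeats))
  print(signif(t(x$ci), 4))
  invisible(x)
}

#' Read a binding design from a CSV manifest
#'
#' The manifest has header `condition,gate,Rtot,curve_file`; `curve_file`
#' paths are resolved relative to the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return List of [design_cell] objects.
#' @export
read_design <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "gate", "Rtot", "curve_file")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("malformed manifest ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(m)), function(i)
    design_cell(m$condition[i], m$gate[i], m$Rtot[i],
                read_binding_curve(file.path(base, m$curve_file[i]))))
}

#' Write a binding design (manifest plus per-curve CSVs) to a directory
#'
#' @param design list of [design_cell] objects.
#' @param dir output directory, created if needed.
#' @return Path of the manifest, invisibly.
#' @export
write_design <- function(design, dir) {
  validate_design(design)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(design, function(d) {
    fn <- sprintf("curve_%s_%s.csv", d$condition, d$gate)
    write_binding_curve(d$curve, file.path(dir, fn))
    data.frame(condition = d$condition, gate = d$gate, Rtot = d$Rtot,
               curve_file = fn)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_params_json
#' @param fit_global_result an `egfr_global_fit` object.
#' @export
write_global_fit_json <- function(fit_global_result, path) {
  stopifnot(inherits(fit_global_result, "egfr_global_fit"))
  x <- fit_global_result
  jsonlite::write_json(
    list(schema_version = 1L, parameters = as.list(x$par),
         scales = as.list(x$scales), norm = x$norm,
         fixed = if (is.null(x$fixed)) NULL else as.list(x$fixed),
         boundary = x$boundary, start_norms = x$start_norms,
         scale_per = x$config$scale_per, weighted = x$config$weighted,
         seed = x$config$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
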