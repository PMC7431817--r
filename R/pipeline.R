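#' Run one stage of the analysis pipeline
#'
#' Thin programmatic entry point tying the stages together; also the backend
#' of the `inst/cli/egfrbind` command-line wrapper. `config` is a named list
#' (or path to a JSON file holding one) with at least `subcommand` and the
#' arguments that stage needs; every stage writes its results as JSON/CSV
#' next to `out` and logs what it did.
#'
#' Subcommands:
#' \describe{
#'   \item{`linkage`}{`params` (JSON path) -> prints and returns the two
#'     linkage constants.}
#'   \item{`fit-hill`}{`input` curve CSV, optional `blank`, `weighted`;
#'     writes `<out>.json`.}
#'   \item{`fit-global`}{`manifest` CSV, optional `seed`, `starts`,
#'     `scale_per`, `weighted`, `fix` (named list); writes `<out>.json` and a
#'     per-start log `<out>.log`.}
#'   \item{`predict-species`}{`params` JSON, `Rtot`, `L`; writes the species
#'     state as JSON.}
#'   \item{`fret-fit`}{`input` bleach CSV, optional `reps`, `seed`; writes
#'     the cluster fit (with Monte-Carlo CI when `reps > 0`).}
#'   \item{`simulate-binding`}{optional generator settings (`cv`,
#'     `replicates`, `seed`, ...); writes a design directory.}
#'   \item{`simulate-fret`}{optional `N`, `mon`, `sd`, `seed`; writes a
#'     bleach-series CSV.}
#' }
#'
#' @param config named list or path to a JSON config file.
#' @return The result object of the stage, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$subcommand)) stop("config$subcommand is required")
  out <- config$out %||% "result"
  res <- switch(
    config$subcommand,
    "linkage" = {
      lk <- linkage_constants(read_params_json(config$params))
      cat(sprintf("D_inactive (K4*K5*K6/K3^2) = %.6g receptors/cell\n",
                  lk["D_inactive"]))
      cat(sprintf("D_active   (K7*K8*K9/K3^2) = %.6g receptors/cell\n",
                  lk["D_active"]))
      lk
    },
    "fit-hill" = {
      cv <- read_binding_curve(config$input)
      if (!is.null(config$blank)) cv <- background_correct(cv, config$blank)
      f <- fit_hill(cv, weighted = isTRUE(config$weighted))
      write_hill_json(f, paste0(out, ".json"))
      f
    },
    "fit-global" = {
      design <- read_design(config$manifest)
      cfg <- global_fit_config(
        starts = config$starts %||% 40L, seed = config$seed %||% 1L,
        scale_per = config$scale_per %||% "condition",
        weighted = isTRUE(config$weighted),
        fix = if (is.null(config$fix)) NULL else unlist(config$fix))
      f <- fit_global(design, cfg)
      write_global_fit_json(f, paste0(out, ".json"))
      writeLines(c(sprintf("seed %d, %d starts, scale_per %s",
                           cfg$seed, cfg$starts, cfg$scale_per),
                   sprintf("start %d: norm %.8g", seq_along(f$start_norms),
                           f$start_norms)),
                 paste0(out, ".log"))
      f
    },
    "predict-species" = {
      st <- solve_equilibrium(read_params_json(config$params),
                              Rtot = config$Rtot, L = config$L)
      write_state_json(st, paste0(out, ".json"))
      st
    },
    "fret-fit" = {
      ser <- read_bleach_series(config$input)
      reps <- config$reps %||% 500L
      f <- if (reps > 0) mc_confidence(ser, reps = reps,
                                       seed = config$seed %||% 1L)
           else fit_bleach_series(ser)
      write_cluster_fit_json(f, paste0(out, ".json"))
      f
    },
    "simulate-binding" = {
      des <- binding_sim_design(
        conc_max = config$conc_max %||% 260,
        n_conc = config$n_conc %||% 14L,
        replicates = config$replicates %||% 3L,
        cv = config$cv %||% 0.05,
        seed = config$seed %||% 1L)
      cells <- simulate_binding_experiment(des)
      write_design(cells, out)
      cells
    },
    "simulate-fret" = {
      des <- fret_sim_design(N = config$N %||% 4L, mon = config$mon %||% 0.2,
                             sd = config$sd %||% 0.003,
                             seed = config$seed %||% 1L)
      ser <- simulate_bleach_experiment(des)
      write_bleach_series(ser, paste0(out, ".csv"))
      ser
    },
    stop("unknown subcommand: ", config$subcommand)
  )
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
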