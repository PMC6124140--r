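#' Solver settings for season integration
#'
#' @param method `deSolve` integration method; the default `"lsoda"`
#'   switches automatically between stiff and non-stiff regimes, which
#'   the plankton dynamics require.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param hmax maximum step size in days (`NULL` = unlimited).
#' @param floor biomass floor epsilon (ugC m^-3); any biomass component
#'   below it is clamped up to it by a daily event, protecting against
#'   stiff-solver undershoot without affecting dynamics at realistic
#'   densities.
#' @return List of solver settings.
#' @export
solver_control <- function(method = "lsoda", rtol = 1e-8, atol = 1e-10,
                           hmax = NULL, floor = 1e-9) {
  list(method = method, rtol = rtol, atol = atol, hmax = hmax, floor = floor)
}

#' Integrate one 90-day growth season
#'
#' Runs the within-season ODE system from a season-start state,
#' integrating alongside the biomasses the per-fish-stage net-production
#' ledger `dP = x B (y sum(F) - 1)` and, in fishing years, the catch
#' ledger `dC = F_max S B`. A daily event clamps biomasses below the
#' floor epsilon up to it.
#'
#' @param B_start named biomass vector at day 0 (after stocking).
#' @param web a validated [foodweb()] object.
#' @param policy optional [harvest_policy()].
#' @param fishing_active logical; apply the policy this season?
#' @param season_length season length in days.
#' @param record_days days within the season at which biomasses are
#'   recorded (default mid-season day 45 and end of season).
#' @param solver a [solver_control()] list.
#' @return List with `record` (matrix, record days x guilds), `B_end`
#'   (named, clamped at the floor), `production` (named per fish stage,
#'   floored at 0 at read-out), `production_raw` (unfloored integral),
#'   and `catch` (named per fish stage).
#' @export
integrate_season <- function(B_start, web, policy = NULL,
                             fishing_active = FALSE, season_length = 90,
                             record_days = c(45, 90),
                             solver = solver_control()) {
  stopifnot(season_length > 0)
  B0 <- as_state(B_start, web)
  if (any(B0 < 0)) stop("negative season-start biomass for: ",
                        paste(names(B0)[B0 < 0], collapse = ", "))
  hr <- if (!is.null(policy) && fishing_active) harvest_rates(web, policy) else NULL
  p <- compile_web(web, harvest_rates = hr, floor = solver$floor)
  n <- attr(p, "n")
  ids <- attr(p, "ids")
  fids <- fish_stage_ids(web)
  nf <- length(fids)

  record_days <- sort(unique(pmin(record_days, season_length)))
  times <- sort(unique(c(0, seq_len(season_length), record_days)))
  y0 <- c(unname(B0), numeric(2 * nf))

  args <- list(y = y0, times = times, func = "atn_derivs",
               parms = pad_parms(p), dllname = "atnstock",
               initfunc = "atn_initmod", method = solver$method,
               rtol = solver$rtol, atol = solver$atol,
               events = list(func = "atn_event", time = seq_len(season_length)))
  if (!is.null(solver$hmax)) args$hmax <- solver$hmax
  sol <- try(do.call(deSolve::ode, args), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times))
    stop("season integration failed: ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "solver stopped early")

  tvec <- sol[, 1]
  Bmat <- sol[, 1 + seq_len(n), drop = FALSE]
  colnames(Bmat) <- ids
  rec <- Bmat[match(record_days, tvec), , drop = FALSE]
  rownames(rec) <- record_days

  last <- nrow(sol)
  B_end <- pmax(setNames(Bmat[last, ], ids), solver$floor)
  if (nf > 0) {
    P_raw <- setNames(sol[last, 1 + n + seq_len(nf)], fids)
    catch <- setNames(sol[last, 1 + n + nf + seq_len(nf)], fids)
  } else {
    P_raw <- catch <- setNames(numeric(0), character(0))
  }
  list(record = rec, B_end = B_end,
       production = pmax(P_raw, 0), production_raw = P_raw, catch = catch)
}

#' Default season-start state for a web
#'
#' Producers split the carrying capacity evenly, consumers start at a
#' tenth of their half-saturation density and fish stages at
#' 10 ugC m^-3; the unfished burn-in period acts as the spin-up towards
#' the web's dynamic equilibrium.
#'
#' @param web a [foodweb()] object.
#' @return Named biomass vector.
#' @export
default_initial_state <- function(web) {
  g <- web$guilds
  B <- setNames(numeric(nrow(g)), g$id)
  prod <- g$role == "producer"
  B[prod] <- web$K / sum(prod)
  cons <- g$role == "consumer"
  B[cons] <- g$B0[cons] / 10
  B[g$role == "fish_stage"] <- 10
  B
}

#' Scenario configuration
#'
#' Bundles everything one multi-year run needs: the web, the stocking
#' plan, the harvest policy and the period structure (a fishing-free
#' burn-in followed by a fished period).
#'
#' @param web a validated [foodweb()] object.
#' @param stocking named list, species -> larval stocking density
#'   (ugC m^-3) added at day 0 of every season (or a per-year vector).
#' @param harvest a [harvest_policy()].
#' @param years_unfished,years_fished lengths of the unfished and
#'   fished periods in years.
#' @param season_length growth-season length in days.
#' @param record_days in-season days recorded each year.
#' @param solver a [solver_control()].
#' @param init optional named initial biomass vector; default
#'   [default_initial_state()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(web, stocking = list(), harvest = harvest_policy(),
                            years_unfished = 100, years_fished = 100,
                            season_length = 90, record_days = c(45, 90),
                            solver = solver_control(), init = NULL) {
  stopifnot(inherits(web, "foodweb"), years_unfished >= 0, years_fished >= 0,
            season_length > 0)
  validate_web(web)
  structure(list(web = web, stocking = stocking, harvest = harvest,
                 years_unfished = as.integer(years_unfished),
                 years_fished = as.integer(years_fished),
                 season_length = season_length, record_days = record_days,
                 solver = solver, init = init),
            class = "scenario_config")
}

#' Run a multi-year stocking scenario
#'
#' Chains growth seasons across years. Every year: stock larvae at day
#' 0, integrate the season ODE, then apply the end-of-season stage
#' transition and recruitment. Fishing is active in every year after
#' the unfished burn-in. The model is fully deterministic: identical
#' configurations give identical results.
#'
#' @param config a [scenario_config()].
#' @return An object of class `scenario_result` with `biomass`
#'   (years x record-days x guilds array), `catch` and `production`
#'   (years x fish-stage matrices), `B_final`, and the echoed period
#'   structure.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  web <- config$web
  ids <- guild_ids(web)
  fids <- fish_stage_ids(web)
  nyears <- config$years_unfished + config$years_fished
  B <- if (is.null(config$init)) default_initial_state(web)
       else as_state(config$init, web)

  if (nyears == 0) {
    return(structure(list(
      biomass = array(NA_real_, c(0, length(config$record_days), length(ids))),
      catch = matrix(NA_real_, 0, length(fids)),
      production = matrix(NA_real_, 0, length(fids)),
      B_final = B, years_unfished = 0L, years_fished = 0L,
      record_days = config$record_days, stocking = config$stocking,
      harvest = config$harvest), class = "scenario_result"))
  }

  rd <- sort(unique(pmin(config$record_days, config$season_length)))
  biomass <- array(NA_real_, c(nyears, length(rd), length(ids)),
                   dimnames = list(NULL, rd, ids))
  catch <- matrix(0, nyears, length(fids), dimnames = list(NULL, fids))
  production <- matrix(0, nyears, length(fids), dimnames = list(NULL, fids))

  for (yr in seq_len(nyears)) {
    fishing <- yr > config$years_unfished
    B <- apply_stocking(B, config$stocking, web, year = yr)
    season <- tryCatch(
      integrate_season(B, web, policy = config$harvest,
                       fishing_active = fishing,
                       season_length = config$season_length,
                       record_days = rd, solver = config$solver),
      error = function(e) stop("year ", yr, ": ", conditionMessage(e)))
    biomass[yr, , ] <- season$record[as.character(rd), ids]
    if (length(fids)) {
      catch[yr, ] <- season$catch[fids]
      production[yr, ] <- season$production[fids]
    }
    B <- end_of_season_transition(season$B_end, season$production, web)
  }

  structure(list(biomass = biomass, catch = catch, production = production,
                 B_final = B, years_unfished = config$years_unfished,
                 years_fished = config$years_fished, record_days = rd,
                 stocking = config$stocking, harvest = config$harvest),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d + %d years (unfished + fished), %d guilds\n",
              x$years_unfished, x$years_fished, dim(x$biomass)[3]))
  invisible(x)
}

#' Stocking plans of the named scenario presets
#'
#' `wht200` is the baseline (whitefish larvae stocked at 200 ugC m^-3),
#' `wht300` raises whitefish stocking to 300, and `wht300_per50`
#' additionally stocks perch larvae at 50 ugC m^-3.
#'
#' @param preset one of `"wht200"`, `"wht300"`, `"wht300_per50"`.
#' @param whitefish,perch species names used in the plan.
#' @return Named list usable as the `stocking` argument of
#'   [scenario_config()].
#' @export
preset_stocking <- function(preset = c("wht200", "wht300", "wht300_per50"),
                            whitefish = "whitefish", perch = "perch") {
  preset <- match.arg(preset)
  switch(preset,
         wht200 = setNames(list(200, 0), c(whitefish, perch)),
         wht300 = setNames(list(300, 0), c(whitefish, perch)),
         wht300_per50 = setNames(list(300, 50), c(whitefish, perch)))
}

#' Run the stocking experiment: named preset arms plus robustness grids
#'
#' Runs the three named arms (baseline `wht200`, increased whitefish
#' stocking `wht300`, and added perch stocking `wht300_per50`) from a
#' shared web and initial state, with identical configuration except
#' the stocking densities. Optional robustness arms vary the whitefish
#' density by +-50, the perch density by +-25 ugC m^-3, and the
#' maximum fishing mortality numerator over {0.4, 0.5, 0.6} (divided by
#' season length + 1).
#'
#' @param web a validated [foodweb()] object.
#' @param years_unfished,years_fished period lengths in years.
#' @param robustness if `TRUE`, also run the robustness arms.
#' @param ... further arguments passed to [scenario_config()].
#' @return Named list of [run_scenario()] results (class
#'   `experiment_result`); robustness arms are named e.g. `wht250`,
#'   `wht300_per25`, `wht300_fmax0.4`.
#' @export
run_experiment <- function(web, years_unfished = 100, years_fished = 100,
                           robustness = FALSE, ...) {
  arms <- list(wht200 = list(stocking = preset_stocking("wht200")),
               wht300 = list(stocking = preset_stocking("wht300")),
               wht300_per50 = list(stocking = preset_stocking("wht300_per50")))
  if (robustness) {
    for (w in c(250, 350))
      arms[[paste0("wht", w)]] <-
        list(stocking = list(whitefish = w, perch = 0))
    for (p in c(25, 75))
      arms[[paste0("wht300_per", p)]] <-
        list(stocking = list(whitefish = 300, perch = p))
    for (fnum in c(0.4, 0.6))
      arms[[sprintf("wht300_fmax%.1f", fnum)]] <-
        list(stocking = preset_stocking("wht300"),
             harvest = harvest_policy(F_max = fnum / 91))
  }
  out <- lapply(arms, function(arm) {
    cfg <- do.call(scenario_config,
                   c(list(web = web, stocking = arm$stocking,
                          years_unfished = years_unfished,
                          years_fished = years_fished),
                     if (!is.null(arm$harvest)) list(harvest = arm$harvest),
                     list(...)))
    run_scenario(cfg)
  })
  structure(out, class = c("experiment_result", "list"))
}
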