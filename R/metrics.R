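ADULT_PREY_GUILDS <- c("daphnia", "cyclopoid", "leptodora")
LARVAL_PREY_GUILDS <- c("rotifer_small", "rotifer_medium", "rotifer_large",
                        "daphnia", "cyclopoid")

period_years <- function(result, period = c("unfished", "fished", "all")) {
  period <- match.arg(period)
  yu <- result$years_unfished
  yf <- result$years_fished
  switch(period,
         unfished = seq_len(yu),
         fished = if (yf > 0) yu + seq_len(yf) else integer(0),
         all = seq_len(yu + yf))
}

#' Annual biomass series of a guild or guild aggregate
#'
#' @param result a [run_scenario()] result.
#' @param guilds one or more guild ids; several ids are summed.
#' @param day in-season record day (default: end of season).
#' @return Numeric vector, one value per simulated year.
#' @export
guild_series <- function(result, guilds, day = max(result$record_days)) {
  di <- match(as.character(day), dimnames(result$biomass)[[2]])
  if (is.na(di)) stop("day ", day, " was not recorded")
  missing <- setdiff(guilds, dimnames(result$biomass)[[3]])
  if (length(missing))
    stop("guilds not in result: ", paste(missing, collapse = ", "))
  m <- result$biomass[, di, guilds, drop = FALSE]
  as.numeric(rowSums(matrix(m, nrow = dim(m)[1])))
}

#' Aggregate zooplankton prey series
#'
#' `"adult_prey"` sums the zooplankton prey of adult fish (Daphnia,
#' Cyclopoid and Leptodora); `"larval_prey"` sums the shared larval
#' prey set (small, medium and large rotifers, Daphnia and Cyclopoid).
#' A character vector of guild ids defines a custom aggregate.
#'
#' @param result a [run_scenario()] result.
#' @param group `"adult_prey"`, `"larval_prey"` or guild ids.
#' @param day in-season record day (default: end of season).
#' @return Numeric vector, one summed biomass per year.
#' @export
prey_aggregate <- function(result, group = "adult_prey",
                           day = max(result$record_days)) {
  ids <- if (identical(group, "adult_prey")) ADULT_PREY_GUILDS
         else if (identical(group, "larval_prey")) LARVAL_PREY_GUILDS
         else as.character(group)
  missing <- setdiff(ids, dimnames(result$biomass)[[3]])
  if (length(missing))
    stop("aggregate member guilds absent from the web: ",
         paste(missing, collapse = ", "))
  guild_series(result, ids, day = day)
}

#' Percent change of end-of-season biomass, treatment vs. baseline
#'
#' Computes `100 * (treatment - baseline) / baseline` per year for a
#' guild (or summed guild aggregate) at a record day and averages it
#' over the final `window` years of the chosen period. Positive values
#' mean the treatment increased the biomass. Because the system keeps
#' drifting even after a century, single-year comparisons are fragile;
#' the terminal-window mean is the headline statistic and the per-year
#' series is available via `per_year = TRUE`.
#'
#' @param treatment,baseline [run_scenario()] results with identical
#'   period structure.
#' @param guilds guild id(s); several ids are summed before comparison.
#' @param period `"unfished"` or `"fished"`.
#' @param window number of terminal years averaged.
#' @param day in-season record day (default: end of season).
#' @param per_year if `TRUE`, return the per-year percent-change series
#'   for the whole period instead of the terminal-window mean.
#' @return Scalar percent change (or per-year vector). Years with a
#'   zero baseline yield `NA` with a warning.
#' @export
percent_change <- function(treatment, baseline, guilds,
                           period = c("unfished", "fished"), window = 10,
                           day = max(baseline$record_days),
                           per_year = FALSE) {
  period <- match.arg(period)
  if (treatment$years_unfished != baseline$years_unfished ||
      treatment$years_fished != baseline$years_fished)
    stop("treatment and baseline runs have different period structures")
  yrs <- period_years(baseline, period)
  if (!length(yrs)) return(numeric(0))
  tr <- guild_series(treatment, guilds, day = day)[yrs]
  ba <- guild_series(baseline, guilds, day = day)[yrs]
  pc <- ifelse(ba == 0, NA_real_, 100 * (tr - ba) / ba)
  if (anyNA(pc)) warning("baseline biomass is zero in ", sum(is.na(pc)),
                         " year(s); percent change undefined there")
  if (per_year) return(pc)
  w <- min(window, length(pc))
  mean(pc[seq(length(pc) - w + 1, length(pc))])
}

#' Total ecosystem biomass series
#'
#' @param result a [run_scenario()] result.
#' @param day in-season record day; the mid-season day is informative
#'   because plankton biomasses cycle within the season.
#' @return Numeric vector of summed biomass over all guilds per year.
#' @export
total_biomass_series <- function(result, day = max(result$record_days)) {
  guild_series(result, dimnames(result$biomass)[[3]], day = day)
}

#' Sliding-window coefficient of variation of an annual series
#'
#' The fluctuation statistic: for each window of `window` consecutive
#' annual values, the population coefficient of variation
#' `sd_pop / mean` with `sd_pop = sqrt(mean((x - mean(x))^2))`.
#' Scale-invariant: multiplying the series by a constant leaves it
#' unchanged.
#'
#' @param series numeric vector of annual values (e.g.
#'   [total_biomass_series()]).
#' @param window window length in years (>= 2).
#' @return data.frame with `window_start` and `cv`; windows with a
#'   nonpositive mean get `NA` with a warning.
#' @export
stability_cv <- function(series, window = 10) {
  stopifnot(window >= 2, length(series) >= window)
  starts <- seq_len(length(series) - window + 1)
  cv <- vapply(starts, function(s) {
    x <- series[s:(s + window - 1)]
    m <- mean(x)
    if (!is.finite(m) || m <= 0) return(NA_real_)
    sqrt(mean((x - m)^2)) / m
  }, numeric(1))
  if (anyNA(cv)) warning("nonpositive window mean; CV undefined there")
  data.frame(window_start = starts, cv = cv)
}

#' Percent change in annual per-stage catches
#'
#' Applies the percent-change machinery to the catch ledgers of the
#' fished period: `100 * (treatment - baseline) / baseline` per year
#' and stage, averaged over the final `window` fished years.
#'
#' @inheritParams percent_change
#' @return Named vector of percent changes, one per fish-stage guild;
#'   empty when the runs have no fished years. Stages with zero
#'   baseline catch throughout (e.g. unselected larvae) are `NA`.
#' @export
catch_comparison <- function(treatment, baseline, window = 10) {
  if (treatment$years_fished != baseline$years_fished)
    stop("treatment and baseline runs have different fished periods")
  yrs <- period_years(baseline, "fished")
  if (!length(yrs)) return(setNames(numeric(0), character(0)))
  stages <- colnames(baseline$catch)
  out <- vapply(stages, function(st) {
    tr <- treatment$catch[yrs, st]
    ba <- baseline$catch[yrs, st]
    pc <- ifelse(ba == 0, NA_real_, 100 * (tr - ba) / ba)
    w <- min(window, length(pc))
    mean(pc[seq(length(pc) - w + 1, length(pc))])
  }, numeric(1))
  out
}
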