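#' Define a fish species as five life-history stages
#'
#' Each species occupies five guilds: larva, juvenile (1-year-old),
#' 2-year-old, 3-year-old and 4-year-old-and-older (an accumulator
#' stage). At the end of every growth season the cohorts move one stage
#' up and a fraction `rho` of the mature stages' season-integrated net
#' productivity becomes next season's larvae.
#'
#' @param name species name.
#' @param stage_ids character vector of exactly five guild ids, ordered
#'   larva, juvenile, 2-y, 3-y, 4-y+.
#' @param mature logical per stage: which stages' net productivity
#'   contributes to recruitment. Default: 2-year-olds and older.
#' @param rho fraction of mature net productivity converted to larval
#'   biomass (0 <= rho <= 1).
#' @param natural_reproduction if `FALSE` the species produces no
#'   larvae of its own (a population maintained purely by stocking)
#'   regardless of `rho`.
#' @return An object of class `fish_species`.
#' @export
fish_species <- function(name, stage_ids,
                         mature = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                         rho = 0.1, natural_reproduction = TRUE) {
  stopifnot(length(stage_ids) == 5L, length(mature) == 5L,
            is.logical(mature), rho >= 0, rho <= 1)
  structure(list(name = name, stage_ids = as.character(stage_ids),
                 mature = mature, rho = rho,
                 natural_reproduction = isTRUE(natural_reproduction)),
            class = "fish_species")
}

STAGE_LABELS <- c("larva", "juvenile", "2y", "3y", "4y_plus")

#' End-of-season stage transition and recruitment
#'
#' Relabels the fish cohorts at the close of a growth season: larvae
#' become juveniles, juveniles become 2-year-olds, and so on; the
#' 4-y+ stage accumulates the incoming 3-year-olds. New larvae are
#' `rho` times the summed (floored) net-production ledger of the mature
#' stages, or zero for species without natural reproduction. All
#' non-fish guilds carry over unchanged.
#'
#' @param B_end named biomass vector at the end of the season.
#' @param production named per-fish-stage net-production ledger read-out
#'   (ugC m^-3); negative entries are floored to zero before use.
#' @param web a [foodweb()] object.
#' @return Named biomass vector at the start of the next season
#'   (before stocking).
#' @export
end_of_season_transition <- function(B_end, production, web) {
  B <- as_state(B_end, web)
  if (any(B < 0))
    stop("negative biomass at season end for: ",
         paste(names(B)[B < 0], collapse = ", "))
  out <- B
  for (sp in web$fish_species) {
    ids <- sp$stage_ids
    if (!all(ids %in% names(production)))
      stop("production ledger is missing stages of species '", sp$name, "'")
    P <- pmax(production[ids], 0)
    recruit <- if (sp$natural_reproduction) sp$rho * sum(P[sp$mature]) else 0
    old <- B[ids]
    out[ids] <- c(recruit, old[1], old[2], old[3], old[4] + old[5])
  }
  out
}

#' Inject stocked larvae at the start of a growth season
#'
#' Adds the planned larval density of each species to that species'
#' larval guild; the injection is additive and all other guilds are
#' untouched. Stocking happens at day 0 of the season, the same moment
#' naturally produced larvae enter the web.
#'
#' @param B_start named biomass vector at season start.
#' @param plan named list or vector, species name -> larval density to
#'   add (ugC m^-3, >= 0). A species entry may also be a per-year
#'   vector, in which case `year` selects the element.
#' @param web a [foodweb()] object.
#' @param year simulation year used to index per-year schedules.
#' @return Updated named biomass vector.
#' @export
apply_stocking <- function(B_start, plan, web, year = 1L) {
  B <- as_state(B_start, web)
  if (length(plan) == 0) return(B)
  species_names <- vapply(web$fish_species, `[[`, "", "name")
  for (nm in names(plan)) {
    k <- match(nm, species_names)
    if (is.na(k))
      stop("stocking plan refers to unknown species: ", nm)
    dens <- plan[[nm]]
    dens <- if (length(dens) > 1) dens[[min(year, length(dens))]] else dens[[1]]
    if (!is.finite(dens) || dens < 0)
      stop("stocking density must be a nonnegative number for species: ", nm)
    larva <- web$fish_species[[k]]$stage_ids[1]
    B[larva] <- B[larva] + dens
  }
  B
}
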