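#' Age-selective fishing policy
#'
#' Fishing operates as a continuous instantaneous mortality through
#' every day of a fishing-year season. The realized per-day rate on a
#' stage is `F_max * S[stage]`. The default maximum rate is
#' 0.5/(90 + 1) per day and the default selectivities are 0 for larvae
#' and juveniles, 1/3 for 2-year-olds, 2/3 for 3-year-olds and 1 for
#' 4-year-old and older fish; both species are fished with the same
#' policy.
#'
#' @param F_max maximum instantaneous fishing mortality, day^-1.
#' @param S selectivity per stage (larva, juvenile, 2-y, 3-y, 4-y+),
#'   each in \[0, 1\].
#' @return An object of class `harvest_policy`.
#' @export
harvest_policy <- function(F_max = 0.5 / (90 + 1),
                           S = c(0, 0, 1 / 3, 2 / 3, 1)) {
  stopifnot(F_max >= 0, length(S) == 5L, all(S >= 0), all(S <= 1))
  structure(list(F_max = F_max, S = as.numeric(S)), class = "harvest_policy")
}

#' Instantaneous fishing mortality of one stage
#'
#' @param stage_index stage position 1..5 (larva .. 4-y+).
#' @param policy a [harvest_policy()].
#' @param active logical; `FALSE` outside fishing years gives 0.
#' @return Per-day mortality rate `F_max * S[stage_index]`.
#' @export
fishing_mortality_rate <- function(stage_index, policy, active = TRUE) {
  stopifnot(stage_index %in% 1:5)
  if (!active) return(0)
  policy$F_max * policy$S[stage_index]
}

#' Per-guild fishing mortality rates for a web
#'
#' Expands a harvest policy over all guilds of a web: fish stages get
#' `F_max * S[stage]`, everything else 0.
#'
#' @param web a [foodweb()] object.
#' @param policy a [harvest_policy()].
#' @return Named vector over the fish-stage guilds only (day^-1).
#' @export
harvest_rates <- function(web, policy) {
  rates <- numeric(0)
  for (sp in web$fish_species) {
    rates <- c(rates, setNames(policy$F_max * policy$S, sp$stage_ids))
  }
  rates
}
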