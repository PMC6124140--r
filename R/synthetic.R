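#' Allometric bioenergetic rates from body mass
#'
#' Metabolic rates follow quarter-power scaling,
#' `x = a_x (M / M_ref)^-0.25` (capped at `x_max`), and the maximum
#' consumption multiple `y` is a role-dependent constant (invertebrates
#' feed faster relative to metabolism than fish). Directly measured
#' rates, when supplied, override the allometry.
#'
#' @param body_mass body mass in ugC per individual (> 0).
#' @param role `"invertebrate"` (zooplankton, bacteria) or `"fish"`.
#' @param constants list of allometric constants: `a_x` (metabolic
#'   normalization at `M_ref`, day^-1), `M_ref` (reference mass, ugC),
#'   `expo` (scaling exponent), `x_max` (cap on x, day^-1), `y_invert`,
#'   `y_fish`.
#' @param x_override,y_override directly measured rates; returned
#'   unchanged when not `NA`.
#' @return List with elements `x` (day^-1) and `y` (dimensionless).
#' @export
allometric_rates <- function(body_mass, role = c("invertebrate", "fish"),
                             constants = list(), x_override = NA,
                             y_override = NA) {
  role <- match.arg(role)
  cst <- utils::modifyList(
    list(a_x = 0.3, M_ref = 1, expo = -0.25, x_max = 2,
         y_invert = 8, y_fish = 4), constants)
  if (any(body_mass <= 0)) stop("body mass must be positive")
  x <- pmin(cst$a_x * (body_mass / cst$M_ref)^cst$expo, cst$x_max)
  y <- if (role == "fish") cst$y_fish else cst$y_invert
  list(x = ifelse(is.na(x_override), x, x_override),
       y = ifelse(is.na(y_override), y, y_override))
}

#' Small deterministic webs for exact testing
#'
#' * `"logistic"`: one producer, no links — pure logistic growth.
#' * `"chain"`: producer and one consumer.
#' * `"competition"`: two consumers sharing one producer.
#' * `"fishery"`: producer, one zooplankton guild and one fish species
#'   in five stages, all feeding on the zooplankton — the minimal web
#'   with stage structure, recruitment and harvest.
#'
#' @param type toy web name.
#' @param K producer carrying capacity (ugC m^-3).
#' @param r producer growth rate (day^-1).
#' @return A validated [foodweb()].
#' @export
make_toy_web <- function(type = c("logistic", "chain", "competition", "fishery"),
                         K = 1000, r = 1) {
  type <- match.arg(type)
  prod <- data.frame(id = "producer", name = "producer", role = "producer",
                     body_mass = 0.001, r = r, x = NA, y = NA, B0 = NA,
                     q = NA, d = NA)
  web <- switch(type,
    logistic = foodweb(prod, data.frame(consumer_id = character(),
                                        prey_id = character(),
                                        omega = numeric(), e = numeric()), K),
    chain = {
      g <- rbind(prod,
                 data.frame(id = "grazer", name = "grazer", role = "consumer",
                            body_mass = 1, r = NA, x = 0.2, y = 4, B0 = 200,
                            q = 1, d = 0))
      l <- data.frame(consumer_id = "grazer", prey_id = "producer",
                      omega = 1, e = 0.45)
      foodweb(g, l, K)
    },
    competition = {
      g <- rbind(prod,
                 data.frame(id = c("grazer_a", "grazer_b"),
                            name = c("grazer a", "grazer b"),
                            role = "consumer", body_mass = 1, r = NA,
                            x = 0.2, y = 4, B0 = 200, q = 1, d = 0.001))
      l <- data.frame(consumer_id = c("grazer_a", "grazer_b"),
                      prey_id = "producer", omega = 1, e = 0.45)
      foodweb(g, l, K)
    },
    fishery = {
      stages <- paste0("fish_", STAGE_LABELS)
      masses <- c(1e3, 1e5, 1e6, 2e6, 4e6)
      xr <- allometric_rates(masses, "fish")
      g <- rbind(prod,
                 data.frame(id = "zoo", name = "zooplankton",
                            role = "consumer", body_mass = 1, r = NA,
                            x = 0.3, y = 8, B0 = 200, q = 1, d = 0.001),
                 data.frame(id = stages, name = stages, role = "fish_stage",
                            body_mass = masses, r = NA, x = xr$x, y = xr$y,
                            B0 = 300, q = 1, d = 0.001))
      l <- rbind(data.frame(consumer_id = "zoo", prey_id = "producer",
                            omega = 1, e = 0.45),
                 data.frame(consumer_id = stages, prey_id = "zoo",
                            omega = 1, e = 0.85))
      foodweb(g, l, K,
              fish_species = list(
                fish_species("fish", stages, rho = 0.2,
                             natural_reproduction = TRUE)))
    })
  validate_web(web)
  web
}

#' Recipe for the lake-like synthetic food web
#'
#' Collects the structural targets and parameter defaults of
#' [make_lc_like_web()]: guild counts per role, the target feeding-link
#' count, allometric and functional-response constants, fish
#' recruitment parameters and the RNG seed. The seed fully determines
#' the generated web.
#'
#' @param seed integer RNG seed.
#' @param n_producers,n_bacteria,n_zoo guild counts per role
#'   (defaults 6 + 2 + 12; with the 10 fish stages, 30 guilds).
#' @param n_links target total feeding-link count (default 133).
#' @param K shared producer carrying capacity, ugC m^-3.
#' @param a_r producer growth normalization at `M_ref_producer`
#'   (day^-1); producer `r` scales as mass^-0.25.
#' @param M_ref_producer reference producer mass, ugC.
#' @param a_x,M_ref,x_max,y_invert,y_fish allometric constants, see
#'   [allometric_rates()].
#' @param a_x_fish metabolic normalization of fish stages (day^-1 at
#'   `M_ref`); fish mass-specific metabolism runs hotter than the
#'   invertebrate normalization would suggest at their large masses.
#' @param b0 half-saturation density of plankton consumers, ugC m^-3.
#' @param b0_fish half-saturation density of fish stages, ugC m^-3.
#' @param b0_pred half-saturation density of predatory zooplankton
#'   (guilds above `predatory_mass`), ugC m^-3.
#' @param b0_larva half-saturation density of fish larvae, ugC m^-3;
#'   larvae foraging on microzooplankton remain food-limited at
#'   densities where older stages already feed near satiation.
#' @param b0_pisc half-saturation density of the piscivorous perch
#'   stages (2-y and older), ugC m^-3; effective hunters saturate on
#'   fish prey at low densities.
#' @param q functional-response shape exponent of plankton consumers (>= 1).
#' @param q_fish shape exponent of fish stages.
#' @param d predator-interference coefficient of plankton consumers,
#'   per ugC m^-3.
#' @param d_fish interference coefficient of fish stages; identical for
#'   whitefish and perch larvae by construction.
#' @param d_perch_old interference coefficient of the oldest perch
#'   stage (a stronger self-limiting competitor).
#' @param e_plant,e_animal assimilation efficiencies for
#'   producer/bacteria prey and animal prey.
#' @param larva_x directly specified mass-specific metabolic rate of
#'   fish larvae (day^-1), overriding the adult-fitted allometry, which
#'   understates larval metabolism and feeding; `NA` keeps the
#'   allometric value.
#' @param larva_rotifer_share total diet-preference weight fish larvae
#'   place on the three rotifer guilds; the remainder is split between
#'   Daphnia and Cyclopoid.
#' @param pisc_whi_share fraction of the piscivorous stages' fish-prey
#'   preference placed on whitefish larvae and juveniles; the rest
#'   falls on conspecific young (perch are strongly cannibalistic).
#' @param pisc_fish_share total diet-preference weight that the mixed
#'   piscivorous perch stages (2-y and 3-y) place on fish prey; the
#'   remainder goes to their zooplankton prey. The oldest perch stage
#'   is exclusively piscivorous.
#' @param rho_perch fraction of mature perch net productivity converted
#'   to larvae.
#' @param predatory_mass predatory-zooplankton mass threshold (ugC);
#'   heavier zooplankton eat only animal prey.
#' @param min_prey minimum prey links retained per plankton consumer
#'   during link pruning.
#' @param larva_individual_mass implied individual mass of a stocked
#'   larva, ugC (stored as metadata only; 200 ugC m^-3 of stocked
#'   larvae is then about one larva per 5 m^3).
#' @return List of class `web_recipe`.
#' @export
web_recipe <- function(seed = 1, n_producers = 6, n_bacteria = 2, n_zoo = 12,
                       n_links = 133, K = 1e5, a_r = 1, M_ref_producer = 1e-3,
                       a_x = 0.1, a_x_fish = a_x, M_ref = 1, x_max = 2,
                       y_invert = 6, y_fish = 6,
                       b0 = 300, b0_fish = 100, b0_pred = 50,
                       b0_larva = b0_fish, b0_pisc = b0_fish,
                       q = 2, q_fish = q, d = 0.1, d_fish = d,
                       d_perch_old = 0.2, e_plant = 0.45, e_animal = 0.85,
                       larva_x = 0.07, larva_rotifer_share = 0.9,
                       pisc_fish_share = 0.15, pisc_whi_share = 0.05,
                       rho_perch = 0.15, predatory_mass = 10, min_prey = 2,
                       larva_individual_mass = 1000) {
  stopifnot(n_producers >= 1, n_bacteria >= 0, n_zoo >= 12, n_links > 0)
  structure(as.list(environment()), class = "web_recipe")
}

lc_zoo_table <- function() {
  data.frame(
    id = c("ciliate_small", "ciliate_large", "rotifer_small",
           "rotifer_medium", "rotifer_large", "nauplii", "bosmina",
           "daphnia", "cyclopoid", "calanoid", "leptodora", "bythotrephes"),
    name = c("small ciliates", "large ciliates", "small rotifers",
             "medium-sized rotifers", "large rotifers", "copepod nauplii",
             "Bosmina", "Daphnia", "Cyclopoid copepods", "Calanoid copepods",
             "Leptodora", "Bythotrephes"),
    body_mass = c(1e-4, 1e-3, 2e-3, 5e-3, 1e-2, 5e-2, 0.3,
                  1, 1.5, 2, 50, 80))
}

lc_producer_table <- function(n) {
  base <- data.frame(
    id = c("pico_algae", "nano_algae", "small_algae", "medium_algae",
           "diatom", "large_algae"),
    name = c("picophytoplankton", "nanophytoplankton", "small algae",
             "medium algae", "diatoms", "large algae"),
    body_mass = c(1e-5, 1e-4, 1e-3, 1e-2, 3e-2, 1e-1))
  if (n <= 6) return(base[seq_len(n), ])
  extra <- data.frame(id = paste0("producer_", seq_len(n - 6)),
                      name = paste("producer", seq_len(n - 6)),
                      body_mass = 10^seq(-4.5, -1.5, length.out = n - 6))
  rbind(base, extra)
}

#' Generate a lake-like synthetic food web
#'
#' Builds a 30-guild, 133-link web emulating the structure of a
#' well-studied alpine-lake plankton-fish community: basal producers
#' and bacteria, a zooplankton assemblage including the named guilds
#' Daphnia, Cyclopoid, Leptodora and three rotifer size classes, and
#' two fish species (planktivorous whitefish, which has no natural
#' reproduction and is maintained by stocking, and perch, whose 2-year
#' and older stages are piscivorous) in five life-history stages each.
#'
#' Plankton feeding links are drawn by a body-mass-ordered feasibility
#' rule (consumers eat strictly smaller guilds; predatory zooplankton
#' eat only animals) and pruned at random, under the recipe's seed, to
#' hit the target link count while every consumer keeps at least
#' `min_prey` links and every guild stays connected. Fish diets are
#' fixed by functional role: all whitefish stages are planktivorous;
#' larvae of both species share the same five larval prey guilds with
#' identical diet preferences and interference coefficients; 2-y+
#' perch eat larval and juvenile fish of both species (the oldest
#' stage exclusively so).
#'
#' @param recipe a [web_recipe()].
#' @return A validated [foodweb()]; the recipe is attached as
#'   attribute `"recipe"`.
#' @export
make_lc_like_web <- function(recipe = web_recipe()) {
  stopifnot(inherits(recipe, "web_recipe"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(recipe$seed)

  prod <- lc_producer_table(recipe$n_producers)
  prod$role <- "producer"
  prod$r <- recipe$a_r * (prod$body_mass / recipe$M_ref_producer)^-0.25

  bact <- if (recipe$n_bacteria > 0) {
    data.frame(id = paste0("bacteria_", seq_len(recipe$n_bacteria)),
               name = paste("bacteria group", seq_len(recipe$n_bacteria)),
               body_mass = 10^seq(-6, -5, length.out = recipe$n_bacteria),
               role = "consumer")
  } else NULL

  zoo <- lc_zoo_table()
  if (recipe$n_zoo > 12) {
    extra <- data.frame(id = paste0("zoo_", seq_len(recipe$n_zoo - 12)),
                        name = paste("zooplankton", seq_len(recipe$n_zoo - 12)),
                        body_mass = 10^seq(-3.5, 0.5,
                                           length.out = recipe$n_zoo - 12))
    zoo <- rbind(zoo, extra)
  }
  zoo$role <- "consumer"

  stage_mass <- list(whitefish = c(1e3, 1e5, 1e6, 2e6, 4e6),
                     perch = c(1e3, 8e4, 8e5, 1.6e6, 3.2e6))
  fish <- do.call(rbind, lapply(names(stage_mass), function(sp) {
    pre <- substr(sp, 1, 3)
    data.frame(id = paste0(pre, "_", STAGE_LABELS),
               name = paste(sp, gsub("_", " ", STAGE_LABELS)),
               body_mass = stage_mass[[sp]], role = "fish_stage")
  }))

  cons <- rbind(bact, zoo)
  cr <- allometric_rates(cons$body_mass, "invertebrate",
                         constants = recipe[c("a_x", "M_ref", "x_max",
                                              "y_invert", "y_fish")])
  cons$x <- cr$x; cons$y <- cr$y
  fcst <- recipe[c("M_ref", "x_max", "y_invert", "y_fish")]
  fcst$a_x <- recipe$a_x_fish
  fr <- allometric_rates(fish$body_mass, "fish", constants = fcst)
  fish$x <- fr$x; fish$y <- fr$y
  if (!is.na(recipe$larva_x))
    fish$x[grepl("_larva$", fish$id)] <- recipe$larva_x
  cons$B0 <- recipe$b0; cons$q <- recipe$q; cons$d <- recipe$d
  cons$B0[cons$id %in% zoo$id & cons$body_mass >= recipe$predatory_mass] <- recipe$b0_pred
  fish$B0 <- recipe$b0_fish; fish$q <- recipe$q_fish; fish$d <- recipe$d_fish
  fish$B0[fish$id %in% c("per_2y", "per_3y", "per_4y_plus")] <- recipe$b0_pisc
  fish$B0[grepl("_larva$", fish$id)] <- recipe$b0_larva
  fish$d[fish$id == "per_4y_plus"] <- recipe$d_perch_old
  prod$x <- prod$y <- prod$B0 <- prod$q <- prod$d <- NA
  cons$r <- fish$r <- NA

  cols <- c("id", "name", "role", "body_mass", "r", "x", "y", "B0", "q", "d")
  guilds <- rbind(prod[cols], cons[cols], fish[cols])

  ## --- fixed links: bacteria and fish diets --------------------------------
  links <- list()
  if (!is.null(bact)) {
    small_prod <- prod$id[order(prod$body_mass)][seq_len(min(2, nrow(prod)))]
    for (b in bact$id)
      links[[length(links) + 1]] <- data.frame(consumer_id = b,
                                               prey_id = small_prod)
  }
  larval_prey <- c("rotifer_small", "rotifer_medium", "rotifer_large",
                   "daphnia", "cyclopoid")
  adult_zoo_prey <- c("daphnia", "cyclopoid", "leptodora")
  juv_perch_prey <- c(adult_zoo_prey, "bosmina", "calanoid")
  fish_prey <- c("whi_larva", "whi_juvenile", "per_larva", "per_juvenile")
  fish_diets <- list(
    whi_larva = larval_prey, per_larva = larval_prey,
    whi_juvenile = adult_zoo_prey, whi_2y = adult_zoo_prey,
    whi_3y = adult_zoo_prey, whi_4y_plus = adult_zoo_prey,
    per_juvenile = juv_perch_prey,
    per_2y = c(fish_prey, adult_zoo_prey),
    per_3y = c(fish_prey, adult_zoo_prey),
    per_4y_plus = fish_prey)
  for (f in names(fish_diets))
    links[[length(links) + 1]] <- data.frame(consumer_id = f,
                                             prey_id = fish_diets[[f]])
  fixed <- do.call(rbind, links)

  ## --- plankton links by mass-ordered feasibility --------------------------
  plank <- rbind(if (!is.null(bact)) bact[c("id", "body_mass")],
                 zoo[c("id", "body_mass")],
                 prod[c("id", "body_mass")])
  cand <- list()
  for (i in seq_len(nrow(zoo))) {
    z <- zoo$id[i]; m <- zoo$body_mass[i]
    pool <- plank[plank$body_mass < m & plank$id != z, ]
    if (m >= recipe$predatory_mass)
      pool <- pool[pool$id %in% zoo$id, ]
    if (nrow(pool))
      cand[[z]] <- data.frame(consumer_id = z, prey_id = pool$id)
  }
  cand <- do.call(rbind, cand)
  target_plank <- recipe$n_links - nrow(fixed)
  if (is.null(cand) || nrow(cand) < target_plank)
    stop(sprintf(
      "infeasible recipe: %d plankton links needed but only %d feasible",
      target_plank, if (is.null(cand)) 0L else nrow(cand)))

  drop_n <- nrow(cand) - target_plank
  for (k in seq_len(drop_n)) {
    deg_cons <- table(cand$consumer_id)
    conn <- table(c(cand$consumer_id, cand$prey_id,
                    fixed$consumer_id, fixed$prey_id))
    removable <- which(deg_cons[cand$consumer_id] > recipe$min_prey &
                       conn[cand$prey_id] > 1)
    if (!length(removable))
      stop("infeasible recipe: cannot prune to the target link count")
    cand <- cand[-removable[sample.int(length(removable), 1)], ]
  }

  all_links <- rbind(fixed, cand)
  ## diet preferences: random weights for plankton, equal for fish
  all_links$omega <- NA_real_
  for (cid in unique(all_links$consumer_id)) {
    rows <- which(all_links$consumer_id == cid)
    if (cid == "per_4y_plus") {
      iswhi <- grepl("^whi", all_links$prey_id[rows])
      all_links$omega[rows] <- ifelse(iswhi,
        recipe$pisc_whi_share / sum(iswhi),
        (1 - recipe$pisc_whi_share) / sum(!iswhi))
    } else if (cid %in% c("whi_larva", "per_larva")) {
      isrot <- grepl("^rotifer", all_links$prey_id[rows])
      all_links$omega[rows] <- ifelse(isrot,
        recipe$larva_rotifer_share / sum(isrot),
        (1 - recipe$larva_rotifer_share) / sum(!isrot))
    } else if (cid %in% c("per_2y", "per_3y")) {
      prey <- all_links$prey_id[rows]
      isfish <- prey %in% fish_prey
      iswhi <- isfish & grepl("^whi", prey)
      isper <- isfish & !iswhi
      w <- numeric(length(prey))
      w[iswhi] <- recipe$pisc_fish_share * recipe$pisc_whi_share / sum(iswhi)
      w[isper] <- recipe$pisc_fish_share * (1 - recipe$pisc_whi_share) / sum(isper)
      w[!isfish] <- (1 - recipe$pisc_fish_share) / sum(!isfish)
      all_links$omega[rows] <- w
    } else if (cid %in% names(fish_diets)) {
      all_links$omega[rows] <- 1 / length(rows)
    } else {
      w <- stats::rgamma(length(rows), shape = 2, rate = 1)
      all_links$omega[rows] <- w / sum(w)
    }
  }
  plant_ids <- c(prod$id, if (!is.null(bact)) bact$id)
  all_links$e <- ifelse(all_links$prey_id %in% plant_ids,
                        recipe$e_plant, recipe$e_animal)

  species <- list(
    fish_species("whitefish", paste0("whi_", STAGE_LABELS),
                 rho = recipe$rho_perch, natural_reproduction = FALSE),
    fish_species("perch", paste0("per_", STAGE_LABELS),
                 rho = recipe$rho_perch, natural_reproduction = TRUE))

  web <- foodweb(guilds, all_links, K = recipe$K, fish_species = species)
  validate_web(web)
  attr(web, "recipe") <- recipe
  web
}
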