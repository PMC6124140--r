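#' Write a food web to a single JSON document
#'
#' Serializes guilds, links, the carrying capacity and the fish-species
#' scaffolds with full numeric precision, so that a written web reads
#' back field-for-field identical and identical webs produce
#' byte-identical files.
#'
#' @param web a [foodweb()] object.
#' @param path output file path (conventionally `web.json`).
#' @return `path`, invisibly.
#' @export
write_web_json <- function(web, path) {
  doc <- list(
    K = web$K,
    guilds = web$guilds,
    links = web$links,
    fish_species = lapply(web$fish_species, function(sp)
      list(name = sp$name, stage_ids = sp$stage_ids, mature = sp$mature,
           rho = sp$rho, natural_reproduction = sp$natural_reproduction)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a food web from its JSON document
#'
#' @param path path to a file written by [write_web_json()].
#' @return A validated [foodweb()].
#' @export
read_web_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  fs <- doc$fish_species
  if (is.data.frame(fs)) fs <- lapply(seq_len(nrow(fs)), function(i) {
    list(name = fs$name[i], stage_ids = fs$stage_ids[[i]],
         mature = fs$mature[[i]], rho = fs$rho[i],
         natural_reproduction = fs$natural_reproduction[i])
  })
  species <- lapply(fs, function(sp)
    fish_species(sp$name, sp$stage_ids, mature = as.logical(sp$mature),
                 rho = sp$rho,
                 natural_reproduction = sp$natural_reproduction))
  guilds <- doc$guilds
  for (col in c("body_mass", "r", "x", "y", "B0", "q", "d"))
    guilds[[col]] <- as.numeric(guilds[[col]])
  web <- foodweb(guilds, doc$links, K = doc$K, fish_species = species)
  validate_web(web)
  web
}

#' Write the guild and link tables as CSV
#'
#' Writes `guilds.csv` (id, name, role, body_mass, r, x, y, B0, q, d;
#' empty cells mean role-inapplicable or derive-allometrically) and
#' `links.csv` (consumer_id, prey_id, omega, e) into a directory. The
#' carrying capacity and fish-species scaffolds live in the JSON
#' format ([write_web_json()]), not in the CSVs.
#'
#' @param web a [foodweb()] object.
#' @param dir output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_web_csv <- function(web, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, "guilds.csv")
  lp <- file.path(dir, "links.csv")
  write.csv(web$guilds, gp, row.names = FALSE, na = "")
  write.csv(web$links, lp, row.names = FALSE, na = "")
  invisible(c(gp, lp))
}

#' Read a food web from guild/link CSV tables
#'
#' @param guilds_csv,links_csv paths to the two tables.
#' @param K shared producer carrying capacity (not stored in the CSVs).
#' @param fish_species list of [fish_species()] scaffolds.
#' @return A validated [foodweb()].
#' @export
read_web_csv <- function(guilds_csv, links_csv, K, fish_species = list()) {
  g <- read.csv(guilds_csv, stringsAsFactors = FALSE)
  l <- read.csv(links_csv, stringsAsFactors = FALSE)
  web <- foodweb(g, l, K = K, fish_species = fish_species)
  validate_web(web)
  web
}

#' Tidy long-format exports of a scenario result
#'
#' `result_biomass_df()` returns one row per (year, day, guild);
#' `result_catch_df()` one row per (year, species, stage).
#'
#' @param result a [run_scenario()] result.
#' @param web the [foodweb()] the scenario ran on (for species labels).
#' @return A data.frame.
#' @export
result_biomass_df <- function(result) {
  dn <- dimnames(result$biomass)
  nyears <- dim(result$biomass)[1]
  grid <- expand.grid(year = seq_len(nyears),
                      day = as.numeric(dn[[2]]),
                      guild = dn[[3]], stringsAsFactors = FALSE)
  grid$biomass <- as.vector(result$biomass)
  grid
}

#' @rdname result_biomass_df
#' @export
result_catch_df <- function(result, web) {
  stage_of <- character(); species_of <- character()
  for (sp in web$fish_species) {
    stage_of[sp$stage_ids] <- STAGE_LABELS
    species_of[sp$stage_ids] <- sp$name
  }
  ids <- colnames(result$catch)
  nyears <- nrow(result$catch)
  data.frame(year = rep(seq_len(nyears), times = length(ids)),
             species = rep(species_of[ids], each = nyears),
             stage = rep(stage_of[ids], each = nyears),
             catch = as.vector(result$catch))
}

#' Write the tidy CSV outputs of a scenario run
#'
#' @param result a [run_scenario()] result.
#' @param web the [foodweb()] used.
#' @param dir output directory (created if missing).
#' @return Paths written, invisibly.
#' @export
write_result_csv <- function(result, web, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bp <- file.path(dir, "biomass.csv")
  cp <- file.path(dir, "catches.csv")
  write.csv(result_biomass_df(result), bp, row.names = FALSE)
  write.csv(result_catch_df(result, web), cp, row.names = FALSE)
  invisible(c(bp, cp))
}
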