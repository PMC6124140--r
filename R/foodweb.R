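#' @useDynLib atnstock, .registration = TRUE
#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv
NULL

GUILD_ROLES <- c("producer", "consumer", "fish_stage")

#' Construct a food web
#'
#' Bundles a guild table, a feeding-link table, the shared producer
#' carrying capacity and the fish life-history scaffolds into a single
#' `foodweb` object, the central container of the package.
#'
#' Biomasses throughout the package are relative carbon densities in
#' ugC m^-3; rates are per day.
#'
#' @param guilds data.frame with columns `id`, `name`, `role`
#'   (`"producer"`, `"consumer"` or `"fish_stage"`), `body_mass`
#'   (ugC per individual), `r` (producer intrinsic growth, day^-1),
#'   `x` (mass-specific metabolic rate, day^-1), `y` (maximum
#'   consumption as a multiple of metabolism), `B0` (half-saturation
#'   density, ugC m^-3), `q` (functional-response shape exponent, at
#'   least 1) and `d` (intraspecific predator-interference coefficient,
#'   per ugC m^-3). Cells that do not apply to a role may be `NA`.
#' @param links data.frame with columns `consumer_id`, `prey_id`,
#'   `omega` (diet preference, rows per consumer must sum to 1) and
#'   `e` (assimilation efficiency in (0, 1]).
#' @param K shared community carrying capacity applied to the summed
#'   biomass of all producers, ugC m^-3.
#' @param fish_species list of [fish_species()] objects mapping
#'   fish-stage guilds to species.
#' @return An object of class `foodweb`.
#' @seealso [validate_web()], [make_lc_like_web()], [make_toy_web()]
#' @export
foodweb <- function(guilds, links, K, fish_species = list()) {
  stopifnot(is.data.frame(guilds), is.data.frame(links))
  need_g <- c("id", "name", "role", "body_mass", "r", "x", "y", "B0", "q", "d")
  for (col in setdiff(need_g, names(guilds))) guilds[[col]] <- NA_real_
  guilds <- guilds[, need_g]
  guilds$id <- as.character(guilds$id)
  guilds$name <- as.character(guilds$name)
  guilds$role <- as.character(guilds$role)
  if (nrow(links) == 0) {
    links <- data.frame(consumer_id = character(), prey_id = character(),
                        omega = numeric(), e = numeric())
  }
  need_l <- c("consumer_id", "prey_id", "omega", "e")
  stopifnot(all(need_l %in% names(links)))
  links <- links[, need_l]
  links$consumer_id <- as.character(links$consumer_id)
  links$prey_id <- as.character(links$prey_id)
  web <- structure(
    list(guilds = guilds, links = links, K = as.numeric(K),
         fish_species = fish_species),
    class = "foodweb")
  web
}

#' @export
print.foodweb <- function(x, ...) {
  cat(sprintf("<foodweb> %d guilds, %d links, K = %g ugC m^-3\n",
              nrow(x$guilds), nrow(x$links), x$K))
  roles <- table(factor(x$guilds$role, levels = GUILD_ROLES))
  cat(sprintf("  producers: %d, consumers: %d, fish stages: %d\n",
              roles[["producer"]], roles[["consumer"]], roles[["fish_stage"]]))
  for (sp in x$fish_species)
    cat(sprintf("  fish species '%s': %s\n", sp$name,
                paste(sp$stage_ids, collapse = ", ")))
  invisible(x)
}

#' Guild ids of a food web
#' @param web a [foodweb()] object.
#' @return Character vector of guild ids in state-vector order.
#' @export
guild_ids <- function(web) web$guilds$id

#' Fish-stage guild ids of a food web
#' @param web a [foodweb()] object.
#' @return Character vector of all fish-stage guild ids, in species then
#'   stage order.
#' @export
fish_stage_ids <- function(web) {
  unlist(lapply(web$fish_species, function(sp) sp$stage_ids), use.names = FALSE)
}

#' Validate the structural invariants of a food web
#'
#' Checks that link endpoints resolve, that producers have no prey,
#' that every consumer's diet preferences sum to one, that every
#' non-producer has at least one prey link, that fish-stage guilds
#' belong to exactly one species, and that rates have admissible signs.
#'
#' @param web a [foodweb()] object.
#' @param strict if `TRUE` (default), any violation raises an error
#'   listing the offending guilds; if `FALSE` violations are only
#'   collected in the returned report.
#' @param tol tolerance for the per-consumer diet-preference sum.
#' @return A `web_validation` report with elements `n_guilds`,
#'   `n_links`, `omega_residuals` and `violations`.
#' @export
validate_web <- function(web, strict = TRUE, tol = 1e-9) {
  stopifnot(inherits(web, "foodweb"))
  g <- web$guilds
  l <- web$links
  if (nrow(g) == 0) stop("invalid food web: no guilds")
  viol <- character()

  if (anyDuplicated(g$id))
    viol <- c(viol, sprintf("duplicated guild ids: %s",
                            paste(unique(g$id[duplicated(g$id)]), collapse = ", ")))
  bad_role <- g$id[!g$role %in% GUILD_ROLES]
  if (length(bad_role))
    viol <- c(viol, sprintf("unknown role for: %s", paste(bad_role, collapse = ", ")))
  bad_mass <- g$id[!is.finite(g$body_mass) | g$body_mass <= 0]
  if (length(bad_mass))
    viol <- c(viol, sprintf("nonpositive body_mass for: %s",
                            paste(bad_mass, collapse = ", ")))

  unresolved <- setdiff(unique(c(l$consumer_id, l$prey_id)), g$id)
  if (length(unresolved))
    viol <- c(viol, sprintf("link endpoints not in guild table: %s",
                            paste(unresolved, collapse = ", ")))
  self <- l$consumer_id[l$consumer_id == l$prey_id]
  if (length(self))
    viol <- c(viol, sprintf("self links: %s", paste(unique(self), collapse = ", ")))

  is_prod <- g$role == "producer"
  prod_with_prey <- intersect(g$id[is_prod], unique(l$consumer_id))
  if (length(prod_with_prey))
    viol <- c(viol, sprintf("producers with outgoing feeding links: %s",
                            paste(prod_with_prey, collapse = ", ")))
  bad_r <- g$id[is_prod & (!is.finite(g$r) | g$r <= 0)]
  if (length(bad_r))
    viol <- c(viol, sprintf("producers need r > 0: %s", paste(bad_r, collapse = ", ")))

  cons <- g$id[!is_prod]
  no_prey <- setdiff(cons, unique(l$consumer_id))
  if (length(no_prey))
    viol <- c(viol, sprintf("consumers with no prey links: %s",
                            paste(no_prey, collapse = ", ")))
  for (col in c("x", "y", "B0")) {
    bad <- g$id[!is_prod & (!is.finite(g[[col]]) | g[[col]] <= 0)]
    if (length(bad))
      viol <- c(viol, sprintf("consumers need %s > 0: %s", col,
                              paste(bad, collapse = ", ")))
  }
  bad_q <- g$id[!is_prod & (!is.finite(g$q) | g$q < 1)]
  if (length(bad_q))
    viol <- c(viol, sprintf("consumers need q >= 1: %s", paste(bad_q, collapse = ", ")))
  bad_d <- g$id[!is_prod & (!is.finite(g$d) | g$d < 0)]
  if (length(bad_d))
    viol <- c(viol, sprintf("consumers need d >= 0: %s", paste(bad_d, collapse = ", ")))

  if (nrow(l)) {
    if (any(!is.finite(l$omega) | l$omega <= 0 | l$omega > 1))
      viol <- c(viol, "diet preferences omega must lie in (0, 1]")
    if (any(!is.finite(l$e) | l$e <= 0 | l$e > 1))
      viol <- c(viol, "assimilation efficiencies e must lie in (0, 1]")
  }
  osum <- tapply(l$omega, l$consumer_id, sum)
  resid <- osum - 1
  bad_omega <- names(osum)[abs(resid) > tol]
  if (length(bad_omega))
    viol <- c(viol, sprintf("diet preferences do not sum to 1 for: %s",
                            paste(sprintf("%s (sum %.6g)", bad_omega,
                                          osum[bad_omega]), collapse = ", ")))

  stage_ids <- fish_stage_ids(web)
  if (anyDuplicated(stage_ids))
    viol <- c(viol, sprintf("fish stages in more than one species: %s",
                            paste(unique(stage_ids[duplicated(stage_ids)]),
                                  collapse = ", ")))
  missing_stage <- setdiff(stage_ids, g$id)
  if (length(missing_stage))
    viol <- c(viol, sprintf("fish stages not in guild table: %s",
                            paste(missing_stage, collapse = ", ")))
  orphan_fish <- setdiff(g$id[g$role == "fish_stage"], stage_ids)
  if (length(orphan_fish))
    viol <- c(viol, sprintf("fish_stage guilds not assigned to a species: %s",
                            paste(orphan_fish, collapse = ", ")))
  for (sp in web$fish_species) {
    if (length(sp$stage_ids) != 5L)
      viol <- c(viol, sprintf("species '%s' must have exactly 5 stages", sp$name))
    if (sp$rho < 0 || sp$rho > 1)
      viol <- c(viol, sprintf("species '%s' needs 0 <= rho <= 1", sp$name))
  }

  if (!is.finite(web$K) || web$K <= 0) viol <- c(viol, "K must be > 0")

  linked <- unique(c(l$consumer_id, l$prey_id))
  orphans <- setdiff(g$id, linked)
  if (nrow(g) > 1 && length(orphans))
    viol <- c(viol, sprintf("orphan guilds with no links: %s",
                            paste(orphans, collapse = ", ")))

  report <- structure(
    list(n_guilds = nrow(g), n_links = nrow(l),
         omega_residuals = resid, violations = viol),
    class = "web_validation")
  if (strict && length(viol))
    stop("invalid food web:\n  ", paste(viol, collapse = "\n  "))
  report
}

#' @export
print.web_validation <- function(x, ...) {
  cat(sprintf("%d guilds, %d links\n", x$n_guilds, x$n_links))
  if (length(x$violations)) {
    cat("violations:\n")
    for (v in x$violations) cat("  -", v, "\n")
  } else {
    cat("no violations\n")
  }
  invisible(x)
}

## ---- compiled parameter packing -------------------------------------------

ATN_MAXPAR <- 25000L

#' Pack a validated web into the flat parameter vector used by the C core
#'
#' @param web a validated [foodweb()] object.
#' @param harvest_rates optional named per-guild vector of instantaneous
#'   fishing mortality rates (day^-1); defaults to all zero.
#' @param floor biomass floor applied by the daily clamp event.
#' @return Numeric vector (unpadded); attribute `n` holds the guild count.
#' @keywords internal
compile_web <- function(web, harvest_rates = NULL, floor = 1e-9) {
  g <- web$guilds
  n <- nrow(g)
  if (n > 100L) stop("webs with more than 100 guilds are not supported")
  ids <- g$id
  is_prod <- as.numeric(g$role == "producer")
  num0 <- function(v) ifelse(is.na(v), 0, v)
  r <- num0(g$r) * is_prod
  x <- num0(g$x) * (1 - is_prod)
  y <- num0(g$y)
  B0 <- ifelse(is.na(g$B0) | g$B0 <= 0, 1, g$B0)
  q <- ifelse(is.na(g$q), 1, g$q)
  d <- num0(g$d)
  h <- rep(0, n)
  if (!is.null(harvest_rates)) {
    idx <- match(names(harvest_rates), ids)
    if (anyNA(idx)) stop("harvest rates refer to unknown guilds: ",
                         paste(names(harvest_rates)[is.na(idx)], collapse = ", "))
    h[idx] <- harvest_rates
  }
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  E <- matrix(1, n, n, dimnames = list(ids, ids))
  if (nrow(web$links)) {
    ci <- match(web$links$consumer_id, ids)
    pi <- match(web$links$prey_id, ids)
    W[cbind(ci, pi)] <- web$links$omega
    E[cbind(ci, pi)] <- web$links$e
  }
  fish_idx <- match(fish_stage_ids(web), ids)
  p <- c(n, web$K, floor, length(fish_idx),
         is_prod, r, x, y, B0, q, d, h, as.numeric(W), as.numeric(E),
         as.numeric(fish_idx))
  if (length(p) > ATN_MAXPAR)
    stop("packed parameter vector exceeds compiled capacity")
  structure(p, n = n, ids = ids, fish_idx = fish_idx)
}

pad_parms <- function(p) {
  out <- numeric(ATN_MAXPAR)
  out[seq_along(p)] <- p
  out
}

## ---- model terms -----------------------------------------------------------

#' Multi-prey functional response of one consumer
#'
#' The realized fraction of maximum consumption of consumer *i* on each
#' of its prey *j*:
#' \deqn{F_{ij} = \frac{\omega_{ij} B_j^{q_i}}{B_{0i}^{q_i}(1 + d_i B_i)
#'   + \sum_k \omega_{ik} B_k^{q_i}}}
#' with diet preference \eqn{\omega}, half-saturation density
#' \eqn{B_0}, shape exponent \eqn{q} and intraspecific predator
#' interference \eqn{d}.
#'
#' @param consumer guild id of the consumer.
#' @param B named biomass vector over all guilds, ugC m^-3.
#' @param web a [foodweb()] object.
#' @return Named vector of \eqn{F_{ij}} over the consumer's prey;
#'   each entry lies in \[0, 1) and the entries sum to < 1.
#' @export
functional_response <- function(consumer, B, web) {
  g <- web$guilds
  i <- match(consumer, g$id)
  if (is.na(i)) stop("unknown guild: ", consumer)
  if (g$role[i] == "producer") stop("producers have no functional response: ", consumer)
  ln <- web$links[web$links$consumer_id == consumer, ]
  if (nrow(ln) == 0) stop("consumer has no prey links: ", consumer)
  B <- as_state(B, web)
  stopifnot(all(is.finite(B)), all(B >= 0))
  qi <- g$q[i]
  Bi <- B[[consumer]]
  wBq <- ln$omega * B[ln$prey_id]^qi
  denom <- g$B0[i]^qi * (1 + g$d[i] * Bi) + sum(wBq)
  setNames(as.numeric(wBq / denom), ln$prey_id)
}

#' Shared logistic growth factor of the producers
#'
#' All producers grow logistically against one community carrying
#' capacity: \eqn{G = 1 - \sum_p B_p / K}.
#'
#' @inheritParams functional_response
#' @return Scalar growth factor in \eqn{(-\infty, 1]}.
#' @export
producer_growth_factor <- function(B, web) {
  B <- as_state(B, web)
  1 - sum(B[web$guilds$role == "producer"]) / web$K
}

as_state <- function(B, web) {
  ids <- web$guilds$id
  if (is.null(names(B))) {
    if (length(B) != length(ids)) stop("state length does not match guild count")
    return(setNames(as.numeric(B), ids))
  }
  if (!all(ids %in% names(B)))
    stop("state is missing guilds: ",
         paste(setdiff(ids, names(B)), collapse = ", "))
  setNames(as.numeric(B[ids]), ids)
}

#' Right-hand side of the within-season biomass dynamics
#'
#' Assembles the daily rate of change of every guild's biomass:
#' producers gain `r * G * B` under the shared logistic factor `G`,
#' consumers gain assimilated consumption `x * y * B * sum(F)` and lose
#' metabolism `x * B`; every prey loses ingested biomass
#' `x_k y_k B_k F_kj / e_kj` to its consumers; fish stages additionally
#' lose `h * B` to fishing when a harvest policy is active.
#'
#' @inheritParams functional_response
#' @param harvest optional [harvest_policy()]; applied only when
#'   `fishing_active` is `TRUE`.
#' @param fishing_active logical; is this a fishing year?
#' @return Named vector `dB/dt` (ugC m^-3 day^-1).
#' @export
atn_rhs <- function(B, web, harvest = NULL, fishing_active = FALSE) {
  B <- as_state(B, web)
  if (any(!is.finite(B)))
    stop("non-finite biomass for: ",
         paste(names(B)[!is.finite(B)], collapse = ", "))
  hr <- NULL
  if (!is.null(harvest) && fishing_active) hr <- harvest_rates(web, harvest)
  p <- compile_web(web, harvest_rates = hr)
  out <- .Call(atn_eval_call, as.numeric(B), as.numeric(p))
  setNames(out$dB, names(B))
}
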