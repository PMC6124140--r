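# Shared fixtures: an independent, loop-based right-hand-side oracle and a
# small random-web generator used by the property-style tests.

# Term-by-term assembly straight from the model definitions, written
# deliberately without reusing any package internals.
oracle_rhs <- function(B, web, harvest = NULL) {
  g <- web$guilds
  l <- web$links
  n <- nrow(g)
  ids <- g$id
  B <- B[ids]
  Fmat <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (g$role[i] == "producer") next
    li <- l[l$consumer_id == ids[i], , drop = FALSE]
    if (nrow(li) == 0) next
    qi <- g$q[i]
    den <- g$B0[i]^qi * (1 + g$d[i] * B[[ids[i]]])
    for (k in seq_len(nrow(li)))
      den <- den + li$omega[k] * B[[li$prey_id[k]]]^qi
    for (k in seq_len(nrow(li)))
      Fmat[ids[i], li$prey_id[k]] <- li$omega[k] * B[[li$prey_id[k]]]^qi / den
  }
  prod_sum <- 0
  for (i in seq_len(n))
    if (g$role[i] == "producer") prod_sum <- prod_sum + B[[ids[i]]]
  G <- 1 - prod_sum / web$K
  dB <- stats::setNames(numeric(n), ids)
  for (i in seq_len(n)) {
    id <- ids[i]
    if (g$role[i] == "producer") {
      dB[id] <- g$r[i] * G * B[[id]]
    } else {
      dB[id] <- g$x[i] * B[[id]] * (-1 + g$y[i] * sum(Fmat[id, ]))
      if (!is.null(harvest) && id %in% names(harvest))
        dB[id] <- dB[id] - harvest[[id]] * B[[id]]
    }
  }
  for (i in seq_len(n)) {
    li <- l[l$consumer_id == ids[i], , drop = FALSE]
    for (k in seq_len(nrow(li))) {
      prey <- li$prey_id[k]
      dB[prey] <- dB[prey] -
        g$x[i] * g$y[i] * B[[ids[i]]] * Fmat[ids[i], prey] / li$e[k]
    }
  }
  dB
}

# Random small web: 1-2 producers, up to 4 consumers, feasible mass-ordered
# links, normalized diet preferences. Deterministic given the seed.
random_small_web <- function(seed) {
  set.seed(seed)
  n_prod <- sample(1:2, 1)
  n_cons <- sample(1:4, 1)
  ids <- c(paste0("p", seq_len(n_prod)), paste0("c", seq_len(n_cons)))
  mass <- sort(stats::runif(n_prod + n_cons, 0.01, 100))
  g <- data.frame(
    id = ids, name = ids,
    role = c(rep("producer", n_prod), rep("consumer", n_cons)),
    body_mass = mass,
    r = c(stats::runif(n_prod, 0.5, 2), rep(NA, n_cons)),
    x = c(rep(NA, n_prod), stats::runif(n_cons, 0.05, 0.5)),
    y = c(rep(NA, n_prod), stats::runif(n_cons, 2, 8)),
    B0 = c(rep(NA, n_prod), stats::runif(n_cons, 50, 500)),
    q = c(rep(NA, n_prod), stats::runif(n_cons, 1, 2)),
    d = c(rep(NA, n_prod), stats::runif(n_cons, 0, 0.2)))
  links <- list()
  for (i in seq_len(n_cons)) {
    cid <- paste0("c", i)
    pool <- ids[seq_len(n_prod + i - 1)]
    prey <- sample(pool, sample(seq_along(pool), 1))
    w <- stats::rgamma(length(prey), 2)
    links[[i]] <- data.frame(consumer_id = cid, prey_id = prey,
                             omega = w / sum(w),
                             e = stats::runif(length(prey), 0.3, 0.9))
  }
  l <- do.call(rbind, links)
  # connect any producer left unpicked so the web validates
  orphans <- setdiff(ids, c(l$consumer_id, l$prey_id))
  last <- paste0("c", n_cons)
  for (o in orphans)
    l <- rbind(l, data.frame(consumer_id = last, prey_id = o,
                             omega = 0.1, e = 0.5))
  for (cid in unique(l$consumer_id)) {
    rows <- l$consumer_id == cid
    l$omega[rows] <- l$omega[rows] / sum(l$omega[rows])
  }
  web <- foodweb(g, l, K = stats::runif(1, 500, 5000))
  validate_web(web)
  web
}

# five inert fish stages (negligible metabolism, empty prey field) over an
# absent producer: the only dynamics left is the harvest term, so catch
# bookkeeping can be checked against conservation exactly
make_inert_fish_web <- function() {
  g <- data.frame(
    id = c("prey", paste0("s", 1:5)),
    name = c("prey", paste0("s", 1:5)),
    role = c("producer", rep("fish_stage", 5)),
    body_mass = c(1, rep(1000, 5)),
    r = c(1, rep(NA, 5)),
    x = c(NA, rep(1e-12, 5)),
    y = c(NA, rep(1, 5)),
    B0 = c(NA, rep(1, 5)),
    q = c(NA, rep(1, 5)),
    d = c(NA, rep(0, 5)))
  l <- data.frame(consumer_id = paste0("s", 1:5), prey_id = "prey",
                  omega = 1, e = 0.85)
  foodweb(g, l, K = 1000,
          fish_species = list(fish_species("inert", paste0("s", 1:5),
                                           rho = 0)))
}

random_state <- function(web, seed) {
  set.seed(seed)
  stats::setNames(stats::runif(nrow(web$guilds), 0, 1000), web$guilds$id)
}
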