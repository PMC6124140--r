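fishery_web <- make_toy_web("fishery")
stages <- fishery_web$fish_species[[1]]$stage_ids

state_with_stages <- function(vals) {
  B <- c(producer = 100, zoo = 50)
  c(B, stats::setNames(vals, stages))
}

test_that("end-of-season transition shifts cohorts and recruits from P", {
  B <- state_with_stages(c(1, 2, 3, 4, 5))
  # rho = 0.2, mature stages 3:5 with P summing to 3.5 -> recruits 0.7
  P <- stats::setNames(c(0, 0, 1, 1, 1.5), stages)
  out <- end_of_season_transition(B, P, fishery_web)
  expect_equal(unname(out[stages]), c(0.7, 1, 2, 3, 9))
  expect_equal(out[["producer"]], 100)
  expect_equal(out[["zoo"]], 50)
})

test_that("no production means no spontaneous recruitment", {
  B <- state_with_stages(rep(0, 5))
  P <- stats::setNames(rep(0, 5), stages)
  out <- end_of_season_transition(B, P, fishery_web)
  expect_equal(unname(out[stages]), rep(0, 5))
})

test_that("species without natural reproduction never recruit", {
  web <- fishery_web
  web$fish_species[[1]]$natural_reproduction <- FALSE
  B <- state_with_stages(c(1, 2, 3, 4, 5))
  P <- stats::setNames(rep(10, 5), stages)
  out <- end_of_season_transition(B, P, web)
  expect_equal(out[[stages[1]]], 0)
})

test_that("aging conserves fish biomass apart from recruitment", {
  for (s in 1:20) {
    set.seed(s)
    vals <- stats::runif(5, 0, 50)
    P <- stats::setNames(stats::runif(5, -2, 5), stages)
    B <- state_with_stages(vals)
    out <- end_of_season_transition(B, P, fishery_web)
    recruits <- out[[stages[1]]]
    expect_equal(sum(out[stages]), sum(vals) - vals[1] + recruits + vals[1])
    expect_gte(recruits, 0)
  }
})

test_that("with zero recruitment repeated transitions drain into 4-y+", {
  web <- fishery_web
  web$fish_species[[1]]$natural_reproduction <- FALSE
  B <- state_with_stages(c(1, 2, 3, 4, 5))
  P <- stats::setNames(rep(0, 5), stages)
  total <- sum(B[stages])
  for (i in 1:6) B <- end_of_season_transition(B, P, web)
  expect_equal(unname(B[stages]), c(0, 0, 0, 0, total))
})

test_that("negative biomass at season end is rejected", {
  B <- state_with_stages(c(-1, 2, 3, 4, 5))
  P <- stats::setNames(rep(0, 5), stages)
  expect_error(end_of_season_transition(B, P, fishery_web), "negative")
})

test_that("stocking is an additive larval injection", {
  B <- state_with_stages(c(10, 0, 0, 0, 0))
  out <- apply_stocking(B, list(fish = 200), fishery_web)
  expect_equal(out[[stages[1]]], 210)
  expect_equal(out[setdiff(names(out), stages[1])],
               B[setdiff(names(B), stages[1])])

  # zero plan is the identity
  expect_equal(apply_stocking(B, list(fish = 0), fishery_web), B)
  expect_equal(apply_stocking(B, list(), fishery_web), B)

  # two applications compose additively
  once <- apply_stocking(B, list(fish = 300), fishery_web)
  twice <- apply_stocking(apply_stocking(B, list(fish = 100), fishery_web),
                          list(fish = 200), fishery_web)
  expect_identical(once, twice)
})

test_that("per-year stocking schedules and unknown species are handled", {
  B <- state_with_stages(c(0, 0, 0, 0, 0))
  plan <- list(fish = c(100, 250))
  expect_equal(apply_stocking(B, plan, fishery_web, year = 1)[[stages[1]]], 100)
  expect_equal(apply_stocking(B, plan, fishery_web, year = 2)[[stages[1]]], 250)
  # years beyond the schedule reuse the last entry
  expect_equal(apply_stocking(B, plan, fishery_web, year = 9)[[stages[1]]], 250)
  expect_error(apply_stocking(B, list(salmon = 10), fishery_web), "salmon")
  expect_error(apply_stocking(B, list(fish = -5), fishery_web), "nonnegative")
})

test_that("net production integrates analytically in a decay-only season", {
  # a lone 4-y+ cohort with no food: dB = -(x + h) B, dP = -x B, dC = h B
  web <- fishery_web
  B <- state_with_stages(c(0, 0, 0, 0, 100))
  B["producer"] <- 0
  B["zoo"] <- 0
  pol <- harvest_policy(F_max = 0.004, S = c(0, 0, 0, 0, 1))
  x5 <- web$guilds$x[web$guilds$id == stages[5]]
  h <- 0.004
  sol <- integrate_season(B, web, policy = pol, fishing_active = TRUE,
                          solver = solver_control(floor = 0))
  decay <- (1 - exp(-(x5 + h) * 90)) / (x5 + h)
  expect_equal(sol$B_end[[stages[5]]], 100 * exp(-(x5 + h) * 90),
               tolerance = 1e-5)
  expect_equal(sol$catch[[stages[5]]], h * 100 * decay, tolerance = 1e-5)
  # raw production integral is negative (pure metabolism), floored at read-out
  expect_equal(sol$production_raw[[stages[5]]], -x5 * 100 * decay,
               tolerance = 1e-5)
  expect_equal(sol$production[[stages[5]]], 0)
})
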