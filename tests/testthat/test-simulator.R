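test_that("producers-only web stays at carrying capacity", {
  web <- make_toy_web("logistic", K = 1000)
  out <- integrate_season(c(producer = 1000), web)
  expect_equal(out$B_end[["producer"]], 1000, tolerance = 1e-6)
})

test_that("producer trajectory matches the closed-form logistic solution", {
  K <- 1000; r <- 1; B0 <- 50
  web <- make_toy_web("logistic", K = K, r = r)
  days <- c(5, 20, 45, 90)
  out <- integrate_season(c(producer = B0), web, record_days = days)
  analytic <- K / (1 + (K / B0 - 1) * exp(-r * days))
  expect_equal(unname(out$record[, "producer"]), analytic, tolerance = 1e-6)
})

test_that("season integration is self-convergent and deterministic", {
  web <- make_toy_web("chain")
  B <- c(producer = 800, grazer = 20)
  default <- integrate_season(B, web)
  tight <- integrate_season(B, web,
                            solver = solver_control(rtol = 1e-10, atol = 1e-12))
  expect_equal(default$B_end, tight$B_end, tolerance = 1e-4)
  again <- integrate_season(B, web)
  expect_identical(default$B_end, again$B_end)
  expect_identical(default$record, again$record)
})

test_that("a zero-year scenario echoes the initial state", {
  web <- make_toy_web("fishery")
  cfg <- scenario_config(web, years_unfished = 0, years_fished = 0)
  res <- run_scenario(cfg)
  expect_equal(dim(res$biomass)[1], 0)
  expect_equal(res$B_final, default_initial_state(web))
})

test_that("an unstocked species without reproduction goes extinct quickly", {
  web <- make_toy_web("fishery")
  web$fish_species[[1]]$natural_reproduction <- FALSE
  cfg <- scenario_config(web, stocking = list(fish = 0), years_unfished = 8,
                         years_fished = 0)
  res <- run_scenario(cfg)
  stages <- web$fish_species[[1]]$stage_ids
  floor <- cfg$solver$floor
  # younger stages drain into the accumulator within 5 transitions
  expect_true(all(res$biomass[6, "90", stages[1:4]] <= floor * 1.001))
})

test_that("scenario results are deterministic and well-shaped", {
  web <- make_toy_web("fishery")
  cfg <- scenario_config(web, stocking = list(fish = 100), years_unfished = 3,
                         years_fished = 2)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$biomass, b$biomass)
  expect_identical(a$catch, b$catch)
  expect_equal(dim(a$biomass), c(5, 2, nrow(web$guilds)))
  expect_true(all(is.finite(a$biomass)))
  # catches appear only in fished years
  expect_true(all(a$catch[1:3, ] == 0))
  expect_gt(sum(a$catch[4:5, ]), 0)
})

test_that("experiment arms differ only in their stated stocking deltas", {
  ex_args <- list(web = make_lc_like_web(), years_unfished = 2,
                  years_fished = 1)
  ex <- do.call(run_experiment, ex_args)
  expect_named(ex, c("wht200", "wht300", "wht300_per50"))
  expect_equal(ex$wht200$stocking$whitefish, 200)
  expect_equal(ex$wht300$stocking$whitefish, 300)
  expect_equal(ex$wht300$stocking$perch, 0)
  expect_equal(ex$wht300_per50$stocking$whitefish, 300)
  expect_equal(ex$wht300_per50$stocking$perch, 50)
  expect_identical(ex$wht200$harvest, ex$wht300_per50$harvest)
})

test_that("the wht300_per50 arm with zero perch stocking equals wht300", {
  web <- make_lc_like_web()
  base <- scenario_config(web, stocking = list(whitefish = 300),
                          years_unfished = 3, years_fished = 2)
  neutral <- scenario_config(web, stocking = list(whitefish = 300, perch = 0),
                             years_unfished = 3, years_fished = 2)
  expect_identical(run_scenario(base)$biomass, run_scenario(neutral)$biomass)
})

test_that("robustness arms enumerate the stated grids", {
  web <- make_toy_web("fishery")  # cheap structural check of arm naming
  web_lc <- make_lc_like_web()
  ex <- run_experiment(web_lc, years_unfished = 1, years_fished = 0,
                       robustness = TRUE)
  expect_true(all(c("wht250", "wht350", "wht300_per25", "wht300_per75",
                    "wht300_fmax0.4", "wht300_fmax0.6") %in% names(ex)))
  expect_equal(ex$wht250$stocking$whitefish, 250)
  expect_equal(ex$wht300_per25$stocking$perch, 25)
  expect_equal(ex$wht300_fmax0.4$harvest$F_max, 0.4 / 91)
})
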