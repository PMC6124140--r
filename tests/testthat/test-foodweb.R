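test_that("functional response hits its closed-form anchor points", {
  web <- make_toy_web("chain")
  B0 <- web$guilds$B0[web$guilds$id == "grazer"]

  # all prey extinct: zero numerator
  B <- c(producer = 0, grazer = 10)
  expect_equal(unname(functional_response("grazer", B, web)), 0)

  # single prey at half-saturation density: F = 1/2 exactly (q = 1, d = 0)
  B <- c(producer = B0, grazer = 10)
  expect_equal(unname(functional_response("grazer", B, web)[["producer"]]), 0.5)

  # two equally preferred prey at B0 each: F = 1/4 each
  g <- rbind(web$guilds[1, ],
             data.frame(id = "producer2", name = "producer2", role = "producer",
                        body_mass = 0.001, r = 1, x = NA, y = NA, B0 = NA,
                        q = NA, d = NA),
             web$guilds[2, ])
  l <- data.frame(consumer_id = "grazer", prey_id = c("producer", "producer2"),
                  omega = 0.5, e = 0.45)
  web2 <- foodweb(g, l, K = 1000)
  B <- c(producer = 200, producer2 = 200, grazer = 10)
  Fv <- functional_response("grazer", B, web2)
  expect_equal(unname(Fv), c(0.25, 0.25))
})

test_that("functional response saturates and responds monotonically", {
  web <- make_toy_web("competition")
  for (s in 1:20) {
    B <- random_state(web, s)
    Fv <- functional_response("grazer_a", B, web)
    expect_true(all(Fv >= 0 & Fv < 1))
    expect_lt(sum(Fv), 1)
    # nondecreasing in prey biomass
    B_up <- B; B_up["producer"] <- B["producer"] * 2 + 1
    expect_gte(sum(functional_response("grazer_a", B_up, web)), sum(Fv))
    # nonincreasing in own biomass when d > 0
    B_self <- B; B_self["grazer_a"] <- B["grazer_a"] * 2 + 1
    expect_lte(sum(functional_response("grazer_a", B_self, web)), sum(Fv))
  }
})

test_that("producer growth factor is the shared logistic term", {
  web <- make_toy_web("logistic", K = 1000)
  expect_equal(producer_growth_factor(c(producer = 1000), web), 0)
  expect_equal(producer_growth_factor(c(producer = 0), web), 1)
  expect_equal(producer_growth_factor(c(producer = 500), web), 0.5)
})

test_that("rhs reduces to logistic growth and never resurrects the extinct", {
  web <- make_toy_web("logistic", K = 1000, r = 1)
  expect_equal(unname(atn_rhs(c(producer = 1000), web)), 0)
  # logistic form at arbitrary density
  expect_equal(unname(atn_rhs(c(producer = 250), web)),
               1 * 250 * (1 - 250 / 1000))

  fishery <- make_toy_web("fishery")
  for (s in 1:10) {
    B <- random_state(fishery, s)
    zero <- sample(names(B), 2)
    B[zero] <- 0
    dB <- atn_rhs(B, fishery)
    expect_true(all(dB[zero] >= 0))
  }
})

test_that("rhs agrees with the loop-based oracle on random small webs", {
  worst <- 0
  for (s in 1:100) {
    web <- random_small_web(s)
    B <- random_state(web, s + 1000)
    got <- atn_rhs(B, web)
    want <- oracle_rhs(B, web)
    denom <- pmax(abs(want), 1)
    worst <- max(worst, max(abs(got - want) / denom))
  }
  expect_lt(worst, 1e-12)
})

test_that("rhs rejects non-finite states with the guild named", {
  web <- make_toy_web("chain")
  expect_error(atn_rhs(c(producer = NaN, grazer = 1), web), "producer")
})

test_that("web validation reports counts and catches broken webs", {
  web <- make_lc_like_web()
  rep <- validate_web(web)
  expect_equal(rep$n_guilds, 30)
  expect_equal(rep$n_links, 133)
  expect_length(rep$violations, 0)
  expect_output(print(rep), "30 guilds, 133 links")

  # diet preferences not summing to one, consumer named
  bad <- web
  i <- which(bad$links$consumer_id == "daphnia")[1]
  bad$links$omega[i] <- bad$links$omega[i] * 0.5
  expect_error(validate_web(bad), "daphnia")
  rep2 <- validate_web(bad, strict = FALSE)
  expect_true(any(grepl("daphnia", rep2$violations)))

  # empty web is a hard error
  empty <- foodweb(web$guilds[0, ], web$links[0, ], K = 1)
  expect_error(validate_web(empty), "no guilds")

  # producers with prey links are flagged
  bad2 <- web
  bad2$links$consumer_id[1] <- "pico_algae"
  expect_error(validate_web(bad2), "pico_algae")
})
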