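test_that("log-normal parameters reproduce the requested median and IQR", {
  for (case in list(c(7.06, 4.71), c(5.89, 3.54), c(12, 0.5))) {
    p <- lognormal_params(case[1], case[2])
    expect_equal(exp(p$log_mean), case[1])
    iqr <- qlnorm(0.75, p$log_mean, p$log_sd) -
      qlnorm(0.25, p$log_mean, p$log_sd)
    expect_lt(abs(iqr - case[2]), 1e-8)
  }
  # zero-spread limit is degenerate at the median
  p0 <- lognormal_params(1, 1e-10)
  expect_lt(p0$log_sd, 1e-9)
  expect_error(lognormal_params(-1, 1), "positive")
  expect_error(lognormal_params(1, 0), "positive")
})

test_that("intercept-only outcome mechanism hits its target rate", {
  cfg <- sim_config(n_children = 50000, codebook = tiny_codebook(),
                    true_log_odds = list(),
                    outcome_intercept = qlogis(0.2), seed = 11)
  d <- generate_survey(cfg)
  frac <- mean(classify_bll(d$bll))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 50000))
})

test_that("area margins match the configured log-normal medians", {
  cfg <- sim_config(n_children = 100000, area_split = 0, seed = 7)
  d <- generate_survey(cfg)
  expect_lt(abs(median(d$bll) - 5.89) / 5.89, 0.01)
  cfg2 <- sim_config(n_children = 100000, area_split = 1, seed = 7)
  d2 <- generate_survey(cfg2)
  expect_lt(abs(median(d2$bll) - 7.06) / 7.06, 0.01)
})

test_that("generation is a pure function of the config", {
  cfg <- tiny_config(n = 500, seed = 99)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  d3 <- generate_survey(tiny_config(n = 500, seed = 100))
  expect_false(identical(generate_survey(cfg), d3))
})

test_that("categorical frequencies are calibrated to category_probs", {
  cfg <- sim_config(n_children = 100000, area_split = 1, seed = 13)
  d <- generate_survey(cfg)
  probs <- cfg$category_probs
  for (nm in c("sex", "wash_hands", "outdoor_play")) {
    pr <- probs[[nm]]
    emp <- prop.table(table(d[[nm]]))
    for (cat in names(pr)) {
      se <- sqrt(pr[cat] * (1 - pr[cat]) / nrow(d))
      expect_lt(abs(emp[cat] - pr[cat]), 3 * se + 1e-12)
    }
  }
  ew <- prop.table(table(d$ewaste_proximity))
  expect_lt(abs(ew["yes"] - 0.40), 3 * sqrt(0.4 * 0.6 / nrow(d)))
})

test_that("a standard logistic fit recovers the true mechanism", {
  cfg <- sim_config(n_children = 10000, area_split = 1, seed = 21)
  d <- generate_survey(cfg)
  enc <- encode_survey(d, attr(d, "codebook"))
  g <- glm(enc$y ~ enc$X[, c("sex.girl", "ewaste_proximity.yes")],
           family = binomial())
  est <- summary(g)$coefficients[2:3, 1:2]
  expect_lt(abs(est[1, 1] - log(0.51)), 3 * est[1, 2])
  expect_lt(abs(est[2, 1] - log(2.28)), 3 * est[2, 2])
})

test_that("missingness injection honors its rates", {
  cfg <- tiny_config(n = 20000, seed = 31)
  d <- generate_survey(cfg)
  expect_identical(inject_missingness(d, list(), seed = 1), d)
  d0 <- inject_missingness(d, list(wash_hands = 0), seed = 1)
  expect_identical(d0, d)
  d1 <- inject_missingness(d, list(wash_hands = 1), seed = 1)
  expect_true(all(is.na(d1$wash_hands)))
  expect_identical(d1$sex, d$sex)
  expect_identical(d1$id, d$id)
  d05 <- inject_missingness(d, list(wash_hands = 0.05), seed = 5)
  expect_lt(abs(sum(is.na(d05$wash_hands)) - 1000),
            3 * sqrt(20000 * 0.05 * 0.95))
  expect_error(inject_missingness(d, list(wash_hands = 1.2)), "0,1")
  expect_error(inject_missingness(d, list(id = 0.5)), "eligible")
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(sim_config(n_children = 0), "positive integer")
  expect_error(sim_config(bll_median_exposed = -1), "> 0")
  expect_error(sim_config(true_log_odds = list(nope = c(a = 1))), "unknown")
  bad_probs <- default_category_probs()
  bad_probs$sex <- c(boy = 0.5, girl = 0.6)
  expect_error(sim_config(category_probs = bad_probs), "sum to 1")
})

test_that("simulation configs round-trip through JSON", {
  cfg <- sim_config(n_children = 150, seed = 77,
                    missing_rates = list(bll = 0.02))
  path <- tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_identical(generate_survey(cfg), generate_survey(cfg2))
})
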