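test_that("chi-square engine matches brute-force expected counts", {
  set.seed(71)
  for (r in 1:25) {
    nr <- sample(2:4, 1)
    nc <- sample(2:3, 1)
    tab <- matrix(rpois(nr * nc, 20) + 1, nr, nc)
    res <- chi_square_test(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_lt(abs(res$statistic - stat), 1e-10)
    expect_equal(res$degrees_of_freedom, (nr - 1) * (nc - 1))
    expect_lt(abs(res$p_value - pchisq(stat, (nr - 1) * (nc - 1),
                                       lower.tail = FALSE)), 1e-12)
  }
  # proportional rows carry no association
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  res0 <- chi_square_test(prop)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_square_test(matrix(1:3, 1)), "2x2")
})

test_that("elevated proportions reconcile with the classifier", {
  d <- generate_survey(tiny_config(n = 2000, seed = 14))
  tab <- proportion_elevated(d, "sex")
  cls <- classify_bll(d$bll)
  for (i in seq_len(nrow(tab))) {
    sub <- cls[d$sex == tab$stratum[i]]
    expect_equal(tab$n_elevated[i], sum(sub == 1, na.rm = TRUE))
    expect_equal(tab$n_total[i], sum(!is.na(sub)))
  }
  expect_equal(tab$percent, 100 * tab$n_elevated / tab$n_total)
  # zero-elevated stratum reports 0%
  d2 <- d
  d2$bll[d2$sex == "girl"] <- 5
  t2 <- proportion_elevated(d2, "sex")
  expect_equal(t2$percent[t2$stratum == "girl"], 0)
  # missing BLLs shrink the denominator, not the stratum
  d3 <- d
  d3$bll[1:100] <- NA
  t3 <- proportion_elevated(d3)
  expect_equal(t3$n_total, nrow(d) - 100)
})

test_that("log-scale t-test behaves under null and alternative", {
  d <- generate_survey(tiny_config(n = 400, seed = 15))
  # a group compared with itself
  dd <- rbind(d, d)
  dd$id <- as.character(seq_len(nrow(dd)))
  dd$half <- rep(c("a", "b"), each = nrow(d))
  res <- compare_log_bll(dd, "half")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # null calibration: rejection rate ~5% over replicates
  set.seed(16)
  rej <- replicate(300, {
    x <- data.frame(bll = exp(rnorm(120, log(6), 0.49)),
                    g = rep(c("a", "b"), 60))
    compare_log_bll(x, "g")$p_value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))

  # power at area-comparison-like margins (log-mean diff 0.18, sd 0.49)
  set.seed(17)
  rej2 <- replicate(100, {
    x <- data.frame(
      bll = exp(c(rnorm(496, log(7.06), 0.49), rnorm(327, log(5.89), 0.49))),
      g = rep(c("e", "r"), c(496, 327)))
    compare_log_bll(x, "g")$p_value < 0.05
  })
  expect_gt(mean(rej2), 0.99 - 1e-9)

  expect_error(compare_log_bll(data.frame(bll = c(1, 2), g = c("a", "b")),
                               "g"), ">= 2")
})

test_that("Mann-Whitney comparison covers exact and tied cases", {
  # identical samples for both sexes
  d <- data.frame(sex = rep(c("boy", "girl"), each = 30),
                  bll = rep(exp(rnorm(30, 2, 0.3)), 2),
                  area = "exposed")
  res <- mann_whitney_by_sex(d)
  expect_equal(unname(res$statistic), 30 * 30 / 2)
  expect_equal(res$p_value, 1)
  # single observation per sex, boy above girl: U = 1, exact p = 1
  d1 <- data.frame(sex = c("boy", "girl"), bll = c(9, 5), area = "exposed")
  r1 <- mann_whitney_by_sex(d1)
  expect_equal(unname(r1$statistic), 1)
  expect_equal(r1$p_value, 1)
  # a real location shift is detected in most replicates
  set.seed(18)
  pvals <- replicate(60, {
    x <- data.frame(sex = rep(c("boy", "girl"), each = 300),
                    bll = exp(c(rnorm(300, log(7) + 0.2, 0.5),
                                rnorm(300, log(7), 0.5))))
    mann_whitney_by_sex(x)$p_value
  })
  expect_gt(mean(pvals < 0.05), 0.5)
  expect_error(mann_whitney_by_sex(data.frame(sex = "boy", bll = 3)),
               "both sexes")
})

test_that("covariance-adjusted area comparison isolates the area effect", {
  set.seed(19)
  n <- 4000
  # covariates independent of area and outcome: adjustment is inert
  d <- data.frame(area = rep(c("exposed", "reference"), each = n / 2),
                  age = rnorm(n, 4.6, 1), height = rnorm(n, 105, 8),
                  weight = rnorm(n, 17, 3))
  d$bll <- exp(log(6) + 0.18 * (d$area == "exposed") + rnorm(n, 0, 0.49))
  adj <- adjusted_area_comparison(d)
  un <- compare_log_bll(d, "area")
  expect_lt(abs(adj$estimate - un$estimate), 0.02)
  expect_lt(abs(adj$estimate - 0.18), 3 * (adj$conf_int[2] - adj$estimate) / 1.96)
  expect_equal(names(adj$adjusted_means), c("exposed", "reference"))

  # area effect entirely mediated by height vanishes after adjustment
  set.seed(20)
  d2 <- data.frame(area = rep(c("exposed", "reference"), each = n / 2),
                   age = rnorm(n, 4.6, 1), weight = rnorm(n, 17, 3))
  d2$height <- 105 + 3 * (d2$area == "exposed") + rnorm(n, 0, 2)
  d2$bll <- exp(log(6) + 0.1 * (d2$height - 105) + rnorm(n, 0, 0.3))
  adj2 <- adjusted_area_comparison(d2)
  expect_lt(abs(adj2$estimate), 3 * (adj2$conf_int[2] - adj2$estimate) / 1.96)

  d3 <- d
  d3$weight <- d3$height
  expect_error(adjusted_area_comparison(d3), "rank-deficient")
})

test_that("descriptive battery is invariant to record order", {
  cfg <- sim_config(n_children = 800, seed = 22)
  d <- generate_survey(cfg)
  s1 <- describe_survey(d)
  set.seed(23)
  d2 <- d[sample(nrow(d)), ]
  s2 <- describe_survey(d2)
  expect_equal(s1$bll_summary, s2$bll_summary)
  expect_equal(s1$elevated_by_area, s2$elevated_by_area)
  expect_equal(s1$area_t_test$p_value, s2$area_t_test$p_value)
  expect_equal(s1$area_ancova$estimate, s2$area_ancova$estimate)
  expect_equal(vapply(s1$stratum_chi_square, `[[`, 0, "p_value"),
               vapply(s2$stratum_chi_square, `[[`, 0, "p_value"))
})
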