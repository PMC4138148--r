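test_that("blood lead dichotomization is inclusive at the threshold", {
  expect_identical(classify_bll(c(7.06, 10, 9.999, 15)), c(0L, 1L, 0L, 1L))
  expect_identical(classify_bll(c(5, NA)), c(0L, NA))
  expect_identical(classify_bll(5, threshold = 5), 1L)
  expect_error(classify_bll(-1), "> 0")
})

test_that("dummy expansion yields reference-omitted contiguous groups", {
  d <- generate_survey(tiny_config(n = 300, seed = 5))
  enc <- encode_survey(d, tiny_codebook())
  # height(1) + sex(1) + 3-cat(2) + 4-cat(3)
  expect_equal(enc$p, 7)
  expect_equal(enc$G, 4)
  expect_equal(enc$df, c(1L, 1L, 2L, 3L))
  expect_equal(enc$rescale, sqrt(c(1, 2, 3)[c(1, 1, 2, 3)]))
  expect_true(all(diff(enc$group) >= 0))
  expect_equal(colnames(enc$X)[3:4], c("outdoor_play.h1_3",
                                       "outdoor_play.h3_plus"))
  # a 4-category item contributes one group of exactly 3 indicator columns
  expect_equal(sum(enc$group == 4), 3)
  # no reference-category column
  expect_false("wash_hands.no" %in% colnames(enc$X))
})

test_that("the default codebook expands to 72 columns in 31 groups", {
  cfg <- sim_config(n_children = 600, seed = 3)
  d <- generate_survey(cfg)
  enc <- encode_survey(d, attr(d, "codebook"))
  expect_equal(enc$p, 72)
  expect_equal(enc$G, 31)
  expect_equal(sum(enc$df), enc$p)
})

test_that("an all-binary codebook gives singleton groups", {
  cb <- codebook(list(
    codebook_entry("a", "binary", c("n", "y")),
    codebook_entry("b", "binary", c("n", "y")),
    codebook_entry("c", "binary", c("n", "y"))
  ))
  set.seed(8)
  d <- data.frame(id = as.character(1:200),
                  a = sample(c("n", "y"), 200, TRUE),
                  b = sample(c("n", "y"), 200, TRUE),
                  c = sample(c("n", "y"), 200, TRUE),
                  bll = exp(rnorm(200, log(8), 0.5)))
  enc <- encode_survey(d, cb)
  expect_equal(enc$p, 3)
  expect_equal(enc$G, 3)
  expect_true(all(enc$df == 1L))
})

test_that("illegal categories and missing records are handled", {
  d <- generate_survey(tiny_config(n = 100, seed = 9))
  d$wash_hands <- as.character(d$wash_hands)
  d$wash_hands[17] <- "sometimes"
  expect_error(encode_survey(d, tiny_codebook()),
               "child_00017.*sometimes.*wash_hands")
  d2 <- generate_survey(tiny_config(n = 200, seed = 10))
  d2$bll[1:20] <- NA
  d2$sex[21:30] <- NA
  enc <- encode_survey(d2, tiny_codebook())
  expect_equal(enc$n, 170)
  # single-class outcome is refused
  d3 <- generate_survey(tiny_config(n = 150, seed = 11))
  expect_error(encode_survey(d3, tiny_codebook(), threshold = Inf),
               "single-class")
})

test_that("group orthonormalization and exact back-transform", {
  set.seed(42)
  n <- 100
  X <- cbind(matrix(rnorm(n * 3), n, 3), rnorm(n, 5, 2))
  y <- as.integer(runif(n) < 0.4)
  enc <- encode_matrix(X, y, c(1, 1, 1, 2))
  std <- standardize_groups(enc)
  for (g in 1:2) {
    j <- which(std$group == g)
    Z <- std$X[, j, drop = FALSE]
    expect_equal(unname(crossprod(Z) / n), diag(length(j)),
                 tolerance = 1e-12)
    expect_equal(unname(colMeans(Z)), rep(0, length(j)), tolerance = 1e-12)
  }
  # singleton group becomes a unit-variance column
  expect_equal(mean(std$X[, 4]^2), 1, tolerance = 1e-12)

  # least squares on one orthonormalized 3-column group, mapped back,
  # equals the direct fit (independent oracle: lm on the raw block)
  X1 <- X[, 1:3]
  enc1 <- encode_matrix(X1, y, c(1, 1, 1))
  std1 <- standardize_groups(enc1)
  yc <- rnorm(n)
  b_std <- drop(crossprod(std1$X, yc)) / n
  int_std <- mean(yc)
  orig <- bllasso:::back_transform(std1, int_std, b_std)
  direct <- lm(yc ~ X1)
  pred_std <- int_std + drop(std1$X %*% b_std)
  pred_orig <- orig$intercept + drop(X1 %*% orig$beta)
  expect_lt(max(abs(pred_std - pred_orig)), 1e-10)
  expect_lt(max(abs(pred_orig - unname(fitted(direct)))), 1e-10)

  # rank-deficient group is refused with its name
  Xbad <- cbind(X[, 1], X[, 1] * 2)
  encb <- encode_matrix(Xbad, y, c(1, 1))
  expect_error(standardize_groups(encb), "rank-deficient")
})

test_that("encoding is invariant to record order", {
  d <- generate_survey(tiny_config(n = 250, seed = 12))
  enc1 <- encode_survey(d, tiny_codebook())
  perm <- sample(nrow(d))
  enc2 <- encode_survey(d[perm, ], tiny_codebook())
  o1 <- order(enc1$ids)
  o2 <- order(enc2$ids)
  expect_identical(enc1$X[o1, ], enc2$X[o2, ])
  expect_identical(enc1$y[o1], enc2$y[o2])
})
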