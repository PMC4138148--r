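test_that("predicted probabilities are correct and saturate safely", {
  enc <- random_instance(50, c(1, 1), seed = 30)
  f <- fit_grplasso(enc, lambda = 1)  # all-null fit
  f$intercept <- 0
  f$beta[] <- 0
  expect_equal(predict_prob(f, c(3, -2)), 0.5)
  f$beta[] <- c(log(2.28), 0)
  expect_equal(predict_prob(f, c(1, 0)), 0.695, tolerance = 1e-3)
  f$beta[] <- c(800, 0)
  expect_equal(predict_prob(f, c(1, 0)), 1)
  expect_equal(predict_prob(f, c(-1, 0)), 0)
  expect_error(predict_prob(f, c(1, 2, 3)), "columns")
})

test_that("penalized objective matches hand computations", {
  set.seed(31)
  y <- rep(0:1, 25)
  X <- matrix(rnorm(100), 50, 2)
  enc <- encode_matrix(X, y, c(1, 2))
  # null model on balanced data: per-observation loss is ln 2
  expect_equal(penalized_objective(enc, 0, c(0, 0), 0.5), log(2))
  # lambda = 0 reduces to the per-observation negative log-likelihood
  b <- c(0.3, -0.2)
  eta <- drop(X %*% b) + 0.1
  nll <- mean(log(1 + exp(eta)) - y * eta)
  expect_equal(penalized_objective(enc, 0.1, b, 0), nll)
  # penalty term: groups of sizes {2,3} with norms {1,2} at lambda 0.1
  enc2 <- encode_matrix(matrix(rnorm(250), 50, 5), y, c(1, 1, 2, 2, 2))
  beta2 <- c(1, 0, 2, 0, 0)
  pen <- penalized_objective(enc2, 0, beta2, 0.1) -
    penalized_objective(enc2, 0, beta2, 0)
  expect_equal(pen, 0.1 * (sqrt(2) * 1 + sqrt(3) * 2), tolerance = 1e-12)
})

test_that("lambda_max bounds the active set exactly", {
  enc <- random_instance(200, c(1, 2, 3), seed = 32)
  lmax <- lambda_max(enc)
  f <- fit_grplasso(enc, 1.01 * lmax)
  expect_length(f$active_groups, 0)
  expect_equal(f$intercept_std, qlogis(mean(enc$y)), tolerance = 1e-6)
  f2 <- fit_grplasso(enc, lmax)
  expect_length(f2$active_groups, 0)
  # just below lambda_max something activates
  f3 <- fit_grplasso(enc, 0.95 * lmax)
  expect_gte(length(f3$active_groups), 1)
  # singleton-group reduction to the classical Lasso formula
  enc1 <- random_instance(150, 1, seed = 33)
  std1 <- standardize_groups(enc1)
  r <- std1$y - mean(std1$y)
  expect_equal(lambda_max(enc1),
               max(abs(crossprod(std1$X, r))) / std1$n, tolerance = 1e-12)
  # constant response has lambda_max 0
  encc <- random_instance(60, c(1, 1), seed = 34)
  encc$y <- rep(0:1, 30)  # keep two classes for encoding, then overwrite
  std <- standardize_groups(encc)
  std$y <- rep(1L, 60)
  expect_equal(lambda_max(std), 0)
})

test_that("near-unpenalized fit matches the Newton-Raphson MLE", {
  set.seed(35)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  beta <- c(0.8, -0.5, 0.3, 0, 0.4)
  y <- as.integer(runif(n) < plogis(0.2 + drop(X %*% beta)))
  enc <- encode_matrix(X, y, c(1, 2, 2, 3, 3))
  f <- fit_grplasso(enc, lambda = 1e-8, tol = 1e-10, max_iter = 20000)
  mle <- glm(y ~ X, family = binomial())
  expect_lt(max(abs(coef(f) - coef(mle))), 1e-4)
})

test_that("group descent agrees with an independent convex minimizer", {
  worst <- 0
  for (r in 1:20) {
    dfs <- sample(1:4, sample(2:3, 1), replace = TRUE)
    enc <- random_instance(sample(40:100, 1), dfs, seed = 400 + r)
    lmax <- lambda_max(enc)
    lambda <- lmax * runif(1, 0.05, 0.6)
    f <- fit_grplasso(enc, lambda, tol = 1e-9, max_iter = 20000)
    std <- standardize_groups(enc)
    mine <- penalized_objective(std, f$intercept_std, f$beta_std, lambda)
    oracle <- oracle_grplasso(enc, lambda)
    worst <- max(worst, abs(mine - oracle$value))
    expect_lt(abs(mine - oracle$value), 1e-5)
    # KKT certificate at the solution
    expect_true(attr(kkt_check(f, enc, tol = 1e-6), "ok"))
  }
  expect_lt(worst, 1e-5)
})

test_that("objective is non-increasing at every descent sweep", {
  enc <- random_instance(120, c(2, 3, 1), seed = 36)
  for (lam in lambda_max(enc) * c(0.5, 0.1, 0.01)) {
    f <- fit_grplasso(enc, lam, trace = TRUE)
    expect_true(all(diff(f$objective_trace) <= 1e-12))
  }
})

test_that("all-singleton groups reproduce the classical Lasso (glmnet)", {
  skip_if_not_installed("glmnet")
  set.seed(37)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6)
  y <- as.integer(runif(n) < plogis(0.3 + X[, 1] * 0.9 - X[, 2] * 0.6))
  enc <- encode_matrix(X, y, 1:6)
  std <- standardize_groups(enc)
  lam <- 0.04
  f <- fit_grplasso(enc, lam, tol = 1e-10, max_iter = 20000)
  g <- glmnet::glmnet(std$X, y, family = "binomial", alpha = 1,
                      lambda = lam, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(f$beta_std - as.numeric(g$beta))), 1e-4)
})

test_that("solutions respect within-group permutation equivariance", {
  enc <- random_instance(150, c(3, 2, 1), seed = 38)
  lam <- 0.3 * lambda_max(enc)
  f1 <- fit_grplasso(enc, lam)
  perm <- c(3, 1, 2, 4, 5, 6)  # permute columns of group 1 only
  enc2 <- encode_matrix(enc$X[, perm], enc$y, enc$group)
  f2 <- fit_grplasso(enc2, lam)
  expect_equal(unname(f2$beta), unname(f1$beta[perm]), tolerance = 1e-6)
  expect_equal(f1$group_norms, f2$group_norms, tolerance = 1e-6)
})

test_that("the lambda path is ordered, continuous and deterministic", {
  enc <- random_instance(200, c(2, 2, 1, 3), seed = 39)
  path <- grplasso_path(enc, n_lambda = 40)
  expect_true(all(diff(path$lambdas) < 0))
  # first entry is the all-null model
  expect_true(all(path$beta_std[, 1] == 0))
  # penalty norm of the solution is non-increasing in lambda
  pen <- vapply(seq_along(path$lambdas), function(l) {
    sum(vapply(seq_len(enc$G), function(g) {
      sqrt(sum(path$beta_std[path$encoded$group == g, l]^2)) *
        path$encoded$rescale[g]
    }, 0))
  }, 0)
  expect_true(all(diff(pen) >= -1e-8))
  # deterministic
  path2 <- grplasso_path(enc, n_lambda = 40)
  expect_identical(path$beta_std, path2$beta_std)

  # a dominant group activates first on the path
  set.seed(40)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6)
  y <- as.integer(runif(n) < plogis(drop(X[, 5:6] %*% c(1.5, -1.2))))
  encd <- encode_matrix(X, y, c(1, 1, 2, 2, 3, 3))
  pd <- grplasso_path(encd, n_lambda = 60)
  first_active <- apply(pd$active, 1, function(a) which(a)[1])
  expect_equal(unname(which.min(first_active)), 3)
})

test_that("unpenalized reference fit reports Wald inference and ORs", {
  # single binary exposure from stratified counts: slope equals the
  # log cross-product odds ratio
  x <- c(rep(0, 409 + 70), rep(1, 221 + 92))
  y <- c(rep(0, 409), rep(1, 70), rep(0, 221), rep(1, 92))
  enc <- encode_matrix(matrix(x, ncol = 1), y, 1)
  mle <- fit_logistic_mle(enc)
  expect_equal(mle$table$estimate[2], log((92 * 409) / (70 * 221)),
               tolerance = 1e-8)
  expect_equal(mle$table$or[2], exp(mle$table$estimate[2]), tolerance = 1e-12)
  # intercept-only model recovers logit(ybar)
  set.seed(41)
  y2 <- rbinom(150, 1, 0.35)
  enc2 <- encode_matrix(matrix(rnorm(150), ncol = 1), y2, 1)
  mle2 <- fit_logistic_mle(enc2, columns = character(0))
  expect_equal(mle2$intercept, qlogis(mean(y2)), tolerance = 1e-8)
  # null Wald p-values are roughly uniform
  set.seed(42)
  pv <- replicate(200, {
    Xn <- matrix(rnorm(400), 200, 2)
    yn <- rbinom(200, 1, 0.4)
    fit_logistic_mle(encode_matrix(Xn, yn, 1:2))$table$p_value[2]
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  # separation is detected
  xs <- c(rep(0, 30), rep(1, 30))
  ys <- xs
  expect_error(fit_logistic_mle(encode_matrix(matrix(xs, ncol = 1), ys, 1)),
               "separation|rank")
})
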