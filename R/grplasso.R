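#' Penalized group-Lasso logistic objective
#'
#' Per-observation negative binomial log-likelihood plus the grouped
#' penalty:
#' `(1/n) * sum_i [log(1 + exp(eta_i)) - y_i eta_i] + lambda * sum_g sqrt(df_g) * ||beta_g||_2`
#' with `eta = intercept + X beta`, evaluated on whatever scale `encoded$X`
#' is currently on.
#'
#' @param encoded a `bll_encoded`.
#' @param intercept scalar intercept.
#' @param beta coefficient vector of length `encoded$p`.
#' @param lambda penalty level (per-observation-loss scale).
#' @return scalar objective value.
#' @export
penalized_objective <- function(encoded, intercept, beta, lambda) {
  stopifnot(length(beta) == encoded$p)
  eta <- drop(intercept + encoded$X %*% beta)
  loss <- mean(log1pexp(eta) - encoded$y * eta)
  pen <- sum(vapply(seq_len(encoded$G), function(g) {
    encoded$rescale[g] * sqrt(sum(beta[encoded$group == g]^2))
  }, 0))
  loss + lambda * pen
}

#' Smallest all-null penalty level
#'
#' The smallest lambda at which every penalized group is zero:
#' `max_g ||X_g' (y - ybar)||_2 / (n * sqrt(df_g))` on the orthonormalized
#' design. Fitting at or above this value yields the intercept-only model.
#'
#' @param encoded a `bll_encoded` (standardized automatically).
#' @return scalar lambda_max.
#' @export
lambda_max <- function(encoded) {
  encoded <- standardize_groups(encoded)
  r <- encoded$y - mean(encoded$y)
  max(vapply(seq_len(encoded$G), function(g) {
    j <- encoded$group == g
    sqrt(sum(crossprod(encoded$X[, j, drop = FALSE], r)^2)) /
      (encoded$n * encoded$rescale[g])
  }, 0))
}

#' Fit a group-Lasso logistic regression at one penalty level
#'
#' Minimizes the penalized objective by group descent: the logistic loss is
#' majorized at the current iterate with the curvature bound 1/4 and every
#' (orthonormalized) group is updated by an exact closed-form group
#' soft-threshold; the intercept is updated unpenalized. The objective is
#' non-increasing across cycles; iteration stops when the largest
#' coefficient change in a cycle falls below `tol`.
#'
#' @param encoded a `bll_encoded` (standardized automatically).
#' @param lambda penalty level, >= 0.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter maximum descent cycles.
#' @param trace record the objective after every cycle (for diagnostics).
#' @return a `grplasso_fit`: intercept and coefficients on both the
#'   original and orthonormalized scales, the active group set, objective,
#'   iterations and convergence flag.
#' @export
fit_grplasso <- function(encoded, lambda, tol = 1e-6, max_iter = 1000,
                         trace = FALSE) {
  stopifnot(lambda >= 0)
  enc <- standardize_groups(encoded)
  eng <- engine_call(enc, lambda, tol, max_iter, trace)
  build_fit(enc, lambda, eng$beta[, 1], eng$b0[1], eng$iterations[1],
            eng$converged[1],
            if (trace) eng$objective_trace[[1]] else NULL)
}

grp_starts <- function(enc) {
  as.integer(cumsum(c(0, enc$df[-enc$G])))
}

# shared entry point to the C++ group-descent core
engine_call <- function(enc, lambdas, tol, max_iter, trace = FALSE,
                        b0_init = qlogis(mean(enc$y)),
                        beta_init = numeric(enc$p)) {
  stopifnot(enc$standardized)
  pat <- matrix(-1L, enc$n, enc$G)
  pmats <- vector("list", enc$G)
  for (g in seq_len(enc$G)) {
    pg <- enc$pattern[[g]]
    if (!is.null(pg)) {
      pat[, g] <- pg$code
      pmats[[g]] <- pg$P
    } else {
      pmats[[g]] <- matrix(0, 0, 0)
    }
  }
  grplasso_engine(enc$X, as.numeric(enc$y), grp_starts(enc), enc$df,
                  enc$rescale, lambdas, tol, as.integer(max_iter),
                  b0_init, beta_init, pat, pmats, trace)
}

# back-transform a whole coefficient matrix (p x L, standardized scale)
back_transform_matrix <- function(enc, b0_std, beta_std) {
  B <- matrix(0, enc$p, ncol(beta_std))
  for (g in seq_len(enc$G)) {
    j <- which(enc$group == g)
    B[j, ] <- enc$transform[[g]] %*% beta_std[j, , drop = FALSE]
  }
  list(intercept = b0_std - drop(crossprod(enc$center, B)), beta = B)
}

build_fit <- function(enc, lambda, beta_std, b0_std, iterations, converged,
                      obj_trace = NULL) {
  if (!converged) {
    warning(sprintf("group descent did not converge in %d cycles at lambda = %g",
                    iterations, lambda))
  }
  orig <- back_transform(enc, b0_std, beta_std)
  gnorm <- vapply(seq_len(enc$G), function(g) {
    sqrt(sum(beta_std[enc$group == g]^2))
  }, 0)
  structure(list(
    intercept = orig$intercept, beta = orig$beta,
    intercept_std = b0_std,
    beta_std = setNames(beta_std, enc$column_names),
    lambda = lambda,
    objective = penalized_objective(enc, b0_std, beta_std, lambda),
    iterations = iterations, converged = converged,
    objective_trace = obj_trace,
    group = enc$group, group_names = enc$group_names,
    df = enc$df, rescale = enc$rescale,
    group_norms = setNames(gnorm, enc$group_names),
    active_groups = enc$group_names[gnorm > 0],
    n = enc$n, threshold = enc$threshold),
    class = "grplasso_fit")
}

#' @export
print.grplasso_fit <- function(x, ...) {
  cat(sprintf("Group-Lasso logistic fit: lambda = %.4g, %d/%d active groups, %s in %d cycles\n",
              x$lambda, length(x$active_groups), length(x$group_names),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  if (length(x$active_groups)) {
    cat("  active:", paste(x$active_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.grplasso_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' Predicted elevated-BLL probability
#'
#' `plogis(intercept + x' beta)` on the original covariate scale,
#' numerically stable (saturates to 0/1 for extreme linear predictors).
#'
#' @param fit a `grplasso_fit`.
#' @param x covariate row or matrix, conformable with `fit$beta`.
#' @return probability vector.
#' @export
predict_prob <- function(fit, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(fit$beta)) {
    stop_invalid("x has %d columns, fit has %d coefficients", ncol(x),
                 length(fit$beta))
  }
  plogis(drop(fit$intercept + x %*% fit$beta))
}

#' @export
predict.grplasso_fit <- function(object, newx, type = c("response", "link"),
                                 ...) {
  type <- match.arg(type)
  newx <- if (is.null(dim(newx))) matrix(newx, nrow = 1) else as.matrix(newx)
  eta <- drop(object$intercept + newx %*% object$beta)
  if (type == "link") eta else plogis(eta)
}

#' Solve the full regularization path
#'
#' Fits on a log-spaced decreasing grid from `lambda_max` (all groups null)
#' down to `lambda_min_ratio * lambda_max`, warm-starting each fit from the
#' previous solution.
#'
#' @inheritParams fit_grplasso
#' @param n_lambda grid size.
#' @param lambda_min_ratio smallest grid value as a fraction of lambda_max.
#' @return a `grplasso_path`: `lambdas`, standardized-scale coefficient
#'   matrix, intercepts, per-lambda active-group matrix, and the encoded
#'   data used.
#' @export
grplasso_path <- function(encoded, n_lambda = 100, lambda_min_ratio = 0.001,
                          tol = 1e-6, max_iter = 1000) {
  enc <- standardize_groups(encoded)
  lmax <- lambda_max(enc)
  if (lmax <= 0) stop_invalid("constant response: lambda_max is 0")
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = n_lambda))
  eng <- engine_call(enc, lambdas, tol, max_iter)
  active <- vapply(seq_along(lambdas), function(l) {
    vapply(seq_len(enc$G), function(g) {
      any(eng$beta[enc$group == g, l] != 0)
    }, NA)
  }, logical(enc$G))
  active <- matrix(active, nrow = enc$G,
                   dimnames = list(enc$group_names, NULL))
  structure(list(lambdas = lambdas, lambda_max = lmax,
                 beta_std = eng$beta, b0_std = eng$b0,
                 iterations = eng$iterations, converged = eng$converged,
                 active = active, encoded = enc),
            class = "grplasso_path")
}

#' @export
print.grplasso_path <- function(x, ...) {
  cat(sprintf("Group-Lasso path: %d lambdas in [%.4g, %.4g], %d groups\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              nrow(x$active)))
  cat(sprintf("  active groups: %d at lambda_min, %d at lambda_max\n",
              sum(x$active[, ncol(x$active)]), sum(x$active[, 1])))
  invisible(x)
}

# materialize the path entry closest to lambda as a grplasso_fit
path_fit <- function(path, lambda) {
  l <- which.min(abs(path$lambdas - lambda))
  build_fit(path$encoded, path$lambdas[l], path$beta_std[, l],
            path$b0_std[l], path$iterations[l], path$converged[l])
}

#' Coefficient-path table
#'
#' Original-scale coefficients along the grid, tidy for plotting.
#'
#' @param path a `grplasso_path`.
#' @return data frame with `lambda`, `term`, `group`, `coefficient`.
#' @export
path_table <- function(path) {
  enc <- path$encoded
  do.call(rbind, lapply(seq_along(path$lambdas), function(l) {
    orig <- back_transform(enc, path$b0_std[l], path$beta_std[, l])
    data.frame(lambda = path$lambdas[l], term = enc$column_names,
               group = enc$group_names[enc$group],
               coefficient = unname(orig$beta))
  }))
}

#' Karush-Kuhn-Tucker certificate
#'
#' At a minimizer of the penalized objective, every active group's
#' per-observation log-likelihood gradient has norm `lambda * sqrt(df_g)`
#' and every inactive group's at most that; the intercept gradient is zero.
#'
#' @param fit a `grplasso_fit`.
#' @param encoded the `bll_encoded` the fit came from.
#' @param tol certificate tolerance.
#' @return invisibly, a data frame of per-group gradient norms and bounds;
#'   attribute `"ok"` is `TRUE` when the certificate holds.
#' @export
kkt_check <- function(fit, encoded, tol = 1e-6) {
  enc <- standardize_groups(encoded)
  eta <- drop(fit$intercept_std + enc$X %*% fit$beta_std)
  r <- plogis(eta) - enc$y
  gn <- vapply(seq_len(enc$G), function(g) {
    j <- enc$group == g
    sqrt(sum(crossprod(enc$X[, j, drop = FALSE], r)^2)) / enc$n
  }, 0)
  bound <- fit$lambda * enc$rescale
  active <- fit$group_norms > 0
  ok <- all(abs(gn[active] - bound[active]) <= tol) &&
    all(gn[!active] <= bound[!active] + tol) &&
    abs(mean(r)) <= tol
  out <- data.frame(group = enc$group_names, gradient_norm = gn,
                    bound = bound, active = active)
  attr(out, "ok") <- ok
  invisible(out)
}
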