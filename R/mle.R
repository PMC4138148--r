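#' Unpenalized logistic reference fit
#'
#' Ordinary maximum-likelihood logistic regression on the dummy-expanded
#' design (IRLS via [stats::glm()]), the conventional comparison model for
#' the penalized fit: per-dummy Wald z-tests, odds ratios and 95%
#' confidence intervals.
#'
#' @param encoded a `bll_encoded` (used on the original, unstandardized
#'   scale).
#' @param columns optional column names to restrict the design to.
#' @return a `bll_mle`: the underlying `glm` fit plus a coefficient table
#'   with `estimate`, `se`, `z`, `p_value`, `or`, `or_low`, `or_high`.
#' @export
fit_logistic_mle <- function(encoded, columns = NULL) {
  X <- encoded$X
  if (encoded$standardized) {
    stop_invalid("fit_logistic_mle expects the unstandardized design")
  }
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  if (nrow(X) <= ncol(X)) stop_invalid("need n > p for the unpenalized fit")
  dat <- data.frame(y = encoded$y, X, check.names = FALSE)
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
  if (any(is.na(coef(fit)))) stop_invalid("rank-deficient design")
  if (!fit$converged || any(abs(coef(fit)) > 15)) {
    stop_invalid(paste("separation detected (diverging coefficients);",
                       "consider a penalized fit"))
  }
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    z = sm[, 3], p_value = sm[, 4],
                    or = exp(sm[, 1]),
                    or_low = exp(sm[, 1] - 1.96 * sm[, 2]),
                    or_high = exp(sm[, 1] + 1.96 * sm[, 2]),
                    row.names = NULL)
  structure(list(glm = fit, table = tab,
                 intercept = unname(coef(fit)[1]),
                 beta = coef(fit)[-1]),
            class = "bll_mle")
}

#' @export
print.bll_mle <- function(x, ...) {
  cat("Unpenalized logistic reference fit\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(head(tab, 15), row.names = FALSE)
  if (nrow(tab) > 15) cat(sprintf("  ... %d more terms\n", nrow(tab) - 15))
  invisible(x)
}
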