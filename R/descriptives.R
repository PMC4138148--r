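#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square without continuity correction, the test used
#' throughout the characteristics-by-stratum comparisons.
#'
#' @param counts r x c matrix of non-negative integer counts (r, c >= 2).
#' @return a `bll_test` result: method, statistic, degrees of freedom,
#'   p-value.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop_invalid("need at least a 2x2 table")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_invalid("degenerate table: a zero marginal")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  test_result("Pearson chi-square", unname(ct$statistic),
              unname(ct$parameter), unname(ct$p.value))
}

test_result <- function(method, statistic, df = NULL, p_value,
                        estimate = NULL, conf_int = NULL) {
  structure(list(method = method, statistic = statistic,
                 degrees_of_freedom = df, p_value = p_value,
                 estimate = estimate, conf_int = conf_int),
            class = "bll_test")
}

#' @export
print.bll_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$method, x$statistic,
              if (!is.null(x$degrees_of_freedom))
                sprintf(" (df = %g)", x$degrees_of_freedom) else "",
              x$p_value))
  if (!is.null(x$estimate)) {
    cat(sprintf("  estimate %.4g", x$estimate))
    if (!is.null(x$conf_int)) {
      cat(sprintf(" (95%% CI %.4g, %.4g)", x$conf_int[1], x$conf_int[2]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Proportion of children with elevated blood lead, by stratum
#'
#' Percentages are computed over non-missing BLL denominators within each
#' stratum, matching how published stratum percentages reconcile with their
#' printed counts.
#'
#' @param dataset data frame with a `bll` column.
#' @param stratify_by character vector of stratifying columns (empty for the
#'   whole sample).
#' @param threshold elevated cutoff, µg/dL.
#' @return data frame with stratum labels, `n_elevated`, `n_total`, and
#'   `percent` (`NaN` for empty strata).
#' @export
proportion_elevated <- function(dataset, stratify_by = character(0),
                                threshold = 10) {
  cls <- classify_bll(dataset$bll, threshold)
  if (length(stratify_by) == 0) {
    strata <- factor(rep("all", nrow(dataset)))
    labels <- data.frame(stratum = "all")
  } else {
    strata <- interaction(dataset[stratify_by], drop = FALSE, sep = ":")
    labels <- data.frame(stratum = levels(strata))
  }
  num <- tapply(cls, strata, function(z) sum(z == 1, na.rm = TRUE))
  den <- tapply(cls, strata, function(z) sum(!is.na(z)))
  num[is.na(num)] <- 0L; den[is.na(den)] <- 0L
  out <- cbind(labels,
               n_elevated = as.integer(num),
               n_total = as.integer(den))
  out$percent <- 100 * out$n_elevated / out$n_total
  rownames(out) <- NULL
  out
}

#' Two-group comparison of log-transformed blood lead
#'
#' Independent-samples t-test on natural-log BLL (pooled variance), the
#' scale on which skewed blood lead concentrations are approximately
#' normal. Reports the log-scale mean difference and geometric means.
#'
#' @param dataset data frame with `bll`.
#' @param grouping name of a two-level grouping column.
#' @return a `bll_test` with `estimate` = difference in log means and
#'   `geometric_means` attached.
#' @export
compare_log_bll <- function(dataset, grouping) {
  g <- factor(dataset[[grouping]])
  ok <- !is.na(dataset$bll) & !is.na(g)
  g <- droplevels(g[ok]); lb <- log(dataset$bll[ok])
  if (nlevels(g) != 2) stop_invalid("'%s' must have exactly 2 observed levels",
                                    grouping)
  if (any(table(g) < 2)) stop_invalid("need >= 2 observations per group")
  tt <- t.test(lb ~ g, var.equal = TRUE)
  res <- test_result("Two-sample t-test on log(BLL)", unname(tt$statistic),
                     unname(tt$parameter), tt$p.value,
                     estimate = unname(diff(rev(tt$estimate))),
                     conf_int = unname(tt$conf.int))
  res$geometric_means <- setNames(exp(tt$estimate), levels(g))
  res
}

#' Mann-Whitney comparison of blood lead between sexes
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum), exact for small untied
#' samples and otherwise the tie-corrected normal approximation.
#'
#' @param dataset data frame with `bll` and `sex`.
#' @param within_area optional area level to restrict to.
#' @return a `bll_test`; the statistic is the U for the first sex level.
#' @export
mann_whitney_by_sex <- function(dataset, within_area = NULL) {
  if (!is.null(within_area)) dataset <- dataset[dataset$area == within_area, ]
  s <- factor(dataset$sex)
  ok <- !is.na(dataset$bll) & !is.na(s)
  s <- droplevels(s[ok]); b <- dataset$bll[ok]
  if (nlevels(s) != 2) stop_invalid("both sexes must be present")
  # ties preclude the exact small-sample p; the tie-corrected normal
  # approximation is then used, so the routine warning is silenced
  wt <- suppressWarnings(wilcox.test(b ~ s, correct = FALSE))
  test_result("Mann-Whitney U", unname(wt$statistic), NULL, wt$p.value)
}

#' Covariance-adjusted area comparison of log blood lead
#'
#' Linear model `log(bll) ~ area + covariates`: the area contrast adjusted
#' for growth covariates, with the F-test for the area term and adjusted
#' (least-squares) means per area at the covariate means.
#'
#' @param dataset data frame with `bll`, `area`, and the covariates.
#' @param covariates character vector of adjustment covariates.
#' @return a `bll_test` with `estimate` = adjusted log-scale area effect
#'   (exposed minus reference) and `adjusted_means` (geometric scale).
#' @export
adjusted_area_comparison <- function(dataset,
                                     covariates = c("age", "height", "weight")) {
  need <- c("bll", "area", covariates)
  dat <- dataset[complete.cases(dataset[, need, drop = FALSE]), need,
                 drop = FALSE]
  dat$logbll <- log(dat$bll)
  dat$area <- factor(dat$area, levels = c("reference", "exposed"))
  fml <- stats::reformulate(c("area", covariates), response = "logbll")
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) stop_invalid("rank-deficient design (collinear covariates)")
  sm <- summary(fit)$coefficients["areaexposed", ]
  cm <- colMeans(dat[covariates])
  nd <- data.frame(area = factor(c("exposed", "reference"),
                                 levels = c("reference", "exposed")),
                   as.list(cm))
  res <- test_result("ANCOVA area contrast on log(BLL)",
                     unname(sm["t value"])^2, 1, unname(sm["Pr(>|t|)"]),
                     estimate = unname(sm["Estimate"]),
                     conf_int = unname(sm["Estimate"] +
                                         c(-1, 1) * 1.96 * sm["Std. Error"]))
  res$adjusted_means <- setNames(exp(predict(fit, nd)),
                                 c("exposed", "reference"))
  res
}

#' Descriptive summary of a survey
#'
#' The descriptive battery: per-area BLL medians (IQR), elevated
#' proportions by area and sex, the log-scale area t-test, the
#' covariance-adjusted area contrast, per-area Mann-Whitney sex
#' comparisons, and chi-square tests of each categorical covariate against
#' the BLL stratum.
#'
#' @param dataset a `bll_survey`.
#' @param threshold elevated cutoff, µg/dL.
#' @return list of tables and `bll_test` results, class `bll_describe`.
#' @export
describe_survey <- function(dataset, threshold = 10) {
  cb <- attr(dataset, "codebook")
  bll_summary <- do.call(rbind, lapply(split(dataset, dataset$area), function(d) {
    data.frame(area = d$area[1], n = sum(!is.na(d$bll)),
               median = median(d$bll, na.rm = TRUE),
               iqr = unname(diff(quantile(d$bll, c(0.25, 0.75), na.rm = TRUE,
                                          type = 7))))
  }))
  rownames(bll_summary) <- NULL
  out <- list(
    bll_summary = bll_summary,
    elevated_by_area = proportion_elevated(dataset, "area", threshold),
    elevated_by_area_sex = proportion_elevated(dataset, c("area", "sex"),
                                               threshold),
    area_t_test = compare_log_bll(dataset, "area"),
    area_ancova = adjusted_area_comparison(dataset),
    sex_mann_whitney = lapply(
      setNames(nm = levels(factor(dataset$area))),
      function(a) mann_whitney_by_sex(dataset, within_area = a))
  )
  if (!is.null(cb)) {
    strat <- factor(classify_bll(dataset$bll, threshold), levels = 0:1,
                    labels = c("low", "high"))
    tests <- list()
    for (e in cb$entries) {
      if (e$kind == "continuous") next
      tab <- table(factor(dataset[[e$name]], levels = e$categories), strat)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) >= 2 && all(colSums(tab) > 0)) {
        tests[[e$name]] <- chi_square_test(unclass(tab))
      }
    }
    out$stratum_chi_square <- tests
  }
  structure(out, class = "bll_describe")
}

#' @export
print.bll_describe <- function(x, ...) {
  cat("BLL by area, µg/dL:\n")
  print(transform(x$bll_summary, median = round(median, 2), iqr = round(iqr, 2)))
  cat("\nElevated BLL by area:\n")
  print(transform(x$elevated_by_area, percent = round(percent, 2)))
  cat(sprintf("\nArea t-test on log(BLL): p = %.3g; ANCOVA-adjusted: p = %.3g\n",
              x$area_t_test$p_value, x$area_ancova$p_value))
  invisible(x)
}
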