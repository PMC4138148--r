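#' Log-normal parameters from a median and interquartile range
#'
#' Blood lead concentrations in exposed child populations are strongly
#' right-skewed and conventionally summarized as median (IQR). A log-normal
#' with log-mean `mu` and log-sd `sigma` has median `exp(mu)` and IQR
#' `2 * sinh(0.6745 * sigma) * median` (0.6745 is the standard normal upper
#' quartile), so `mu = log(median)` and `sigma` is recovered by a root find
#' on the IQR equation.
#'
#' @param median target median, µg/dL (> 0).
#' @param iqr target interquartile range, µg/dL (> 0).
#' @return list with `log_mean` and `log_sd`; the implied distribution has
#'   exactly the requested median and an IQR matching `iqr` within 1e-8.
#' @examples
#' p <- lognormal_params(7.06, 4.71)
#' qlnorm(0.75, p$log_mean, p$log_sd) - qlnorm(0.25, p$log_mean, p$log_sd)
#' @export
lognormal_params <- function(median, iqr) {
  if (!is.numeric(median) || median <= 0 || !is.numeric(iqr) || iqr <= 0) {
    stop_invalid("median and iqr must be strictly positive")
  }
  z75 <- qnorm(0.75)
  # 2 * sinh(z75 * sigma) * median = iqr  =>  sigma in closed form
  log_sd <- asinh(iqr / (2 * median)) / z75
  # polish with a root find on the exact quantile equation
  f <- function(s) qlnorm(0.75, log(median), s) - qlnorm(0.25, log(median), s) - iqr
  log_sd <- uniroot(f, c(log_sd / 2, log_sd * 2 + 1e-9), tol = 1e-12)$root
  list(log_mean = log(median), log_sd = log_sd)
}

#' Default per-covariate category probabilities
#'
#' Category probabilities for the categorical entries of
#' [default_codebook()]. Probabilities may be area-dependent (a list with
#' `exposed` and `reference` elements); by default only the e-waste
#' proximity item differs by area (common around a recycling site, rare in
#' the reference area). `age_group` carries no probabilities: it is derived
#' from the simulated age.
#'
#' @param cb a `bll_codebook`.
#' @return named list of probability vectors (or exposed/reference pairs).
#' @export
default_category_probs <- function(cb = default_codebook()) {
  cn <- covariate_names(cb)
  probs <- list()
  if ("sex" %in% cn) probs$sex <- c(boy = 0.56, girl = 0.44)
  if ("ewaste_proximity" %in% cn) {
    probs$ewaste_proximity <- list(exposed = c(no = 0.60, yes = 0.40),
                                   reference = c(no = 0.95, yes = 0.05))
  }
  for (e in cb$entries) {
    if (e$kind == "continuous" || e$name %in% c(names(probs), "age_group")) next
    k <- length(e$categories)
    p <- if (k == 4) c(0.15, 0.40, 0.30, 0.15) else c(0.30, 0.45, 0.25)
    probs[[e$name]] <- setNames(p, e$categories)
  }
  probs
}

#' Simulation configuration
#'
#' Bundles everything the survey generator needs: cohort size and area
#' split, the codebook and category probabilities, the per-area log-normal
#' blood-lead margins (median and IQR, µg/dL), the true logistic mechanism
#' for the elevated-BLL outcome (log-odds per dummy column), optional
#' missingness rates, and the seed. The default margins and effects are the
#' study conditions this generator emulates: medians 7.06 (IQR 4.71) and
#' 5.89 (IQR 3.54) µg/dL in the exposed and reference areas, odds ratio
#' 0.51 for girls and 2.28 for e-waste workshops near the house.
#'
#' When `outcome_intercept` is `NA` (the default) the intercept is
#' calibrated per area so that the cohort-average elevated probability
#' equals the log-normal tail probability above `threshold`; the truncated
#' draws then reassemble the full log-normal, so the continuous margins and
#' the odds-ratio structure hold simultaneously.
#'
#' @param n_children number of children (>= 1).
#' @param area_split proportion of children in the exposed area.
#' @param codebook a `bll_codebook`.
#' @param category_probs named list of category probabilities; entries may
#'   be a single vector or a list with `exposed`/`reference` vectors.
#' @param bll_median_exposed,bll_median_reference,bll_iqr_exposed,bll_iqr_reference
#'   log-normal margins per area, µg/dL (> 0).
#' @param true_log_odds named list: covariate name -> named log-odds vector
#'   on the dummy scale (names are non-reference categories).
#' @param outcome_intercept log-odds intercept, or `NA` to calibrate per
#'   area (see Details).
#' @param threshold elevated-BLL cutoff, µg/dL.
#' @param missing_rates named per-field missingness probabilities in [0,1].
#' @param seed integer seed; generation is a pure function of the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_children = 823,
                       area_split = 0.603,
                       codebook = default_codebook(),
                       category_probs = default_category_probs(codebook),
                       bll_median_exposed = 7.06,
                       bll_median_reference = 5.89,
                       bll_iqr_exposed = 4.71,
                       bll_iqr_reference = 3.54,
                       true_log_odds = list(
                         sex = c(girl = log(0.51)),
                         ewaste_proximity = c(yes = log(2.28))),
                       outcome_intercept = NA_real_,
                       threshold = 10,
                       missing_rates = list(),
                       seed = 1L) {
  if (!is_count(n_children)) stop_invalid("n_children must be a positive integer")
  if (area_split < 0 || area_split > 1) stop_invalid("area_split must be in [0,1]")
  for (m in c(bll_median_exposed, bll_median_reference,
              bll_iqr_exposed, bll_iqr_reference)) {
    if (!is.numeric(m) || m <= 0) stop_invalid("medians and IQRs must be > 0")
  }
  stopifnot(inherits(codebook, "bll_codebook"))
  cn <- covariate_names(codebook)
  for (nm in names(category_probs)) {
    if (!nm %in% cn) stop_invalid("category_probs names unknown covariate '%s'", nm)
    e <- codebook_get(codebook, nm)
    pr <- category_probs[[nm]]
    pr <- if (is.list(pr)) pr else list(pr)
    for (v in pr) {
      if (any(v < 0) || any(v > 1) || abs(sum(v) - 1) > 1e-9) {
        stop_invalid("category probabilities for '%s' must lie in [0,1] and sum to 1", nm)
      }
      if (length(v) != length(e$categories)) {
        stop_invalid("category probabilities for '%s' must have %d entries",
                     nm, length(e$categories))
      }
    }
  }
  for (nm in names(true_log_odds)) {
    if (!nm %in% cn) stop_invalid("true_log_odds names unknown covariate '%s'", nm)
  }
  for (nm in names(missing_rates)) {
    r <- missing_rates[[nm]]
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop_invalid("missing rate for '%s' must be in [0,1]", nm)
    }
  }
  structure(list(n_children = as.integer(n_children), area_split = area_split,
                 codebook = codebook, category_probs = category_probs,
                 bll_median_exposed = bll_median_exposed,
                 bll_median_reference = bll_median_reference,
                 bll_iqr_exposed = bll_iqr_exposed,
                 bll_iqr_reference = bll_iqr_reference,
                 true_log_odds = true_log_odds,
                 outcome_intercept = as.numeric(outcome_intercept),
                 threshold = as.numeric(threshold),
                 missing_rates = missing_rates, seed = as.integer(seed)),
            class = "sim_config")
}

# linear predictor of the outcome mechanism (excluding intercept)
mechanism_eta <- function(config, responses) {
  eta <- numeric(nrow(responses))
  for (nm in names(config$true_log_odds)) {
    co <- config$true_log_odds[[nm]]
    hit <- match(as.character(responses[[nm]]), names(co))
    eta <- eta + ifelse(is.na(hit), 0, co[hit])
  }
  eta
}

#' Generate a synthetic child survey
#'
#' Draws a seeded cohort with the structure the downstream analysis
#' assumes: area of residence, sex, age, anthropometrics, coded
#' questionnaire responses, and a blood lead level (µg/dL). The elevated
#' status is drawn first from the logistic mechanism
#' `P(BLL >= threshold) = plogis(intercept + x' beta_true)`, then the BLL is
#' drawn from the area's log-normal truncated to the corresponding side of
#' the threshold, so the continuous margins and the odds-ratio mechanism
#' are honored simultaneously. Identical configs (including seed) produce
#' byte-identical datasets.
#'
#' @param config a [sim_config()].
#' @return a `bll_survey` data frame (one child per row) with the codebook
#'   attached as attribute `"codebook"`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_children
  cb <- config$codebook
  with_seed(config$seed, {
    area <- factor(ifelse(runif(n) < config$area_split, "exposed", "reference"),
                   levels = c("exposed", "reference"))
    # age in years, truncated normal over the kindergarten range
    age <- rnorm(n, 4.62, 1.13)
    age <- pmin(pmax(age, 1.5), 10.9)

    dat <- data.frame(id = sprintf("child_%05d", seq_len(n)),
                      area = area, age = round(age, 2),
                      stringsAsFactors = FALSE)
    # anthropometrics grow with age
    dat$height <- round(72.5 + 6.9 * age + rnorm(n, 0, 4.2), 1)
    dat$weight <- round(7.9 + 2.0 * age + rnorm(n, 0, 2.1), 1)
    dat$head_circumference <- round(46.9 + 0.69 * age + rnorm(n, 0, 1.6), 1)
    dat$chest_circumference <- round(46.8 + 1.12 * age + rnorm(n, 0, 3.1), 1)

    for (e in cb$entries) {
      if (e$kind == "continuous") next
      if (e$name == "age_group") {
        dat$age_group <- factor(cut(age, c(-Inf, 3, 6, Inf),
                                    labels = e$categories, right = FALSE),
                                levels = e$categories)
        next
      }
      pr <- config$category_probs[[e$name]]
      if (is.null(pr)) {
        pr <- setNames(rep(1 / length(e$categories), length(e$categories)),
                       e$categories)
      }
      if (is.list(pr)) {
        resp <- character(n)
        for (a in levels(area)) {
          idx <- which(area == a)
          resp[idx] <- sample(e$categories, length(idx), replace = TRUE,
                              prob = pr[[a]])
        }
      } else {
        resp <- sample(e$categories, n, replace = TRUE, prob = pr)
      }
      dat[[e$name]] <- factor(resp, levels = e$categories)
    }

    eta <- mechanism_eta(config, dat)
    intercept <- numeric(n)
    for (a in levels(area)) {
      idx <- which(area == a)
      if (!length(idx)) next
      if (is.na(config$outcome_intercept)) {
        lp <- if (a == "exposed") {
          lognormal_params(config$bll_median_exposed, config$bll_iqr_exposed)
        } else {
          lognormal_params(config$bll_median_reference, config$bll_iqr_reference)
        }
        p_target <- 1 - plnorm(config$threshold, lp$log_mean, lp$log_sd)
        f <- function(c0) mean(plogis(c0 + eta[idx])) - p_target
        intercept[idx] <- uniroot(f, c(-30, 30), tol = 1e-10)$root
      } else {
        intercept[idx] <- config$outcome_intercept
      }
    }
    elevated <- runif(n) < plogis(intercept + eta)

    bll <- numeric(n)
    for (a in levels(area)) {
      idx <- which(area == a)
      if (!length(idx)) next
      lp <- if (a == "exposed") {
        lognormal_params(config$bll_median_exposed, config$bll_iqr_exposed)
      } else {
        lognormal_params(config$bll_median_reference, config$bll_iqr_reference)
      }
      Ft <- plnorm(config$threshold, lp$log_mean, lp$log_sd)
      u <- runif(length(idx))
      # inverse-CDF draw from the truncated region matching elevated status
      u <- ifelse(elevated[idx], Ft + u * (1 - Ft), u * Ft)
      bll[idx] <- qlnorm(pmin(pmax(u, 1e-15), 1 - 1e-15), lp$log_mean, lp$log_sd)
    }
    # full precision: rounding could flip draws sitting at the threshold
    dat$bll <- bll

    if (length(config$missing_rates)) {
      dat <- inject_missingness(dat, config$missing_rates,
                                seed = derive_seed(config$seed, 1L))
    }
    structure(dat, codebook = cb, class = c("bll_survey", "data.frame"))
  })
}

#' Inject missing-completely-at-random values
#'
#' Each eligible field is independently set missing with its configured
#' rate; ids, the area label, and fields without a rate are untouched.
#'
#' @param dataset a `bll_survey` data frame.
#' @param missing_rates named list of per-field probabilities in [0,1].
#' @param seed integer seed.
#' @return the dataset with `NA`s injected.
#' @export
inject_missingness <- function(dataset, missing_rates, seed = 1L) {
  for (nm in names(missing_rates)) {
    r <- missing_rates[[nm]]
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop_invalid("missing rate for '%s' must be in [0,1]", nm)
    }
    if (!nm %in% names(dataset) || nm %in% c("id", "area")) {
      stop_invalid("'%s' is not an eligible field", nm)
    }
  }
  with_seed(seed, {
    for (nm in names(missing_rates)) {
      hit <- runif(nrow(dataset)) < missing_rates[[nm]]
      dataset[[nm]][hit] <- NA
    }
    dataset
  })
}

#' @export
print.bll_survey <- function(x, ...) {
  cat(sprintf("Child survey: %d records (%d exposed / %d reference), %d fields\n",
              nrow(x), sum(x$area == "exposed"), sum(x$area == "reference"),
              ncol(x)))
  cat(sprintf("  BLL, µg/dL: median %.2f (IQR %.2f), %d missing\n",
              median(x$bll, na.rm = TRUE),
              diff(quantile(x$bll, c(0.25, 0.75), na.rm = TRUE)),
              sum(is.na(x$bll))))
  invisible(x)
}
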