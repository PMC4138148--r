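#' Selection-frequency stability of the group Lasso
#'
#' Robustness machinery for the selected covariate groups: how often each
#' group is active in the CV-tuned group-Lasso fit across resampled
#' datasets.
#'
#' `bootstrap_stability()` draws, per replicate, `N` records with
#' replacement, re-encodes (dropping dummy columns for categories absent
#' from the draw), re-standardizes, re-tunes lambda by stratified k-fold
#' cross-validation, and records the active group set at the selected
#' lambda. `permutation_stability()` instead draws a stratified subsample
#' of size `N` that preserves the overall elevated/non-elevated proportion
#' and then randomly permutes the outcome labels within it (class counts
#' fixed exactly), so any selection on these replicates is spurious.
#' Replicates whose outcome collapses to a single class are redrawn (and
#' counted). Replicate seeds derive from the master seed by a counter, so
#' the frequency vector is reproducible.
#'
#' @param dataset a `bll_survey`.
#' @param N replicate sample size (conventionally 150, 200 or 250).
#' @param B number of replicates.
#' @param seed master seed.
#' @param threshold elevated cutoff, µg/dL.
#' @param codebook a `bll_codebook`; defaults to the dataset's.
#' @param k,n_lambda,lambda_min_ratio,tol,max_iter tuning controls passed
#'   to [cv_grplasso()].
#' @return a `bll_stability`: per-group selection frequencies (over all
#'   codebook groups), per-replicate selected lambdas and active-set
#'   sizes, scenario, `N`, `B`, seed, and the redraw count.
#' @export
bootstrap_stability <- function(dataset, N, B = 100, seed = 1L,
                                threshold = 10,
                                codebook = attr(dataset, "codebook"),
                                k = 10, n_lambda = 100,
                                lambda_min_ratio = 0.001,
                                tol = 1e-6, max_iter = 1000) {
  stability_run(dataset, "bootstrap", N, B, seed, threshold, codebook,
                k, n_lambda, lambda_min_ratio, tol, max_iter)
}

#' @rdname bootstrap_stability
#' @export
permutation_stability <- function(dataset, N, B = 100, seed = 1L,
                                  threshold = 10,
                                  codebook = attr(dataset, "codebook"),
                                  k = 10, n_lambda = 100,
                                  lambda_min_ratio = 0.001,
                                  tol = 1e-6, max_iter = 1000) {
  stability_run(dataset, "permutation", N, B, seed, threshold, codebook,
                k, n_lambda, lambda_min_ratio, tol, max_iter)
}

stability_run <- function(dataset, scenario, N, B, seed, threshold, codebook,
                          k, n_lambda, lambda_min_ratio, tol, max_iter) {
  stopifnot(inherits(codebook, "bll_codebook"), is_count(N), is_count(B))
  vars <- covariate_names(codebook)
  complete <- dataset[complete.cases(dataset[, c(vars, "bll"), drop = FALSE]), ,
                      drop = FALSE]
  n <- nrow(complete)
  y_all <- classify_bll(complete$bll, threshold)
  prop_high <- mean(y_all)
  n_high <- round(N * prop_high)
  if (scenario == "permutation" &&
      (n_high > sum(y_all) || N - n_high > sum(!y_all))) {
    stop_invalid("N = %d too large for a proportion-preserving subsample", N)
  }

  gnames <- vars
  counts <- setNames(numeric(length(gnames)), gnames)
  sel_lambda <- numeric(B)
  n_active <- integer(B)
  class_prop <- numeric(B)
  redraws <- 0L

  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      rep_seed <- derive_seed(seed, b + (B + 1) * attempt)
      res <- with_seed(rep_seed, {
        if (scenario == "bootstrap") {
          idx <- sample.int(n, N, replace = TRUE)
          dat_b <- complete[idx, , drop = FALSE]
        } else {
          ihi <- which(y_all == 1)
          ilo <- which(y_all == 0)
          hi <- ihi[sample.int(length(ihi), n_high)]
          lo <- ilo[sample.int(length(ilo), N - n_high)]
          dat_b <- complete[c(hi, lo), , drop = FALSE]
        }
        enc_b <- tryCatch(
          encode_survey(dat_b, codebook, threshold, drop_unused = TRUE),
          error = function(e) e)
        if (!inherits(enc_b, "error") && scenario == "permutation") {
          enc_b$y <- sample(enc_b$y)
        }
        if (inherits(enc_b, "error")) enc_b else {
          cv_seed <- derive_seed(rep_seed, 1L)
          tryCatch(cv_grplasso(enc_b, k = k, n_lambda = n_lambda,
                               lambda_min_ratio = lambda_min_ratio,
                               seed = cv_seed, tol = tol,
                               max_iter = max_iter),
                   error = function(e) e)
        }
      })
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 20) {
        stop_invalid("replicate %d failed repeatedly: %s", b,
                     conditionMessage(res))
      }
    }
    act <- res$selected_fit$active_groups
    counts[act] <- counts[act] + 1
    sel_lambda[b] <- res$selected_lambda
    n_active[b] <- length(act)
    class_prop[b] <- mean(res$path$encoded$y)
  }

  structure(list(scenario = scenario, N = as.integer(N), B = as.integer(B),
                 frequency = counts / B, selected_lambda = sel_lambda,
                 n_active = n_active, class_proportion = class_prop,
                 source_proportion = prop_high,
                 seed = as.integer(seed), redraws = redraws),
            class = "bll_stability")
}

#' @export
print.bll_stability <- function(x, ...) {
  cat(sprintf("%s stability: N = %d, B = %d replicates (%d redraws)\n",
              x$scenario, x$N, x$B, x$redraws))
  top <- sort(x$frequency, decreasing = TRUE)[1:min(5, length(x$frequency))]
  cat("  top selection frequencies:\n")
  for (nm in names(top)) cat(sprintf("    %-20s %.2f\n", nm, top[nm]))
  cat(sprintf("  mean active groups per replicate: %.2f\n", mean(x$n_active)))
  invisible(x)
}

#' Tidy stability table
#'
#' @param ... one or more `bll_stability` results.
#' @return data frame with `scenario`, `N`, `group`, `frequency`.
#' @export
stability_table <- function(...) {
  do.call(rbind, lapply(list(...), function(s) {
    data.frame(scenario = s$scenario, N = s$N, group = names(s$frequency),
               frequency = unname(s$frequency))
  }))
}
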