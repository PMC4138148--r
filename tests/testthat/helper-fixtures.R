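# small codebook: one continuous + binary + 3-category + 4-category item
tiny_codebook <- function() {
  codebook(list(
    codebook_entry("height", "continuous"),
    codebook_entry("sex", "binary", c("boy", "girl")),
    codebook_entry("outdoor_play", "ordinal", c("h0_1", "h1_3", "h3_plus")),
    codebook_entry("wash_hands", "ordinal",
                   c("no", "occasionally", "often", "always"))
  ))
}

tiny_config <- function(n = 400, seed = 1, ...) {
  sim_config(n_children = n, codebook = tiny_codebook(),
             true_log_odds = list(sex = c(girl = -0.5)),
             seed = seed, ...)
}

# random grouped logistic instance for solver oracles
random_instance <- function(n, df_per_group, beta = NULL, seed = 1) {
  set.seed(seed)
  p <- sum(df_per_group)
  X <- matrix(rnorm(n * p), n, p)
  group <- rep(seq_along(df_per_group), df_per_group)
  if (is.null(beta)) beta <- rnorm(p, 0, 0.8)
  eta <- drop(X %*% beta) - mean(X %*% beta)
  y <- as.integer(runif(n) < plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  encode_matrix(X, y, group)
}

# independent minimizer of the penalized objective: accelerated proximal
# gradient (FISTA) with the exact group-norm prox and a global Lipschitz
# step — a different algorithm family from the block-coordinate solver
oracle_grplasso <- function(encoded, lambda, iters = 6000) {
  enc <- standardize_groups(encoded)
  Xa <- cbind(1, enc$X)
  y <- enc$y
  n <- enc$n
  L <- max(svd(Xa, nu = 0, nv = 0)$d)^2 / (4 * n)
  groups <- lapply(seq_len(enc$G), function(g) which(enc$group == g) + 1)
  obj <- function(b) {
    eta <- drop(Xa %*% b)
    mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      lambda * sum(vapply(seq_len(enc$G), function(g) {
        enc$rescale[g] * sqrt(sum(b[groups[[g]]]^2))
      }, 0))
  }
  b <- c(qlogis(mean(y)), numeric(enc$p))
  v <- b
  tk <- 1
  best <- obj(b)
  for (it in seq_len(iters)) {
    eta <- drop(Xa %*% v)
    z <- v - drop(crossprod(Xa, plogis(eta) - y)) / (n * L)
    bn <- z
    for (g in seq_len(enc$G)) {
      j <- groups[[g]]
      nrm <- sqrt(sum(z[j]^2))
      thr <- lambda * enc$rescale[g] / L
      bn[j] <- if (nrm > thr) (1 - thr / nrm) * z[j] else 0
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- bn + ((tk - 1) / tn) * (bn - b)
    b <- bn
    tk <- tn
    if (it %% 500 == 0) best <- min(best, obj(b))
  }
  list(value = min(best, obj(b)), par = b)
}
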