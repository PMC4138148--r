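#' Dichotomize a blood lead level
#'
#' Elevated blood lead is defined inclusively at the public-health action
#' threshold: `1` iff `bll >= threshold` (default 10 µg/dL).
#'
#' @param bll blood lead level(s), µg/dL (> 0; `NA` allowed and propagated —
#'   records with missing BLL are excluded upstream, not classified).
#' @param threshold cutoff, µg/dL.
#' @return integer vector of 0/1 (with `NA` where `bll` is missing).
#' @export
classify_bll <- function(bll, threshold = 10) {
  if (any(!is.na(bll) & bll <= 0)) stop_invalid("bll must be > 0")
  as.integer(bll >= threshold)
}

#' Encode a survey into a group-structured design matrix
#'
#' Builds the binary response `y` (elevated BLL) and the dummy-expanded
#' design matrix `X` with its group structure: each k-category covariate
#' becomes one contiguous group of k-1 indicator columns (reference level
#' omitted), each continuous covariate a singleton group. Only complete
#' cases over the codebook covariates and the BLL are kept. The per-group
#' penalty rescaling is `sqrt(df_g)`.
#'
#' @param dataset a `bll_survey` data frame (or any data frame with the
#'   codebook's columns and a `bll` column).
#' @param codebook a `bll_codebook`; defaults to the one attached to the
#'   dataset.
#' @param threshold elevated-BLL cutoff, µg/dL.
#' @param drop_unused drop dummy columns whose category is absent from the
#'   (sub)sample, shrinking the group; groups left without columns are
#'   removed. Used by the resampling machinery, where small subsamples can
#'   miss rare categories entirely.
#' @return an object of class `bll_encoded` with elements `y`, `X`,
#'   `group` (per-column group index), `group_names`, `df`, `rescale`,
#'   `column_names`, `ids`, and standardization state.
#' @export
encode_survey <- function(dataset, codebook = attr(dataset, "codebook"),
                          threshold = 10, drop_unused = FALSE) {
  stopifnot(inherits(codebook, "bll_codebook"))
  vars <- covariate_names(codebook)
  miss <- setdiff(c(vars, "bll"), names(dataset))
  if (length(miss)) stop_invalid("dataset lacks columns: %s",
                                 paste(miss, collapse = ", "))

  for (e in codebook$entries) {
    if (e$kind == "continuous") next
    v <- as.character(dataset[[e$name]])
    bad <- which(!is.na(v) & !v %in% e$categories)
    if (length(bad)) {
      id <- if ("id" %in% names(dataset)) dataset$id[bad[1]] else bad[1]
      stop_invalid("record %s: illegal category '%s' for field '%s'",
                   id, v[bad[1]], e$name)
    }
  }

  keep <- complete.cases(dataset[, c(vars, "bll"), drop = FALSE])
  dat <- dataset[keep, , drop = FALSE]
  if (nrow(dat) == 0) stop_invalid("no complete cases")
  y <- classify_bll(dat$bll, threshold)
  if (length(unique(y)) < 2) {
    stop_invalid("single-class outcome: all BLLs on one side of %g µg/dL",
                 threshold)
  }

  cols <- list(); grp <- integer(0); cnames <- character(0)
  gnames <- character(0); g <- 0L
  for (e in codebook$entries) {
    if (e$kind == "continuous") {
      block <- matrix(as.numeric(dat[[e$name]]), ncol = 1)
      colnames(block) <- e$name
    } else {
      v <- factor(as.character(dat[[e$name]]), levels = e$categories)
      block <- vapply(e$categories[-1], function(cat) as.numeric(v == cat),
                      numeric(nrow(dat)))
      block <- matrix(block, nrow = nrow(dat))
      colnames(block) <- paste(e$name, e$categories[-1], sep = ".")
    }
    if (drop_unused) {
      used <- apply(block, 2, function(x) var(x) > 0)
      block <- block[, used, drop = FALSE]
      if (ncol(block) == 0) next
    }
    g <- g + 1L
    cols[[g]] <- block
    grp <- c(grp, rep(g, ncol(block)))
    cnames <- c(cnames, colnames(block))
    gnames <- c(gnames, e$name)
  }
  X <- do.call(cbind, cols)
  dimnames(X) <- list(NULL, cnames)
  df <- as.integer(table(factor(grp, levels = seq_len(g))))

  structure(list(y = y, X = X, group = grp, group_names = gnames,
                 df = df, rescale = sqrt(df), column_names = cnames,
                 n = nrow(X), p = ncol(X), G = g,
                 ids = if ("id" %in% names(dat)) dat$id else seq_len(nrow(dat)),
                 threshold = threshold,
                 standardized = FALSE, center = NULL, transform = NULL),
            class = "bll_encoded")
}

#' @export
print.bll_encoded <- function(x, ...) {
  cat(sprintf("Encoded dataset: n = %d complete cases, p = %d columns in %d groups\n",
              x$n, x$p, x$G))
  cat(sprintf("  elevated (BLL >= %g): %d (%.1f%%)%s\n", x$threshold,
              sum(x$y), 100 * mean(x$y),
              if (x$standardized) "; group-orthonormalized" else ""))
  invisible(x)
}

#' Encode a raw design matrix with explicit group structure
#'
#' Low-level constructor for users who already have a binary response and a
#' design matrix with a group layout, bypassing the survey semantics.
#'
#' @param X numeric design matrix.
#' @param y binary response (0/1) with both classes present.
#' @param group integer vector of per-column group labels; columns of a
#'   group must be contiguous and labels consecutive from 1.
#' @param group_names optional per-group names.
#' @return a `bll_encoded`.
#' @export
encode_matrix <- function(X, y, group, group_names = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), length(group) == ncol(X))
  if (!all(y %in% 0:1) || length(unique(y)) < 2) {
    stop_invalid("y must be binary with both classes present")
  }
  if (any(diff(group) < 0) || !all(group %in% seq_len(max(group)))) {
    stop_invalid("groups must be contiguous and numbered consecutively from 1")
  }
  G <- max(group)
  df <- as.integer(table(factor(group, levels = seq_len(G))))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  gn <- group_names %||% paste0("g", seq_len(G))
  structure(list(y = y, X = X, group = as.integer(group), group_names = gn,
                 df = df, rescale = sqrt(df), column_names = colnames(X),
                 n = nrow(X), p = ncol(X), G = G, ids = seq_len(nrow(X)),
                 threshold = NA_real_,
                 standardized = FALSE, center = NULL, transform = NULL),
            class = "bll_encoded")
}

#' Center and group-orthonormalize the design
#'
#' Columns are centered and every group block is transformed so that
#' `t(Z_g) %*% Z_g / n` is the identity. Under this parameterization the
#' group-descent update is an exact closed-form group soft-threshold. The
#' per-group affine transform is stored so fitted coefficients can be mapped
#' back to the original covariate scale exactly.
#'
#' @param encoded a `bll_encoded` object.
#' @return the encoded object with `X` replaced by the orthonormalized
#'   design and `center`/`transform` recorded.
#' @export
standardize_groups <- function(encoded) {
  stopifnot(inherits(encoded, "bll_encoded"))
  if (encoded$standardized) return(encoded)
  n <- encoded$n
  X <- encoded$X
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  transform <- vector("list", encoded$G)
  pattern <- vector("list", encoded$G)
  for (g in seq_len(encoded$G)) {
    j <- which(encoded$group == g)
    B <- Xc[, j, drop = FALSE]
    sv <- svd(B, nu = 0)
    if (min(sv$d) / sqrt(n) < 1e-8) {
      stop_invalid("group '%s' is rank-deficient after centering",
                   encoded$group_names[g])
    }
    Tg <- sv$v %*% diag(sqrt(n) / sv$d, length(sv$d))
    Xc[, j] <- B %*% Tg
    transform[[g]] <- Tg
    # dummy blocks take only k+1 distinct rows; record the category
    # pattern so the solver can work on per-category aggregates
    raw <- X[, j, drop = FALSE]
    k <- length(j)
    if (k + 1 <= 32 && all(raw %in% c(0, 1)) && all(rowSums(raw) <= 1)) {
      code <- as.integer(raw %*% seq_len(k))
      P <- (rbind(0, diag(k)) -
              matrix(center[j], k + 1, k, byrow = TRUE)) %*% Tg
      pattern[[g]] <- list(code = code, P = P)
    }
  }
  encoded$X <- Xc
  encoded$center <- center
  encoded$transform <- transform
  encoded$pattern <- pattern
  encoded$standardized <- TRUE
  encoded
}

# map (intercept, beta) fitted on the orthonormalized scale back to the
# original covariate scale; exact by construction
back_transform <- function(encoded, intercept, beta_std) {
  stopifnot(encoded$standardized)
  beta <- numeric(encoded$p)
  for (g in seq_len(encoded$G)) {
    j <- which(encoded$group == g)
    beta[j] <- encoded$transform[[g]] %*% beta_std[j]
  }
  names(beta) <- encoded$column_names
  list(intercept = intercept - sum(encoded$center * beta), beta = beta)
}
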