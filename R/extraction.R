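#' Fitted one-dimensional index models
#'
#' An `index_model` holds the result of extracting the first dimension from a
#' pooled design: the method (`pca`, `efa`, `mca`), the correlation kind it
#' was fit on, per-item loadings, the share of variance explained by the
#' first dimension, and the scoring parameters (pooled column means/SDs for
#' PCA/EFA; category masses, standard column coordinates and the first
#' singular value for MCA). Loadings are reported on the "standardized"
#' scale — eigenvector entries times the square root of the first eigenvalue
#' for PCA (so they are item-component correlations); the raw unit-norm
#' weight vector is kept alongside.
#'
#' @name index_model
NULL

new_index_model <- function(method, corr_kind, items, loadings, weights,
                            var_explained, lambda1, means, sds,
                            mca = NULL, reference = "electricity",
                            crowding_binary = FALSE,
                            ordinal_items = character()) {
  m <- structure(
    list(method = method, corr_kind = corr_kind, items = items,
         loadings = setNames(loadings, items),
         weights = setNames(weights, items),
         var_explained = var_explained, lambda1 = lambda1,
         means = means, sds = sds, mca = mca, reference = reference,
         crowding_binary = crowding_binary, ordinal_items = ordinal_items),
    class = "index_model")
  orient(m)
}

#' @export
print.index_model <- function(x, ...) {
  cat("<index_model> method = ", x$method, " (", x$corr_kind,
      "), ", length(x$items), " items, PC1 variance share = ",
      sprintf("%.3f", x$var_explained), "\n", sep = "")
  invisible(x)
}

#' @method tidy index_model
#' @export
tidy.index_model <- function(x, ...) {
  tibble::tibble(item = x$items,
                 loading = unname(x$loadings),
                 weight = unname(x$weights))
}

#' @method glance index_model
#' @export
glance.index_model <- function(x, ...) {
  tibble::tibble(method = x$method, corr_kind = x$corr_kind,
                 n_items = length(x$items),
                 lambda1 = x$lambda1,
                 var_explained = x$var_explained)
}

#' First-principal-component index (benchmark extraction)
#'
#' Extracts the leading eigenpair of a correlation matrix. Loadings are the
#' first eigenvector scaled by \eqn{\sqrt{\lambda_1}}; the variance share is
#' \eqn{\lambda_1 / p}. Scores computed from this model are the unit-norm
#' eigenvector applied to pooled z-scores, so on the fitting sample they have
#' mean 0 and standard deviation \eqn{\sqrt{\lambda_1}}.
#'
#' @param corr A `corr_matrix`.
#' @param means,sds Pooled scoring parameters (from the design the matrix was
#'   computed on).
#' @param ... Passed to the model constructor (orientation reference etc.).
#' @return An `index_model`.
#' @export
fit_pca <- function(corr, means = NULL, sds = NULL, ...) {
  R <- corr$R
  p <- ncol(R)
  if (p < 2) abort("need at least 2 items")
  e <- eigen(R, symmetric = TRUE)
  if (e$values[1] <= 0) abort("correlation matrix is not positive on PC1")
  v <- e$vectors[, 1]
  lambda1 <- e$values[1]
  new_index_model("pca", corr$kind, colnames(R),
                  loadings = v * sqrt(lambda1), weights = v,
                  var_explained = lambda1 / p, lambda1 = lambda1,
                  means = means, sds = sds, ...)
}

#' One-factor minres exploratory factor analysis
#'
#' Finds loadings \eqn{l} minimizing the sum of squared off-diagonal
#' residuals \eqn{\sum_{i<j}(r_{ij} - l_i l_j)^2}. With a single factor the
#' varimax rotation is the identity, so none is applied. Scores use the
#' regression method, \eqn{z R^{-1} l}. Heywood cases (communalities above 1)
#' are clipped to 0.995 and flagged via a warning.
#'
#' @inheritParams fit_pca
#' @param score_corr Correlation matrix of the *observed* scored columns used
#'   for the regression weights (defaults to `corr`). For polychoric fits the
#'   latent correlations overstate the near-collinearity of the observed 0/1
#'   columns, which makes \eqn{R^{-1} l} on the latent scale numerically
#'   explosive; passing the observed Pearson matrix keeps the projection on
#'   the scale of the data actually being scored.
#' @return An `index_model` with method `"efa"`.
#' @export
fit_efa_minres <- function(corr, means = NULL, sds = NULL,
                           score_corr = NULL, ...) {
  R <- corr$R
  p <- ncol(R)
  offdiag <- upper.tri(R)
  obj <- function(l) sum((R[offdiag] - tcrossprod(l)[offdiag])^2)
  grad <- function(l) {
    Rhat <- tcrossprod(l)
    D <- Rhat - R
    diag(D) <- 0
    2 * D %*% l
  }
  e <- eigen(R, symmetric = TRUE)
  start <- e$vectors[, 1] * sqrt(max(e$values[1], 0.1))
  fit <- optim(start, obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  l <- fit$par
  if (any(l^2 > 1)) {
    warn("Heywood case: communalities clipped to 0.995")
    l <- sign(l) * pmin(abs(l), sqrt(0.995))
  }
  # regression-method weights R^{-1} l, inverted on the spectrum with
  # smoothing-induced null directions (eigenvalues below 1e-3) truncated
  Rs <- if (is.null(score_corr)) R else score_corr$R[colnames(R), colnames(R)]
  ev <- eigen(Rs, symmetric = TRUE)
  keep <- ev$values > 1e-3
  V <- ev$vectors[, keep, drop = FALSE]
  w <- V %*% (crossprod(V, l) / ev$values[keep])
  new_index_model("efa", corr$kind, colnames(R),
                  loadings = l, weights = as.numeric(w),
                  var_explained = sum(l^2) / p, lambda1 = sum(l^2),
                  means = means, sds = sds, ...)
}

#' Multiple correspondence analysis index
#'
#' Correspondence analysis of the complete disjunctive (indicator) coding of
#' all-binary items: two indicator columns per item, correspondence matrix
#' \eqn{P = Z / n_{tot}}, standardized residuals
#' \eqn{S = D_r^{-1/2}(P - r c^\top) D_c^{-1/2}}, SVD of \eqn{S}. Household
#' scores are first-dimension row principal coordinates; item loadings are
#' the first-dimension principal coordinates of the level-1 (ownership)
#' categories. The reported variance share is the first principal inertia's
#' share of total inertia.
#'
#' @param design A `pooled_design` whose raw matrix is all-binary (pool with
#'   `crowding_binary = TRUE`).
#' @param ... Passed to the model constructor.
#' @return An `index_model` with method `"mca"`.
#' @export
fit_mca <- function(design, ...) {
  X <- design$X
  if (!all(X %in% c(0, 1))) {
    abort("MCA requires all-binary items (binarize crowding upstream)")
  }
  keep <- apply(X, 2, function(x) length(unique(x)) > 1)
  if (!all(keep)) {
    warn(paste0("dropping constant item(s) for MCA: ",
                paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X); n <- nrow(X)
  Zind <- matrix(0, n, 2 * p)
  Zind[, seq(1, 2 * p, 2)] <- 1 - X
  Zind[, seq(2, 2 * p, 2)] <- X
  colnames(Zind) <- paste0(rep(colnames(X), each = 2), c(":0", ":1"))
  tot <- sum(Zind)
  P <- Zind / tot
  r <- rowSums(P); cmass <- colSums(P)
  S <- (P - tcrossprod(r, cmass)) / sqrt(tcrossprod(r, cmass))
  sv <- svd(S)
  sigma1 <- sv$d[1]
  inertia <- sv$d^2
  # standard column coordinates on dim 1
  bstd <- sv$v[, 1] / sqrt(cmass)
  # principal coordinates of the level-1 categories = item loadings
  col_principal <- bstd * sigma1
  lev1 <- seq(2, 2 * p, 2)
  new_index_model("mca", "indicator", colnames(X),
                  loadings = col_principal[lev1],
                  weights = col_principal[lev1],
                  var_explained = inertia[1] / sum(inertia),
                  lambda1 = sigma1^2,
                  means = design$means[colnames(X)],
                  sds = design$sds[colnames(X)],
                  mca = list(bstd = bstd, cmass = cmass, p = p,
                             sigma1 = sigma1, categories = colnames(Zind)),
                  ...)
}

#' Orient an index model
#'
#' Flips the sign of the whole solution, if needed, so that the reference
#' item (default `electricity`) has a non-negative loading; if the reference
#' is absent or loads exactly zero, the majority-of-loadings-positive rule
#' decides. Idempotent; never forces every loading positive (a weakly
#' relevant item such as radio can legitimately load negative).
#'
#' @param model An `index_model`.
#' @return The oriented model.
#' @export
orient <- function(model) {
  ref <- model$reference
  ld <- if (!is.null(ref) && ref %in% names(model$loadings) &&
            model$loadings[[ref]] != 0) {
    model$loadings[[ref]]
  } else {
    sum(sign(model$loadings))
  }
  if (ld < 0) {
    model$loadings <- -model$loadings
    model$weights <- -model$weights
    if (!is.null(model$mca)) model$mca$bstd <- -model$mca$bstd
  }
  model
}

#' Score households with a fitted index model
#'
#' Applies the model's scoring rule to a design: for PCA/EFA, the stored
#' weight vector on columns standardized with the *model's* pooled
#' means/SDs (so out-of-sample records are scored on the fitting scale);
#' for MCA, the correspondence-analysis transition formula on the indicator
#' profile. Deterministic; identical households receive identical scores.
#'
#' @param model An `index_model`.
#' @param design A `pooled_design` containing every model item.
#' @return Tibble `household_id, wave, stratum, score`.
#' @export
score <- function(model, design) {
  miss <- setdiff(model$items, design$items)
  if (length(miss) > 0) {
    abort(paste0("design lacks model item(s): ", paste(miss, collapse = ", ")))
  }
  X <- design$X[, model$items, drop = FALSE]
  if (model$method == "mca") {
    p <- model$mca$p
    Zind <- matrix(0, nrow(X), 2 * p)
    Zind[, seq(1, 2 * p, 2)] <- 1 - X
    Zind[, seq(2, 2 * p, 2)] <- X
    profile <- Zind / p
    centered <- sweep(profile, 2, model$mca$cmass, "-")
    s <- as.numeric(centered %*% model$mca$bstd)
  } else {
    means <- model$means[model$items]
    sds <- model$sds[model$items]
    if (is.null(means) || is.null(sds)) {
      abort("model lacks scoring means/sds")
    }
    Z <- scale(X, center = means, scale = sds)
    s <- as.numeric(Z %*% model$weights[model$items])
  }
  dplyr::bind_cols(design$keys, tibble::tibble(score = s))
}
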