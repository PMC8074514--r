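toy_corr <- function(R, items = paste0("it", seq_len(ncol(R)))) {
  dimnames(R) <- list(items, items)
  harmindex:::new_corr_matrix(R, "pearson")
}

# single-factor binary design for cross-method comparisons
toy_factor_design <- function(n = 1500, lambdas = c(1.2, 1.0, 0.9, 0.8, 0.7,
                                                    0.6, 1.1, 0.95),
                              seed = 1) {
  set.seed(seed)
  w <- rnorm(n)
  X <- sapply(seq_along(lambdas), function(j) {
    as.numeric(lambdas[j] * w + rnorm(n) > runif(1, -0.8, 0.8))
  })
  colnames(X) <- paste0("it", seq_along(lambdas))
  means <- colMeans(X); sds <- apply(X, 2, sd)
  structure(list(Z = scale(X, means, sds), X = X,
                 keys = tibble::tibble(household_id = seq_len(n), wave = "w1",
                                       stratum = NA_character_),
                 items = colnames(X), means = means, sds = sds,
                 dropped = character(), n = n, waves = "w1"),
            class = "pooled_design")
}

test_that("PCA matches closed forms on structured matrices", {
  # 2 x 2: lambda1 = 1 + r, loadings proportional to (1,1)/sqrt(2)
  r <- 0.6
  m <- fit_pca(toy_corr(matrix(c(1, r, r, 1), 2)))
  expect_equal(m$lambda1, 1 + r, tolerance = 1e-12)
  expect_equal(unname(m$weights), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(m$var_explained, (1 + r) / 2, tolerance = 1e-12)
  expect_equal(unname(m$loadings), rep(sqrt(1 + r) / sqrt(2), 2),
               tolerance = 1e-12)

  # equicorrelation: variance explained (1 + (p-1) r) / p
  for (p in c(4, 7)) {
    for (r in c(0.2, 0.49)) {
      R <- matrix(r, p, p); diag(R) <- 1
      m <- fit_pca(toy_corr(R))
      expect_equal(m$var_explained, (1 + (p - 1) * r) / p, tolerance = 1e-12)
    }
  }
})

test_that("PCA eigenpair matches an independent power-iteration oracle", {
  m3 <- fit_pca(toy_corr(matrix(c(1, .5, .3, .5, 1, .2, .3, .2, 1), 3)))
  o3 <- power_iteration(matrix(c(1, .5, .3, .5, 1, .2, .3, .2, 1), 3))
  expect_equal(m3$lambda1, o3$value, tolerance = 1e-8)
  expect_equal(abs(unname(m3$weights)), abs(o3$vector), tolerance = 1e-8)

  set.seed(13)
  for (i in 1:5) {
    p <- sample(3:10, 1)
    A <- matrix(rnorm(p * 20), 20, p)
    R <- cor(A)
    m <- fit_pca(toy_corr(R))
    o <- power_iteration(R)
    expect_equal(m$lambda1, o$value, tolerance = 1e-8)
    expect_equal(abs(unname(m$weights)), abs(o$vector), tolerance = 1e-8)
  }
})

test_that("scores are centred with SD sqrt(lambda1) on the fitting sample", {
  d <- toy_factor_design(seed = 2)
  m <- fit_pca(pearson_matrix(d), means = d$means, sds = d$sds)
  s <- score(m, d)
  expect_equal(mean(s$score), 0, tolerance = 1e-8)
  expect_equal(sd(s$score), sqrt(m$lambda1), tolerance = 1e-6)
  # identical rows score identically
  i <- which(apply(d$X, 1, paste, collapse = "") ==
               apply(d$X, 1, paste, collapse = "")[1])
  expect_length(unique(round(s$score[i], 12)), 1)
  # missing model item rejected
  d2 <- d; d2$items <- d2$items[-1]
  d2$X <- d2$X[, -1]; d2$Z <- d2$Z[, -1]
  expect_error(score(m, d2), "lacks model item")
})

test_that("PCA is invariant to row order and sample duplication", {
  d <- toy_factor_design(n = 500, seed = 3)
  m <- fit_pca(pearson_matrix(d), means = d$means, sds = d$sds)
  ddup <- d
  ddup$X <- rbind(d$X, d$X); ddup$Z <- rbind(d$Z, d$Z)
  ddup$keys <- dplyr::bind_rows(d$keys, d$keys)
  ddup$n <- 2 * d$n
  mdup <- fit_pca(pearson_matrix(ddup), means = ddup$means, sds = ddup$sds)
  expect_equal(m$loadings, mdup$loadings, tolerance = 1e-10)
})

test_that("minres EFA recovers a constructed one-factor structure", {
  l <- c(0.8, 0.7, 0.6, 0.5)
  R <- tcrossprod(l); diag(R) <- 1
  m <- fit_efa_minres(toy_corr(R))
  expect_equal(unname(m$loadings), l, tolerance = 1e-4)

  # equicorrelation 0.49 with 4 items: l = 0.7 for all
  R2 <- matrix(0.49, 4, 4); diag(R2) <- 1
  m2 <- fit_efa_minres(toy_corr(R2))
  expect_equal(unname(m2$loadings), rep(0.7, 4), tolerance = 1e-6)
})

test_that("EFA and PCA scores agree on single-factor data across seeds", {
  for (seed in 1:20) {
    d <- toy_factor_design(n = 800, seed = seed)
    cm <- pearson_matrix(d)
    sp <- score(fit_pca(cm, means = d$means, sds = d$sds), d)
    se <- score(fit_efa_minres(cm, means = d$means, sds = d$sds), d)
    expect_gte(spearman_rho(sp$score, se$score), 0.99)
  }
})

test_that("MCA first dimension matches a dense SVD oracle", {
  set.seed(51)
  d <- toy_factor_design(n = 50, lambdas = rep(c(1.1, 0.8), 5), seed = 51)
  m <- fit_mca(d)
  # oracle: direct CA of the indicator matrix with base svd
  X <- d$X; p <- ncol(X)
  Zind <- matrix(0, nrow(X), 2 * p)
  Zind[, seq(1, 2 * p, 2)] <- 1 - X
  Zind[, seq(2, 2 * p, 2)] <- X
  P <- Zind / sum(Zind)
  r <- rowSums(P); cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  expect_equal(m$mca$sigma1, sv$d[1], tolerance = 1e-8)
  f_oracle <- (1 / sqrt(r)) * sv$u[, 1] * sv$d[1]
  s <- score(m, d)
  expect_equal(abs(s$score), abs(f_oracle), tolerance = 1e-8)
})

test_that("MCA scores are mass-invariant and track PCA on binary data", {
  d <- toy_factor_design(n = 600, seed = 52)
  m <- fit_mca(d)
  s1 <- score(m, d)
  ddup <- d
  ddup$X <- rbind(d$X, d$X); ddup$Z <- rbind(d$Z, d$Z)
  ddup$keys <- dplyr::bind_rows(d$keys, d$keys); ddup$n <- 2 * d$n
  mdup <- fit_mca(ddup)
  s2 <- score(mdup, ddup)
  expect_equal(abs(s2$score[seq_len(d$n)]), abs(s1$score), tolerance = 1e-10)

  sp <- score(fit_pca(pearson_matrix(d), means = d$means, sds = d$sds), d)
  expect_gte(abs(spearman_rho(s1$score, sp$score)), 0.99)
})

test_that("orientation follows the reference and is idempotent", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  dimnames(R) <- list(c("a", "b", "electricity"), c("a", "b", "electricity"))
  m <- fit_pca(harmindex:::new_corr_matrix(R, "pearson"))
  expect_gte(m$loadings[["electricity"]], 0)
  flipped <- m
  flipped$loadings <- -flipped$loadings
  flipped$weights <- -flipped$weights
  back <- orient(flipped)
  expect_equal(back$loadings, m$loadings)
  expect_equal(orient(back), back)
  # majority rule without a reference item
  m2 <- m; names(m2$loadings) <- names(m2$weights) <- c("a", "b", "c")
  m2$items <- c("a", "b", "c")
  m2$loadings <- -abs(m2$loadings); m2$weights <- -abs(m2$weights)
  expect_true(all(orient(m2)$loadings > 0))
})
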