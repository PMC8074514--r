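test_that("bivariate normal CDF matches closed form and quadrature", {
  # closed form at the origin: Phi2(0,0,rho) = 1/4 + asin(rho)/(2*pi)
  for (rho in c(-0.95, -0.5, 0, 0.3, 0.7, 0.925, 0.99)) {
    expect_equal(pbvnorm(0, 0, rho), 0.25 + asin(rho) / (2 * pi),
                 tolerance = 1e-7)
  }
  # independent case factorizes
  expect_equal(pbvnorm(0.7, -0.3, 0), pnorm(0.7) * pnorm(-0.3),
               tolerance = 1e-12)
  # against the independent trapezoid quadrature oracle
  set.seed(11)
  for (i in 1:20) {
    h <- runif(1, -2, 2); k <- runif(1, -2, 2); r <- runif(1, -0.98, 0.98)
    expect_lt(abs(pbvnorm(h, k, r) - num_bvn_lower(h, k, r, n = 4000)), 1e-6)
  }
  # perfect dependence limits
  expect_equal(pbvnorm(0.5, 1.2, 1), pnorm(0.5), tolerance = 1e-9)
  expect_equal(pbvnorm(0.5, -0.2, -1), pnorm(0.5) - pnorm(0.2),
               tolerance = 1e-9)
})

test_that("pearson matrix handles the elementary cases", {
  x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)
  d <- list(Z = scale(cbind(a = x, b = 1 - x, c = y)))
  class(d) <- "pooled_design"
  R <- pearson_matrix(d)$R
  expect_equal(R["a", "b"], -1)
  expect_equal(R["a", "c"], 0)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
})

test_that("tetrachoric MLE agrees with the grid-search oracle", {
  expect_equal(tetrachoric_rho(matrix(c(25, 25, 25, 25), 2)), 0,
               tolerance = 1e-6)
  tabs <- list(matrix(c(40, 10, 10, 40), 2),
               matrix(c(30, 5, 20, 45), 2),
               matrix(c(10, 40, 35, 15), 2))
  for (tab in tabs) {
    rho_hat <- tetrachoric_rho(tab)
    rho_grid <- grid_tetrachoric(tab)
    expect_equal(rho_hat, rho_grid, tolerance = 1e-3)
  }
})

test_that("degenerate concordant tables need the continuity correction", {
  tab <- matrix(c(50, 0, 0, 50), 2)
  expect_error(tetrachoric_rho(tab), "continuity")
  rho <- tetrachoric_rho(tab, correct = TRUE)
  expect_gt(rho, 0.95)
  expect_lte(abs(rho), 0.999)
})

test_that("tetrachoric is antisymmetric under label swap", {
  set.seed(21)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(tetrachoric_rho(tab[, 2:1]), -tetrachoric_rho(tab),
                 tolerance = 1e-4)
  }
})

test_that("tetrachoric recovers latent rho where Pearson attenuates", {
  set.seed(31)
  n <- 50000
  rho <- 0.6
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  x <- as.numeric(z1 > 0.6); y <- as.numeric(z2 > -0.3)
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  rho_hat <- tetrachoric_rho(unclass(tab))
  expect_equal(rho_hat, rho, tolerance = 0.03)
  expect_lt(abs(cor(x, y)), abs(rho_hat))
})

test_that("polychoric reduces to tetrachoric and recovers simulated rho", {
  tab <- matrix(c(40, 10, 10, 40), 2)
  expect_equal(polychoric_rho(tab), tetrachoric_rho(tab), tolerance = 1e-9)

  # independence in a 3x3
  tab3 <- matrix(rep(30, 9), 3)
  expect_equal(polychoric_rho(tab3), 0, tolerance = 1e-6)

  # discretized bivariate normal draws at known thresholds, true rho = 0.5
  set.seed(41)
  n <- 1e6
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  cut1 <- c(-0.5, 0.8); cut2 <- c(-0.2, 1.0)
  a <- findInterval(z1, cut1); b <- findInterval(z2, cut2)
  rho_hat <- polychoric_rho(table(a, b))
  expect_equal(rho_hat, 0.5, tolerance = 0.01)
})

test_that("empty marginal categories are merged with a warning", {
  tab <- matrix(c(20, 0, 15, 10, 0, 12, 5, 0, 30), 3)
  expect_warning(r <- polychoric_rho(tab), "merged")
  expect_true(is.finite(r))
})

test_that("polychoric matrix is pairwise-tetrachoric and PSD across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 400
    w <- rnorm(n)
    X <- sapply(c(0.8, 1.0, 1.2, 0.9), function(l) {
      as.numeric(l * w + rnorm(n) > runif(1, -0.5, 0.5))
    })
    colnames(X) <- paste0("it", 1:4)
    cm <- polychoric_matrix(X)
    expect_false(cm$smoothed)
    expect_gte(min(eigen(cm$R, symmetric = TRUE)$values), -1e-8)
    # spot-check one pair against the scalar estimator
    tab <- table(factor(X[, 1], levels = 0:1), factor(X[, 2], levels = 0:1))
    if (all(tab > 0)) {
      expect_equal(cm$R[1, 2], polychoric_rho(unclass(tab)),
                   tolerance = 1e-8)
    }
  }
})

test_that("indefinite pairwise matrices are smoothed to PSD, unit diagonal", {
  R <- matrix(c(1, 0.95, -0.9, 0.95, 1, 0.9, -0.9, 0.9, 1), 3)
  sm <- harmindex:::smooth_psd(R)
  expect_true(sm$smoothed)
  expect_gte(min(eigen(sm$R, symmetric = TRUE)$values), 0)
  expect_equal(diag(sm$R), rep(1, 3))
  expect_true(all(abs(sm$R) <= 1 + 1e-12))
})
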