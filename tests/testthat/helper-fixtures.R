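# Small in-code fixtures and independent oracles used across the suite.

mini_codebook <- function() {
  yn <- c("0" = 0, "1" = 1, no = 0, yes = 1)
  f3b <- setNames(c(0, 0, 1, 0, 0, 1), c("dirt", "cement", "tile", "0", "1", "2"))
  f3o <- setNames(c(0, 1, 2, 0, 1, 2), c("dirt", "cement", "tile", "0", "1", "2"))
  items <- tibble::tibble(
    item = c("radio", "automobile", "floor", "electricity", "rooms_per_member"),
    kind = c("asset", "asset", "housing", "housing", "crowding"),
    availability = list(c("w1", "w2", "w3"), c("w2", "w3"),
                        c("w1", "w2", "w3"), c("w1", "w2", "w3"),
                        c("w1", "w2", "w3")),
    binary_recode = list(yn, yn, f3b, yn, NULL),
    ordinal_recode = list(NULL, NULL, f3o, NULL, NULL),
    impute_zero_waves = list(character(), "w1", character(), character(),
                             character()))
  codebook(items, c("w1", "w2", "w3"))
}

# random valid mini panel on the mini codebook, with a single latent wealth
# factor so extraction methods have real structure; automobile not asked in w1
random_mini_panel <- function(n = 20, seed = 1) {
  set.seed(seed)
  mu <- c(w1 = -0.5, w2 = 0, w3 = 0.5)
  lam <- c(radio = 0.5, automobile = 0.9, electricity = 1.1)
  rows <- list()
  for (t in names(mu)) {
    w <- mu[[t]] + rnorm(n)
    for (it in names(lam)) {
      if (it == "automobile" && t == "w1") {
        rows[[length(rows) + 1]] <- tibble::tibble(
          household_id = seq_len(n), wave = t, item = it,
          value = NA_real_, ordinal = NA_real_, missing = "not_asked")
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          household_id = seq_len(n), wave = t, item = it,
          value = as.numeric(lam[[it]] * w + rnorm(n) > runif(1, -0.5, 0.5)),
          ordinal = NA_real_, missing = "observed")
      }
    }
    y <- w + rnorm(n)
    ordv <- as.numeric(y > -0.3) + as.numeric(y > 0.5)
    rows[[length(rows) + 1]] <- tibble::tibble(
      household_id = seq_len(n), wave = t, item = "floor",
      value = as.numeric(ordv == 2), ordinal = ordv, missing = "observed")
    rows[[length(rows) + 1]] <- tibble::tibble(
      household_id = seq_len(n), wave = t, item = "rooms_per_member",
      value = round(pmax(0.1, 0.8 + 0.25 * w + rnorm(n, 0, 0.2)), 3),
      ordinal = NA_real_, missing = "observed")
  }
  out <- dplyr::bind_rows(rows)
  out$stratum <- NA_character_
  as_asset_panel(out, waves = c("w1", "w2", "w3"))
}

# ---- independent oracles -------------------------------------------------

# leading eigenpair by plain power iteration (no eigen())
power_iteration <- function(A, iters = 5000, tol = 1e-14) {
  v <- rep(1, ncol(A)) / sqrt(ncol(A))
  lambda <- 0
  for (i in seq_len(iters)) {
    v2 <- A %*% v
    lambda2 <- sqrt(sum(v2^2))
    v2 <- as.numeric(v2 / lambda2)
    if (max(abs(abs(v2) - abs(v))) < tol) {
      v <- v2; lambda <- lambda2; break
    }
    v <- v2; lambda <- lambda2
  }
  list(value = lambda, vector = v)
}

# grid-search tetrachoric MLE with rectangle probabilities from numerical
# integration of the bivariate normal density (independent of pbvnorm)
num_bvn_lower <- function(h, k, rho, n = 200) {
  # integrate P(X<=h, Y<=k) = int_{-inf}^{h} phi(x) Phi((k - rho x)/sqrt(1-rho^2)) dx
  lo <- -8
  if (h <= lo) return(0)
  xs <- seq(lo, h, length.out = n + 1)
  fx <- stats::dnorm(xs) * stats::pnorm((k - rho * xs) / sqrt(1 - rho^2))
  sum((fx[-1] + fx[-length(fx)]) / 2 * diff(xs))
}

grid_tetrachoric <- function(tab, step = 1e-3) {
  n <- sum(tab)
  h <- stats::qnorm(rowSums(tab)[1] / n)
  k <- stats::qnorm(colSums(tab)[1] / n)
  grid <- seq(-0.995, 0.995, by = step)
  ll <- vapply(grid, function(r) {
    p11 <- num_bvn_lower(h, k, r)
    p <- c(p11, stats::pnorm(h) - p11, stats::pnorm(k) - p11,
           1 - stats::pnorm(h) - stats::pnorm(k) + p11)
    p <- pmax(p, 1e-12)
    sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(p))
  }, numeric(1))
  grid[which.max(ll)]
}

# brute-force Spearman: average ranks then the Pearson formula by hand
brute_spearman <- function(x, y) {
  rk <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    })
  }
  a <- rk(x); b <- rk(y)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# KMO for a 3x3 correlation matrix via explicit cofactor inversion
kmo3_cofactor <- function(R) {
  stopifnot(all(dim(R) == c(3, 3)))
  detR <- R[1, 1] * (R[2, 2] * R[3, 3] - R[2, 3] * R[3, 2]) -
    R[1, 2] * (R[2, 1] * R[3, 3] - R[2, 3] * R[3, 1]) +
    R[1, 3] * (R[2, 1] * R[3, 2] - R[2, 2] * R[3, 1])
  cof <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    minor <- R[-i, -j]
    cof[i, j] <- (-1)^(i + j) * (minor[1, 1] * minor[2, 2] -
                                   minor[1, 2] * minor[2, 1])
  }
  S <- t(cof) / detR
  Q <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) Q[i, j] <- -S[i, j] / sqrt(S[i, i] * S[j, j])
  num <- sum(R[upper.tri(R)]^2)
  den <- num + sum(Q[upper.tri(Q)]^2)
  num / den
}

# default simulated cohort shared by the slower tests (cached per session)
cached_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$panel)) {
      env$spec <- default_cohort_spec()
      env$panel <- simulate_panel(env$spec)
      env$cb <- default_codebook(extended = TRUE)
      env$bench <- harmonized_index(env$panel, env$cb)
    }
    list(spec = env$spec, panel = env$panel, cb = env$cb, bench = env$bench)
  }
})
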