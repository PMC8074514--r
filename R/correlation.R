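#' Standard bivariate normal CDF
#'
#' \eqn{P(X \le h, Y \le k)} for standard bivariate normal (X, Y) with
#' correlation `rho`, computed with the Drezner–Wesolowsky/Genz hybrid
#' quadrature (Gauss–Legendre on the arcsine-transformed correlation for
#' moderate \eqn{|\rho|}, the tail-stable transformed integrand for
#' \eqn{|\rho| > 0.925}); absolute error below 1e-7.
#'
#' @param h,k Upper limits (scalars).
#' @param rho Correlation in \[-1, 1\].
#' @return A probability.
#' @export
pbvnorm <- function(h, k, rho) {
  if (!is.finite(rho) || abs(rho) > 1) abort("rho must lie in [-1, 1]")
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(pnorm(k))
    if (k == Inf) return(pnorm(h))
  }
  # bvnd computes P(X > dh, Y > dk)
  bvnd(-h, -k, rho)
}

gl_nodes <- list(
  w3 = c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
  x3 = c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970),
  w6 = c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
         0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
  x6 = c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
         0.5873179542866171, 0.3678314989981802, 0.1252334085114692),
  w10 = c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
          0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
          0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
          0.1527533871307259),
  x10 = c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
          0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
          0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
          0.07652652113349733))

bvnd <- function(dh, dk, r) {
  if (abs(r) < 0.3) { w <- gl_nodes$w3; xg <- gl_nodes$x3 }
  else if (abs(r) < 0.75) { w <- gl_nodes$w6; xg <- gl_nodes$x6 }
  else { w <- gl_nodes$w10; xg <- gl_nodes$x10 }
  h <- dh; k <- dk; hk <- h * k; bvn <- 0
  if (abs(r) < 0.925) {
    if (abs(r) > 0) {
      hs <- (h * h + k * k) / 2
      asr <- asin(r)
      for (i in seq_along(w)) {
        for (is in c(-1, 1)) {
          sn <- sin(asr * (is * xg[i] + 1) / 2)
          bvn <- bvn + w[i] * exp((sn * hk - hs) / (1 - sn * sn))
        }
      }
      bvn <- bvn * asr / (4 * pi)
    }
    bvn <- bvn + pnorm(-h) * pnorm(-k)
  } else {
    if (r < 0) { k <- -k; hk <- -hk }
    if (abs(r) < 1) {
      as_ <- (1 - r) * (1 + r); a <- sqrt(as_)
      bs <- (h - k)^2; cc <- (4 - hk) / 8; d <- (12 - hk) / 16
      asr <- -(bs / as_ + hk) / 2
      if (asr > -100) {
        bvn <- a * exp(asr) *
          (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 + cc * d * as_ * as_ / 5)
      }
      if (-hk < 100) {
        b <- sqrt(bs)
        sp <- sqrt(2 * pi) * pnorm(-b / a)
        bvn <- bvn - exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - d * bs / 5) / 3)
      }
      a <- a / 2
      for (i in seq_along(w)) {
        for (is in c(-1, 1)) {
          xs <- (a * (is * xg[i] + 1))^2
          rs <- sqrt(1 - xs)
          asr <- -(bs / xs + hk) / 2
          if (asr > -100) {
            sp <- 1 + cc * xs * (1 + d * xs)
            ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
            bvn <- bvn + a * w[i] * exp(asr) * (ep - sp)
          }
        }
      }
      bvn <- -bvn / (2 * pi)
    }
    if (r > 0) {
      bvn <- bvn + pnorm(-max(h, k))
    } else {
      bvn <- -bvn
      if (k > h) bvn <- bvn + pnorm(k) - pnorm(h)
    }
  }
  max(0, min(1, bvn))
}

new_corr_matrix <- function(R, kind, thresholds = NULL, smoothed = FALSE,
                            corrected_pairs = NULL) {
  stopifnot(isSymmetric(unname(R)))
  structure(list(R = R, items = colnames(R), kind = kind,
                 thresholds = thresholds, smoothed = smoothed,
                 corrected_pairs = corrected_pairs),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("<corr_matrix> ", x$kind, ", ", ncol(x$R), " items",
      if (isTRUE(x$smoothed)) ", PSD-smoothed", "\n", sep = "")
  invisible(x)
}

#' Pearson correlation matrix of a pooled design
#'
#' Product-moment correlations of the (mixed binary/continuous) pooled
#' columns — the correlation matrix behind the benchmark index.
#'
#' @param design A `pooled_design`.
#' @return A `corr_matrix` of kind `"pearson"`.
#' @export
pearson_matrix <- function(design) {
  Z <- design$Z
  if (ncol(Z) < 2) abort("need at least 2 columns")
  if (any(apply(Z, 2, sd) == 0)) abort("constant column reached pearson_matrix")
  R <- cor(Z)
  new_corr_matrix(R, "pearson")
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Two-step maximum likelihood: thresholds are the normal quantiles of the
#' marginal proportions; the latent correlation maximizes the multinomial
#' likelihood with cell probabilities given by bivariate-normal rectangle
#' probabilities. The estimate is capped at \eqn{|\rho| \le 0.999}.
#'
#' @param tab 2x2 count table; rows index the first variable's levels (0, 1),
#'   columns the second's.
#' @param correct Apply a +0.5 continuity correction to all cells when a cell
#'   is zero? Without it, zero margins or cells raise an error.
#' @return Scalar correlation estimate.
#' @export
tetrachoric_rho <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab == 0)) {
    if (!correct) {
      abort(paste0("zero cell(s) in 2x2 table; rerun with correct = TRUE ",
                   "for a +0.5 continuity correction"))
    }
    tab <- tab + 0.5
  }
  if (any(rowSums(tab) <= 0) || any(colSums(tab) <= 0)) {
    abort("all margins must be positive")
  }
  polychoric_rho(tab)
}

#' Polychoric correlation from an RxC table (R, C in 2..3)
#'
#' Thresholds from cumulative marginal proportions via the normal quantile
#' function; the correlation by 1-D likelihood maximization over
#' bivariate-normal rectangle probabilities. Empty marginal categories are
#' merged into their lower neighbour with a warning. Reduces to
#' [tetrachoric_rho()] for 2x2 input.
#'
#' @param tab Count table with 2 or 3 rows/columns, levels in increasing
#'   order.
#' @return Scalar correlation estimate, capped at 0.999 in magnitude.
#' @export
polychoric_rho <- function(tab) {
  tab <- as.matrix(tab)
  tab <- drop_empty_margins(tab)
  n <- sum(tab)
  rr <- nrow(tab); cc <- ncol(tab)
  if (rr < 2 || cc < 2) abort("table degenerate after dropping empty categories")
  # thresholds: K-1 interior cut points per margin
  a <- qnorm(cumsum(rowSums(tab))[-rr] / n)
  b <- qnorm(cumsum(colSums(tab))[-cc] / n)
  nll <- function(rho) {
    P <- rect_probs(a, b, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6)
  # guard against a boundary-adjacent local issue by checking the endpoints
  cand <- c(opt$minimum, -0.999, 0.999)
  cand[which.min(vapply(cand, nll, numeric(1)))]
}

drop_empty_margins <- function(tab) {
  repeat {
    r0 <- which(rowSums(tab) == 0)
    c0 <- which(colSums(tab) == 0)
    if (length(r0) == 0 && length(c0) == 0) return(tab)
    warn("empty marginal category dropped (merged with neighbour)")
    if (length(r0) > 0) tab <- tab[-r0[1], , drop = FALSE]
    else tab <- tab[, -c0[1], drop = FALSE]
  }
}

# rectangle probabilities for thresholds a (rows), b (cols) at correlation rho
rect_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf); bb <- c(-Inf, b, Inf)
  R <- length(aa) - 1; C <- length(bb) - 1
  Phi <- matrix(0, R + 1, C + 1)
  for (i in seq_len(R + 1)) {
    for (j in seq_len(C + 1)) {
      Phi[i, j] <- pbvnorm(aa[i], bb[j], rho)
    }
  }
  P <- matrix(0, R, C)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      P[i, j] <- Phi[i + 1, j + 1] - Phi[i, j + 1] - Phi[i + 1, j] + Phi[i, j]
    }
  }
  P
}

#' Pairwise polychoric correlation matrix
#'
#' Tetrachoric/polychoric correlations for every pair of categorical columns
#' (binary or 3-level; crowding must be binarized upstream). Pairs with zero
#' cells receive a +0.5 continuity correction and are flagged. If the
#' assembled matrix is indefinite it is eigenvalue-smoothed (negative
#' eigenvalues clipped to 1e-8, diagonal renormalized) and flagged.
#'
#' @param X Matrix/data frame of categorical columns coded 0/1(/2).
#' @return A `corr_matrix` of kind `"polychoric"`.
#' @export
polychoric_matrix <- function(X) {
  if (inherits(X, "pooled_design")) X <- X$X
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) abort("need at least 2 columns")
  if (!all(X %in% c(0, 1, 2))) abort("columns must be coded 0/1(/2)")
  R <- diag(1, p)
  corrected <- character()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tab <- table(factor(X[, i], levels = sort(unique(X[, i]))),
                   factor(X[, j], levels = sort(unique(X[, j]))))
      if (any(tab == 0)) {
        tab <- tab + 0.5
        corrected <- c(corrected,
                       paste(colnames(X)[i], colnames(X)[j], sep = ":"))
      }
      R[i, j] <- R[j, i] <- polychoric_rho(tab)
    }
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  sm <- smooth_psd(R)
  thr <- lapply(seq_len(p), function(i) {
    tabi <- table(X[, i])
    qnorm(cumsum(tabi)[-length(tabi)] / sum(tabi))
  })
  names(thr) <- colnames(X)
  new_corr_matrix(sm$R, "polychoric", thresholds = thr,
                  smoothed = sm$smoothed,
                  corrected_pairs = if (length(corrected)) corrected)
}

# clip negative eigenvalues and renormalize to unit diagonal
smooth_psd <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol) return(list(R = R, smoothed = FALSE))
  v <- pmax(e$values, tol)
  Rs <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(Rs))
  Rs <- Rs / tcrossprod(d)
  diag(Rs) <- 1
  dimnames(Rs) <- dimnames(R)
  list(R = (Rs + t(Rs)) / 2, smoothed = TRUE)
}
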