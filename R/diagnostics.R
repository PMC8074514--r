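#' Standardized Cronbach's alpha
#'
#' \eqn{\alpha = k\bar r / (1 + (k-1)\bar r)} with \eqn{\bar r} the mean
#' off-diagonal Pearson correlation — the raw alpha of z-scored items.
#'
#' @param x A `pooled_design`, `corr_matrix`, or correlation matrix.
#' @return Scalar alpha (at most 1).
#' @export
cronbach_alpha <- function(x) {
  R <- as_R(x)
  k <- ncol(R)
  if (k < 2) abort("need at least 2 items")
  rbar <- mean(R[upper.tri(R)])
  k * rbar / (1 + (k - 1) * rbar)
}

as_R <- function(x) {
  if (inherits(x, "pooled_design")) return(cor(x$Z))
  if (inherits(x, "corr_matrix")) return(x$R)
  as.matrix(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' \eqn{KMO = \sum_{i \ne j} r_{ij}^2 / (\sum_{i \ne j} r_{ij}^2 +
#' \sum_{i \ne j} q_{ij}^2)}, where the \eqn{q_{ij}} are anti-image partial
#' correlations obtained from the inverse correlation matrix,
#' \eqn{q_{ij} = -s_{ij}/\sqrt{s_{ii} s_{jj}}} with \eqn{S = R^{-1}}.
#' A singular matrix gets a 1e-8 ridge (flagged with a warning).
#'
#' @param x A `pooled_design`, `corr_matrix`, or correlation matrix.
#' @return Scalar in \[0, 1\].
#' @export
kmo <- function(x) {
  R <- as_R(x)
  S <- tryCatch(solve(R), error = function(e) {
    warn("singular correlation matrix: ridge 1e-8 added for KMO")
    solve(R + diag(1e-8, ncol(R)))
  })
  d <- sqrt(diag(S))
  Q <- -S / tcrossprod(d)
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Clumping statistics for one wave's scores
#'
#' A quantitative proxy for the histogram-based clumping assessment:
#' `modal_share` is the fraction of households at the single most frequent
#' score value (after rounding to 1e-9, so algebraically identical scores
#' coincide), and `distinct_ratio` the number of distinct values divided by
#' n. Limited item variation in a wave (e.g. few owned assets in early
#' waves) shows up as a high modal share and low distinct ratio.
#'
#' @param scores Numeric vector of index scores for one wave.
#' @return Tibble with `modal_share`, `distinct_ratio`, `n`.
#' @export
clumping <- function(scores) {
  n <- length(scores)
  if (n < 1) abort("need at least one score")
  r <- round(scores / 1e-9) * 1e-9
  tab <- table(r)
  tibble::tibble(modal_share = max(tab) / n,
                 distinct_ratio = length(tab) / n,
                 n = n)
}

#' Truncation statistics for one wave's scores
#'
#' Shares of the wave's households lying within 1% of the pooled score range
#' of the pooled minimum (`lower_share`) and maximum (`upper_share`) — a
#' proxy for the index failing to differentiate households at the extremes.
#'
#' @param scores Numeric vector of one wave's scores.
#' @param pooled_min,pooled_max Pooled score range.
#' @param eps Boundary band as a fraction of the pooled range.
#' @return Tibble with `lower_share`, `upper_share`, `n`.
#' @export
truncation <- function(scores, pooled_min, pooled_max, eps = 0.01) {
  rng <- pooled_max - pooled_min
  if (!is.finite(rng) || rng <= 0) abort("pooled range must be positive")
  band <- eps * rng
  tibble::tibble(lower_share = mean(scores <= pooled_min + band),
                 upper_share = mean(scores >= pooled_max - band),
                 n = length(scores))
}

#' Per-wave summaries of index scores
#'
#' n, mean, SD, median, quartiles (type-7 linear interpolation) and range of
#' the index by wave, in chronological order.
#'
#' @param scores Tibble with `wave` and `score` columns (as from [score()]).
#' @param waves Chronological wave labels (default: order of appearance).
#' @return Tibble, one row per non-empty wave.
#' @export
wave_summaries <- function(scores, waves = NULL) {
  waves <- waves %||% unique(scores$wave)
  empty <- setdiff(waves, unique(scores$wave))
  if (length(empty) > 0) {
    warn(paste0("no scores for wave(s): ", paste(empty, collapse = ", ")))
  }
  scores |>
    dplyr::filter(.data$wave %in% waves) |>
    dplyr::group_by(wave = factor(.data$wave, levels = waves)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$score),
      sd = sd(.data$score),
      median = median(.data$score),
      q25 = quantile(.data$score, 0.25, names = FALSE, type = 7),
      q75 = quantile(.data$score, 0.75, names = FALSE, type = 7),
      min = min(.data$score),
      max = max(.data$score),
      .groups = "drop") |>
    dplyr::mutate(wave = as.character(.data$wave))
}

#' External-validity correlation with a household-linked measure
#'
#' Pearson correlation between an external measure (e.g. parental or
#' attained schooling) and the index score at the earliest (or latest) wave
#' at which each household is observed — the wave "closest" to the life
#' stage the measure refers to.
#'
#' @param scores Tibble `household_id, wave, score`.
#' @param external Tibble `household_id, value`.
#' @param pairing `"earliest"` or `"latest"` observed wave per household.
#' @param waves Chronological wave labels (default: panel order in `scores`).
#' @return Tibble with `r` and `n`.
#' @export
external_validity <- function(scores, external,
                              pairing = c("earliest", "latest"),
                              waves = NULL) {
  pairing <- match.arg(pairing)
  waves <- waves %||% unique(scores$wave)
  sc <- scores |>
    dplyr::mutate(wave_i = match(.data$wave, waves)) |>
    dplyr::group_by(.data$household_id) |>
    dplyr::slice(if (pairing == "earliest") which.min(.data$wave_i) else
      which.max(.data$wave_i)) |>
    dplyr::ungroup()
  merged <- dplyr::inner_join(sc, external, by = "household_id") |>
    dplyr::filter(is.finite(.data$score), is.finite(.data$value))
  if (nrow(merged) < 3) abort("fewer than 3 complete score/measure pairs")
  tibble::tibble(r = cor(merged$score, merged$value), n = nrow(merged))
}

#' Full diagnostics report for a fitted index
#'
#' Cronbach's alpha and KMO on the pooled design, the first component's
#' variance share, and per-wave clumping and truncation statistics.
#'
#' @param model An `index_model`.
#' @param design The `pooled_design` it was fitted on.
#' @param scores Scores from [score()] (computed if omitted).
#' @return List of class `index_diagnostics` with elements `alpha`, `kmo`,
#'   `var_explained` and a per-wave `shape` tibble.
#' @export
diagnostics <- function(model, design, scores = NULL) {
  scores <- scores %||% score(model, design)
  pooled_min <- min(scores$score); pooled_max <- max(scores$score)
  shape <- scores |>
    dplyr::group_split(factor(.data$wave, levels = unique(.data$wave))) |>
    purrr::map_dfr(function(sw) {
      dplyr::bind_cols(tibble::tibble(wave = sw$wave[1]),
                       clumping(sw$score)[c("modal_share", "distinct_ratio")],
                       truncation(sw$score, pooled_min,
                                  pooled_max)[c("lower_share", "upper_share")],
                       tibble::tibble(n = nrow(sw)))
    })
  structure(list(alpha = cronbach_alpha(design), kmo = kmo(pearson_matrix(design)),
                 var_explained = model$var_explained, shape = shape),
            class = "index_diagnostics")
}

#' @export
print.index_diagnostics <- function(x, ...) {
  cat("<index_diagnostics> alpha = ", sprintf("%.3f", x$alpha),
      ", KMO = ", sprintf("%.3f", x$kmo),
      ", PC1 variance share = ", sprintf("%.3f", x$var_explained),
      "\n", sep = "")
  print(x$shape)
  invisible(x)
}
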