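#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks) — the
#' comparison statistic used throughout the sensitivity protocol.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return Scalar rank correlation.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must be paired")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("rank correlation undefined for a constant vector")
  cor(x, y, method = "spearman")
}

# Spearman r between two score tables on their common (household, wave) keys
compare_scores <- function(bench, variant) {
  m <- dplyr::inner_join(bench, variant, by = c("household_id", "wave"),
                         suffix = c("_bench", "_var"))
  stopifnot(nrow(m) > 2)
  tibble::tibble(n = nrow(m),
                 spearman = spearman_rho(m$score_bench, m$score_var))
}

# fast pooled PCA refit on row/column subsets of an existing design matrix
refit_subset <- function(design, items = design$items, waves = design$waves,
                         keep_rows = NULL, reference = "electricity") {
  rows <- design$keys$wave %in% waves
  if (!is.null(keep_rows)) rows <- rows & keep_rows
  X <- design$X[rows, intersect(items, colnames(design$X)), drop = FALSE]
  keys <- design$keys[rows, ]
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < 2 || nrow(X) < 3) {
    abort("degenerate refit: fewer than 2 items or 3 households remain")
  }
  means <- colMeans(X); sds <- apply(X, 2, sd)
  sub <- structure(list(Z = scale(X, means, sds), X = X,
                        keys = keys, items = colnames(X),
                        means = means, sds = sds, dropped = dropped,
                        n = nrow(X), waves = waves),
                   class = "pooled_design")
  model <- fit_pca(pearson_matrix(sub), means = means, sds = sds,
                   reference = reference)
  list(model = model, design = sub, scores = score(model, sub))
}

#' S1: cross-sectional (optionally stratified) index for one wave
#'
#' Refits the PCA index on a single wave's households — restricted to an
#' urban/rural stratum if requested — using the same indicator set but
#' dropping items not asked in that wave and any zero-variance column, then
#' compares to the benchmark scores of the same households by Spearman rank
#' correlation.
#'
#' @param panel An `asset_panel`.
#' @param codebook An `asset_codebook`.
#' @param benchmark A `harmonized_index` (the pooled benchmark).
#' @param wave Wave label.
#' @param stratum Optional stratum label (`"urban"`/`"rural"`).
#' @return List with the refit `model` and a `comparison` tibble
#'   (`label`, `n`, `spearman`).
#' @export
s1_cross_sectional <- function(panel, codebook, benchmark, wave,
                               stratum = NULL) {
  items <- benchmark$model$items
  avail <- purrr::map_lgl(items, function(it) {
    wave %in% cb_item(codebook, it)$availability[[1]]
  })
  keep_rows <- if (is.null(stratum)) NULL else {
    !is.na(benchmark$design$keys$stratum) &
      benchmark$design$keys$stratum == stratum
  }
  fit <- refit_subset(benchmark$design, items = items[avail], waves = wave,
                      keep_rows = keep_rows)
  cmpr <- compare_scores(benchmark$scores, fit$scores)
  label <- if (is.null(stratum)) wave else paste(stratum, wave)
  list(model = fit$model,
       comparison = dplyr::bind_cols(tibble::tibble(label = label), cmpr))
}

#' S2: extended index with newer assets
#'
#' Refits the pooled index adding the six newer assets (video player, sound
#' system, computer, telephone, washing machine, improved sewage),
#' zero-imputed for the waves preceding their introduction, and reports the
#' Spearman correlation with the benchmark within each of the waves in which
#' at least one newer asset was actually asked.
#'
#' @param panel Panel containing the newer items.
#' @param codebook Extended codebook declaring them.
#' @param benchmark The benchmark `harmonized_index`.
#' @return List with the extended `model` and per-wave `comparison` tibble.
#' @export
s2_extended <- function(panel, codebook, benchmark) {
  ext_items <- c(harmonized_item_set(codebook),
                 intersect(newer_items(), codebook$item))
  fit <- harmonized_index(panel, codebook, items = ext_items)
  asked_new <- unique(unlist(
    codebook$availability[codebook$item %in% newer_items()]))
  waves <- intersect(codebook_waves(codebook), asked_new)
  comparison <- purrr::map_dfr(waves, function(w) {
    dplyr::bind_cols(
      tibble::tibble(label = w),
      compare_scores(benchmark$scores[benchmark$scores$wave == w, ],
                     fit$scores[fit$scores$wave == w, ]))
  })
  list(model = fit$model, comparison = comparison)
}

#' S3: leave-out refits (items and/or waves)
#'
#' Refits the pooled PCA index after omitting up to two indicators and/or up
#' to two waves, and compares to the benchmark by Spearman correlation on
#' the households of the remaining waves (both indices are scored on the
#' same records; the comparison population after a wave omission is the
#' remaining waves' households).
#'
#' @param benchmark The benchmark `harmonized_index`.
#' @param omit_items Character vector (0-2 items).
#' @param omit_waves Character vector (0-2 waves).
#' @return Tibble `label, n, spearman`.
#' @export
s3_leave_out <- function(benchmark, omit_items = character(),
                         omit_waves = character()) {
  if (length(omit_items) > 2 || length(omit_waves) > 2) {
    abort("omit at most 2 items and 2 waves")
  }
  items <- setdiff(benchmark$model$items, omit_items)
  waves <- setdiff(benchmark$waves, omit_waves)
  if (length(items) < 2 || length(waves) < 1) {
    abort("at least 2 items and 1 wave must remain")
  }
  fit <- refit_subset(benchmark$design, items = items, waves = waves)
  parts <- c(
    if (length(omit_items)) paste0("-", paste(omit_items, collapse = ",-")),
    if (length(omit_waves)) paste0("-", paste(omit_waves, collapse = ",-")))
  label <- if (length(parts) == 0) "none" else paste(parts, collapse = " ")
  dplyr::bind_cols(tibble::tibble(label = label),
                   compare_scores(benchmark$scores, fit$scores))
}

#' S3 sweeps: all pair/wave/joint omissions
#'
#' Enumerates the full omission lattice: every pair of indicators
#' (\eqn{\binom{19}{2} = 171} for the benchmark set), every single wave and
#' pair of waves, and every joint single-indicator x single-wave omission.
#' Degenerate refits are recorded with `status = "skipped"` and an `NA`
#' correlation rather than aborting the sweep.
#'
#' @param benchmark The benchmark `harmonized_index`.
#' @param what Which sweeps to run.
#' @return Tibble `block, label, n, spearman, status`.
#' @export
s3_sweep <- function(benchmark,
                     what = c("item_pairs", "waves", "joint")) {
  what <- match.arg(what, several.ok = TRUE)
  items <- benchmark$model$items
  waves <- benchmark$waves
  run <- function(block, oi, ow) {
    tryCatch(
      dplyr::bind_cols(tibble::tibble(block = block),
                       s3_leave_out(benchmark, oi, ow),
                       tibble::tibble(status = "ok")),
      error = function(e) {
        tibble::tibble(block = block,
                       label = paste(c(oi, ow), collapse = ","),
                       n = NA_integer_, spearman = NA_real_,
                       status = "skipped")
      })
  }
  out <- list()
  if ("item_pairs" %in% what) {
    prs <- combn(items, 2, simplify = FALSE)
    out <- c(out, purrr::map(prs, ~run("item_pairs", .x, character())))
  }
  if ("waves" %in% what) {
    singles <- purrr::map(waves, ~run("waves", character(), .x))
    prs <- combn(waves, 2, simplify = FALSE)
    doubles <- purrr::map(prs, ~run("waves", character(), .x))
    out <- c(out, singles, doubles)
  }
  if ("joint" %in% what) {
    grid <- tidyr::crossing(item = items, wave = waves)
    out <- c(out, purrr::pmap(grid, function(item, wave) {
      run("joint", item, wave)
    }))
  }
  dplyr::bind_rows(out)
}

#' S4: alternate correlation structure / extraction method
#'
#' Refits the pooled index under an alternate specification — Pearson or
#' polychoric correlations crossed with PCA or one-factor minres EFA, or
#' MCA on the binary-coded items (crowding binarized at 0.75) — and compares
#' to the benchmark on all pooled households.
#'
#' @param panel An `asset_panel`.
#' @param codebook An `asset_codebook`.
#' @param benchmark The benchmark `harmonized_index`.
#' @param corr `"pearson"` or `"polychoric"` (ignored, and must be left at
#'   `"pearson"`, for MCA).
#' @param method `"pca"`, `"efa"` or `"mca"`.
#' @return List with the variant `model` and `comparison` tibble.
#' @export
s4_alternate <- function(panel, codebook, benchmark,
                         corr = c("pearson", "polychoric"),
                         method = c("pca", "efa", "mca")) {
  corr <- match.arg(corr)
  method <- match.arg(method)
  if (method == "mca" && corr != "pearson") {
    abort(paste0("unsupported combination; supported: (pearson|polychoric) x ",
                 "(pca|efa), or mca"))
  }
  fit <- harmonized_index(panel, codebook, items = benchmark$model$items,
                          method = method, corr = corr)
  label <- if (method == "mca") "mca" else paste(method, corr)
  list(model = fit$model,
       comparison = dplyr::bind_cols(tibble::tibble(label = label),
                                     compare_scores(benchmark$scores,
                                                    fit$scores)))
}

#' S5: three-level ordinal recoding of housing materials
#'
#' Re-specifies the housing-material items that carry an ordinal recode
#' (low/medium/high) as 3-level columns, builds the polychoric correlation
#' matrix, extracts by PCA or EFA, and compares to the benchmark.
#'
#' @inheritParams s4_alternate
#' @param method `"pca"` or `"efa"`.
#' @return List with the variant `model` and `comparison` tibble.
#' @export
s5_ordinal <- function(panel, codebook, benchmark,
                       method = c("pca", "efa")) {
  method <- match.arg(method)
  ord_items <- codebook$item[has_ordinal_recode(codebook, codebook$item)]
  ord_items <- intersect(benchmark$model$items, ord_items)
  if (length(ord_items) == 0) {
    abort("no benchmark items carry an ordinal recode")
  }
  has_ord <- panel$item %in% ord_items & panel$missing == "observed" &
    is.na(panel$ordinal)
  if (any(has_ord)) {
    abort(paste0("ordinal values missing for item(s): ",
                 paste(unique(panel$item[has_ord]), collapse = ", ")))
  }
  fit <- harmonized_index(panel, codebook, items = benchmark$model$items,
                          method = method, corr = "polychoric",
                          ordinal_items = ord_items)
  list(model = fit$model,
       comparison = dplyr::bind_cols(
         tibble::tibble(label = paste("ordinal", method)),
         compare_scores(benchmark$scores, fit$scores)))
}

#' Run the full S1-S5 sensitivity protocol
#'
#' Produces the sensitivity report table: one row per variant with its
#' block, label, number of compared households and Spearman correlation with
#' the benchmark. Variant failures are recorded as rows with
#' `status = "failed"` and the run continues.
#'
#' @param panel An `asset_panel` (benchmark items; pass the extended panel
#'   via `extended_panel`/`extended_codebook` for S2).
#' @param codebook The benchmark `asset_codebook`.
#' @param benchmark The benchmark `harmonized_index` (fit if omitted).
#' @param grid Which blocks to run, a subset of `c("s1","s2","s3","s4","s5")`.
#' @param extended_panel,extended_codebook Inputs for S2 (skipped if absent).
#' @param strata Stratum labels for the stratified S1 fits in waves where
#'   stratum labels are present.
#' @return A tibble of class `sensitivity_report`.
#' @export
sensitivity_report <- function(panel, codebook, benchmark = NULL,
                               grid = c("s1", "s2", "s3", "s4", "s5"),
                               extended_panel = NULL,
                               extended_codebook = NULL,
                               strata = c("urban", "rural")) {
  benchmark <- benchmark %||% harmonized_index(panel, codebook)
  rows <- list()
  add <- function(block, f) {
    r <- tryCatch(
      dplyr::bind_cols(tibble::tibble(block = block), f(),
                       tibble::tibble(status = "ok")),
      error = function(e) {
        tibble::tibble(block = block, label = "(failed)", n = NA_integer_,
                       spearman = NA_real_, status = paste("failed:",
                                                           conditionMessage(e)))
      })
    rows[[length(rows) + 1]] <<- r
  }
  if ("s1" %in% grid) {
    for (w in benchmark$waves) {
      add("s1", function() s1_cross_sectional(panel, codebook, benchmark,
                                              w)$comparison)
    }
    labelled <- benchmark$design$keys
    for (w in benchmark$waves) {
      present <- labelled$stratum[labelled$wave == w]
      for (s in intersect(strata, unique(present[!is.na(present)]))) {
        add("s1", function() s1_cross_sectional(panel, codebook, benchmark,
                                                w, stratum = s)$comparison)
      }
    }
  }
  if ("s2" %in% grid && !is.null(extended_panel) &&
      !is.null(extended_codebook)) {
    add("s2", function() s2_extended(extended_panel, extended_codebook,
                                     benchmark)$comparison)
  }
  if ("s3" %in% grid) {
    s3 <- s3_sweep(benchmark)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(block = paste0("s3_", s3$block)),
      s3[c("label", "n", "spearman", "status")])
  }
  if ("s4" %in% grid) {
    for (spec in list(c("pearson", "pca"), c("pearson", "efa"),
                      c("polychoric", "pca"), c("polychoric", "efa"),
                      c("pearson", "mca"))) {
      add("s4", function() s4_alternate(panel, codebook, benchmark,
                                        corr = spec[1],
                                        method = spec[2])$comparison)
    }
  }
  if ("s5" %in% grid) {
    for (m in c("pca", "efa")) {
      add("s5", function() s5_ordinal(panel, codebook, benchmark,
                                      method = m)$comparison)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Minimum correlation per sensitivity block
#'
#' @param report A `sensitivity_report`.
#' @return Tibble `block, n_variants, min_spearman`.
#' @export
sensitivity_summary <- function(report) {
  report |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(n_variants = dplyr::n(),
                     min_spearman = min(.data$spearman),
                     .groups = "drop")
}
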