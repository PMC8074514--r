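#' Wave-aware zero-imputation of not-asked items
#'
#' Applies the harmonization rule that ownership items absent from a wave's
#' survey instrument are imputed as "not owned" (0) for that wave: land,
#' record player, sewing machine, television, motorcycle and automobile for
#' 1967, record player for 2002 onwards, and — in the extended set — the
#' newer assets for the waves preceding their introduction. Only not-asked
#' cells may be imputed; household nonresponse is never touched, and a rule
#' that targets an (item, wave) actually asked is an error, so observed data
#' can never be silently overwritten.
#'
#' @param panel An `asset_panel`.
#' @param codebook An `asset_codebook`; by default the rules are its
#'   `impute_zero_waves` declarations.
#' @param rules Optional override: tibble with columns `item`, `wave`.
#' @return The panel with imputed cells set to 0 and `missing = "imputed"`.
#' @export
impute_not_asked_as_zero <- function(panel, codebook, rules = NULL) {
  if (is.null(rules)) {
    rules <- tidyr::unnest(codebook[c("item", "impute_zero_waves")],
                           cols = "impute_zero_waves")
    names(rules)[2] <- "wave"
  }
  rules <- rules[rules$wave %in% unique(panel$wave), ]
  if (nrow(rules) == 0) return(panel)
  key <- paste(panel$item, panel$wave)
  hit <- key %in% paste(rules$item, rules$wave)
  if (any(panel$missing[hit] %in% c("observed", "nonresponse"))) {
    ex <- panel[hit & panel$missing %in% c("observed", "nonresponse"), ][1, ]
    abort(paste0("zero-imputation rule targets asked data: item '", ex$item,
                 "', wave ", ex$wave))
  }
  panel$value[hit] <- 0
  panel$ordinal[hit] <- ifelse(is.na(panel$ordinal[hit]) &
                                 has_ordinal_recode(codebook, panel$item[hit]),
                               0, panel$ordinal[hit])
  panel$missing[hit] <- "imputed"
  restore_panel(panel, panel)
}

has_ordinal_recode <- function(codebook, items) {
  !purrr::map_lgl(codebook$ordinal_recode[match(items, codebook$item)],
                  is.null)
}

#' Pool waves into a standardized design matrix
#'
#' Pools the requested waves into one household-by-item design. Records with
#' any remaining missing value (nonresponse, or not-asked cells left
#' unimputed) on the item set are excluded listwise. Columns are centred and
#' scaled by the *pooled* mean and standard deviation — one scale across all
#' waves, which is what makes scores comparable over time. Zero-variance
#' columns are flagged, dropped from the fit, and reported with a warning.
#'
#' @param panel An `asset_panel` (typically after [impute_not_asked_as_zero()]).
#' @param items Character vector of items to pool.
#' @param waves Waves to include (default: all panel waves).
#' @param ordinal_items Items for which the three-level ordinal coding is
#'   used instead of the binary coding (the S5 re-specification).
#' @param crowding_binary Binarize crowding at 0.75 (for MCA/polychoric)?
#' @param crowding_item Name of the crowding item.
#' @return A `pooled_design`: list with standardized matrix `Z`, raw matrix
#'   `X`, row `keys` (household_id, wave, stratum), pooled `means`/`sds`,
#'   `dropped` items and pooled `n`.
#' @export
pool <- function(panel, items, waves = NULL,
                 ordinal_items = character(),
                 crowding_binary = FALSE,
                 crowding_item = "rooms_per_member") {
  waves <- waves %||% panel_waves(panel)
  waves <- intersect(panel_waves(panel), waves)
  px <- panel[panel$wave %in% waves & panel$item %in% items, ]
  if (nrow(px) == 0) abort("no records for the requested items/waves")
  px$val <- ifelse(px$item %in% ordinal_items & !is.na(px$ordinal),
                   px$ordinal, px$value)
  if (crowding_binary && crowding_item %in% items) {
    isc <- px$item == crowding_item & !is.na(px$val)
    px$val[isc] <- binarize_crowding(px$val[isc])
  }
  wide <- tidyr::pivot_wider(
    px[c("household_id", "wave", "stratum", "item", "val")],
    names_from = "item", values_from = "val")
  absent <- setdiff(items, names(wide))
  if (length(absent) > 0) {
    abort(paste0("item(s) absent from panel: ", paste(absent, collapse = ", ")))
  }
  wide <- wide[c("household_id", "wave", "stratum", items)]
  X <- as.matrix(wide[items])
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  keys <- wide[complete, c("household_id", "wave", "stratum")]
  if (nrow(X) < 3) abort("fewer than 3 complete records after exclusion")
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  if (length(dropped) > 0) {
    warn(paste0("dropping zero-variance column(s): ",
                paste(dropped, collapse = ", ")))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  Z <- scale(X, center = means, scale = sds)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  structure(list(Z = Z, X = X, keys = tibble::as_tibble(keys),
                 items = colnames(X), means = means, sds = sds,
                 dropped = dropped, n = nrow(X), waves = waves),
            class = "pooled_design")
}

#' @export
print.pooled_design <- function(x, ...) {
  cat("<pooled_design> n = ", x$n, ", ", length(x$items), " items, waves: ",
      paste(x$waves, collapse = ", "), "\n", sep = "")
  if (length(x$dropped) > 0) {
    cat("  dropped (zero variance): ", paste(x$dropped, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
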