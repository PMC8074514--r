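#' Survey codebooks for multi-wave asset panels
#'
#' A codebook declares, for every survey item, its kind (`asset`, `housing`
#' or `crowding`), the recoding of raw response levels to binary (and
#' optionally three-level ordinal) quality codes, the set of waves in which
#' the item was on the survey instrument, and the waves for which absent
#' ownership items are zero-imputed before pooling. Wave chronology is the
#' order of the `waves` attribute, not anything parsed from the labels.
#'
#' @param items A data frame with columns `item`, `kind`, and list-columns
#'   `availability`, `binary_recode`, `ordinal_recode`, `impute_zero_waves`.
#' @param waves Character vector of wave labels in chronological order.
#' @return A tibble of class `asset_codebook`.
#' @export
codebook <- function(items, waves) {
  items <- tibble::as_tibble(items)
  required <- c("item", "kind", "availability", "binary_recode",
                "ordinal_recode", "impute_zero_waves")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("codebook items missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(items$item)) {
    abort("codebook item names must be unique")
  }
  if (!all(items$kind %in% c("asset", "housing", "crowding"))) {
    abort("item kind must be one of 'asset', 'housing', 'crowding'")
  }
  if (sum(items$kind == "crowding") != 1L) {
    abort("exactly one codebook item must have kind = 'crowding'")
  }
  for (i in seq_len(nrow(items))) {
    av <- items$availability[[i]]
    if (length(av) == 0 || !all(av %in% waves)) {
      abort(paste0("item '", items$item[i],
                   "': availability must be a non-empty subset of waves"))
    }
    iz <- items$impute_zero_waves[[i]]
    if (length(iz) > 0 && !all(iz %in% waves)) {
      abort(paste0("item '", items$item[i],
                   "': impute_zero_waves outside declared waves"))
    }
    br <- items$binary_recode[[i]]
    or <- items$ordinal_recode[[i]]
    if (!is.null(br) && !all(br %in% c(0, 1))) {
      abort(paste0("item '", items$item[i], "': binary codes must be 0/1"))
    }
    if (!is.null(or)) {
      if (!all(or %in% c(0, 1, 2))) {
        abort(paste0("item '", items$item[i], "': ordinal codes must be 0/1/2"))
      }
      # ordering agreement: ordinal extremes pin down the binary code
      common <- intersect(names(br), names(or))
      bad <- common[(or[common] == 0 & br[common] != 0) |
                    (or[common] == 2 & br[common] != 1)]
      if (length(bad) > 0) {
        abort(paste0("item '", items$item[i],
                     "': binary and ordinal recodes disagree on level(s) ",
                     paste(bad, collapse = ", ")))
      }
    }
  }
  structure(items, waves = as.character(waves),
            class = c("asset_codebook", class(items)))
}

#' @export
print.asset_codebook <- function(x, ...) {
  cat("<asset_codebook> ", nrow(x), " items, ",
      length(attr(x, "waves")), " waves (",
      paste(attr(x, "waves"), collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Wave labels of a codebook, in chronological order
#' @param codebook An `asset_codebook`.
#' @return Character vector of wave labels.
#' @export
codebook_waves <- function(codebook) attr(codebook, "waves")

cb_item <- function(codebook, name) {
  i <- match(name, codebook$item)
  if (is.na(i)) abort(paste0("item '", name, "' not in codebook"))
  codebook[i, ]
}

#' The benchmark harmonized item set
#'
#' Returns the 19-item benchmark set (8 durable assets and 11 housing
#' characteristics, including rooms-per-member crowding) used for the
#' harmonized index, verifying that every benchmark item is declared in the
#' codebook. Extended codebooks with newer assets still yield only the
#' benchmark 19.
#'
#' @param codebook An `asset_codebook`.
#' @return Character vector of 19 item names.
#' @export
harmonized_item_set <- function(codebook) {
  bench <- benchmark_items()
  missing <- setdiff(bench, codebook$item)
  if (length(missing) > 0) {
    abort(paste0("codebook is missing benchmark item(s): ",
                 paste(missing, collapse = ", ")))
  }
  bench
}

benchmark_items <- function() {
  c("radio", "record_player", "sewing_machine", "refrigerator", "television",
    "bicycle", "motorcycle", "automobile",
    "owns_land", "owns_house", "rooms_per_member", "floor", "roof", "walls",
    "separate_kitchen", "cooking_medium", "sanitary_installation",
    "electricity", "improved_water_source")
}

newer_items <- function() {
  c("video_player", "sound_system", "computer", "telephone",
    "washing_machine", "improved_sewage")
}

#' Default six-wave cohort codebook
#'
#' The codebook for the six-wave Guatemalan cohort design: 19 benchmark items
#' plus, when `extended = TRUE`, six newer assets introduced from 2002
#' onwards. Item availability follows the survey instruments (e.g. record
#' player asked only in 1975 and 1987; automobile not asked in 1967), and
#' `impute_zero_waves` encodes the harmonization rules: land, record player,
#' sewing machine, television, motorcycle and automobile zero-imputed for
#' 1967; record player zero-imputed from 2002 onwards; newer assets
#' zero-imputed for the waves before they entered the instrument.
#'
#' @param extended Include the six newer assets (video player, sound system,
#'   computer, telephone, washing machine, improved sewage)?
#' @return An `asset_codebook`.
#' @export
default_codebook <- function(extended = FALSE) {
  waves <- c("1967", "1975", "1987", "2002", "2015-16", "2017-18")
  all_w <- waves
  not67 <- waves[-1]
  from02 <- waves[4:6]
  yn <- c("0" = 0, "1" = 1, no = 0, yes = 1)
  yn_ord <- NULL

  row <- function(item, kind, availability, impute = character(),
                  binary = yn, ordinal = yn_ord) {
    tibble::tibble(item = item, kind = kind,
                   availability = list(availability),
                   binary_recode = list(binary),
                   ordinal_recode = list(ordinal),
                   impute_zero_waves = list(impute))
  }
  # three-level housing materials: middle quality is coded low in the binary
  # recode, so binary "high quality" corresponds to the top ordinal level
  lev3 <- function(l0, l1, l2) {
    list(binary = setNames(c(0, 0, 1, 0, 0, 1), c(l0, l1, l2, "0", "1", "2")),
         ordinal = setNames(c(0, 1, 2, 0, 1, 2), c(l0, l1, l2, "0", "1", "2")))
  }
  floor3 <- lev3("dirt", "cement", "tile")
  roof3 <- lev3("thatch", "lamina", "concrete")
  walls3 <- lev3("adobe", "wood", "block")

  items <- dplyr::bind_rows(
    row("radio", "asset", all_w),
    row("record_player", "asset", waves[2:3],
        impute = c("1967", from02)),
    row("sewing_machine", "asset", not67, impute = "1967"),
    row("refrigerator", "asset", all_w),
    row("television", "asset", not67, impute = "1967"),
    row("bicycle", "asset", all_w),
    row("motorcycle", "asset", not67, impute = "1967"),
    row("automobile", "asset", not67, impute = "1967"),
    row("owns_land", "housing", not67, impute = "1967"),
    row("owns_house", "housing", all_w),
    row("rooms_per_member", "crowding", all_w, binary = NULL),
    row("floor", "housing", all_w, binary = floor3$binary,
        ordinal = floor3$ordinal),
    row("roof", "housing", all_w, binary = roof3$binary,
        ordinal = roof3$ordinal),
    row("walls", "housing", all_w, binary = walls3$binary,
        ordinal = walls3$ordinal),
    row("separate_kitchen", "housing", all_w),
    row("cooking_medium", "housing", all_w),
    row("sanitary_installation", "housing", all_w),
    row("electricity", "housing", all_w),
    row("improved_water_source", "housing", all_w)
  )
  if (extended) {
    pre02 <- waves[1:3]
    items <- dplyr::bind_rows(
      items,
      row("video_player", "asset", from02, impute = pre02),
      row("sound_system", "asset", from02, impute = pre02),
      row("computer", "asset", from02, impute = pre02),
      row("telephone", "asset", from02, impute = pre02),
      row("washing_machine", "asset", waves[5:6],
          impute = c(pre02, "2002")),
      row("improved_sewage", "housing", from02, impute = pre02)
    )
  }
  codebook(items, waves)
}

#' Read / write a codebook as JSON
#'
#' @param path File path.
#' @return `read_codebook()` returns an `asset_codebook`;
#'   `write_codebook()` returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- purrr::map_dfr(j$items, function(it) {
    tibble::tibble(
      item = it$item, kind = it$kind,
      availability = list(unlist(it$availability)),
      binary_recode = list(if (is.null(it$binary_recode)) NULL else
        unlist(it$binary_recode)),
      ordinal_recode = list(if (is.null(it$ordinal_recode)) NULL else
        unlist(it$ordinal_recode)),
      impute_zero_waves = list(as.character(unlist(it$impute_zero_waves)))
    )
  })
  codebook(items, unlist(j$waves))
}

#' @rdname read_codebook
#' @param codebook An `asset_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  j <- list(
    waves = as.list(codebook_waves(codebook)),
    items = purrr::pmap(codebook, function(item, kind, availability,
                                           binary_recode, ordinal_recode,
                                           impute_zero_waves, ...) {
      list(item = item, kind = kind,
           availability = as.list(availability),
           binary_recode = if (is.null(binary_recode)) NULL else
             as.list(binary_recode),
           ordinal_recode = if (is.null(ordinal_recode)) NULL else
             as.list(ordinal_recode),
           impute_zero_waves = as.list(impute_zero_waves))
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
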