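#' Household-by-wave asset panels
#'
#' An asset panel is a long tibble with one row per (household, wave, item)
#' cell: columns `household_id`, `wave`, `stratum` (urban/rural or `NA`),
#' `item`, `value` (recoded binary 0/1, or positive real for crowding),
#' `ordinal` (0/1/2 for items with a three-level recode, else `NA`), and
#' `missing`, one of `"observed"`, `"not_asked"` (item absent from the wave's
#' instrument — all-or-none across households within a wave), `"nonresponse"`
#' (household-level gap) or `"imputed"` (zero-imputed by the harmonization
#' rules). `value` is `NA` exactly when `missing` is `"not_asked"` or
#' `"nonresponse"`.
#'
#' @param x A data frame with the columns above (`stratum`/`ordinal` optional).
#' @param waves Chronological wave labels; defaults to order of appearance.
#' @return A tibble of class `asset_panel`.
#' @export
as_asset_panel <- function(x, waves = NULL) {
  x <- tibble::as_tibble(x)
  if (!"stratum" %in% names(x)) x$stratum <- NA_character_
  if (!"ordinal" %in% names(x)) x$ordinal <- NA_real_
  need <- c("household_id", "wave", "stratum", "item", "value", "ordinal",
            "missing")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("asset panel missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- x[need]
  x$wave <- as.character(x$wave)
  if (is.null(waves)) waves <- unique(x$wave)
  if (anyDuplicated(x[c("household_id", "wave", "item")])) {
    abort("duplicate (household_id, wave, item) records in panel")
  }
  bad <- x$missing %in% c("not_asked", "nonresponse") & !is.na(x$value)
  if (any(bad)) abort("missing-marked cells must have NA value")
  bad <- !(x$missing %in% c("not_asked", "nonresponse")) & is.na(x$value)
  if (any(bad)) abort("observed cells must carry a value")
  # not-asked must be all-or-none per (item, wave)
  chk <- dplyr::summarise(
    dplyr::group_by(x, .data$item, .data$wave),
    any_na_ask = any(.data$missing == "not_asked"),
    all_na_ask = all(.data$missing == "not_asked"), .groups = "drop")
  if (any(chk$any_na_ask & !chk$all_na_ask)) {
    abort("'not_asked' must be all-or-none within an (item, wave)")
  }
  structure(x, waves = as.character(waves),
            class = c("asset_panel", class(x)))
}

#' @export
print.asset_panel <- function(x, ...) {
  cat("<asset_panel> ",
      dplyr::n_distinct(x$household_id), " households, ",
      dplyr::n_distinct(x$wave), " waves, ",
      dplyr::n_distinct(x$item), " items\n", sep = "")
  NextMethod()
}

panel_waves <- function(panel) {
  attr(panel, "waves") %||% unique(panel$wave)
}

restore_panel <- function(x, template) {
  as_asset_panel(x, waves = panel_waves(template))
}

#' Rooms-per-member crowding
#'
#' Crowding is measured as rooms per household member; a higher value
#' reflects greater wealth.
#'
#' @param rooms Number of rooms (>= 1).
#' @param members Number of household members (>= 1).
#' @return `rooms / members`, a positive real.
#' @export
compute_crowding <- function(rooms, members) {
  if (any(!is.finite(rooms)) || any(!is.finite(members)) ||
      any(rooms < 1) || any(members < 1)) {
    abort("rooms and members must be finite and >= 1")
  }
  rooms / members
}

#' Binarize crowding at the 0.75 rooms-per-member cut
#'
#' Used for the MCA and polychoric variants: values strictly greater than
#' 0.75 are coded 1, all others 0.
#'
#' @param value Positive, finite crowding value(s).
#' @return 0/1 vector.
#' @export
binarize_crowding <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    abort("crowding values must be finite and > 0")
  }
  as.numeric(value > 0.75)
}

recode_level <- function(raw, map, item, allowed) {
  if (is.null(map)) {
    v <- suppressWarnings(as.numeric(raw))
    if (any(is.na(v) & !is.na(raw))) {
      abort(paste0("item '", item, "': non-numeric level(s) ",
                   paste(unique(raw[is.na(v) & !is.na(raw)]), collapse = ", "),
                   " with no recode map"))
    }
    return(v)
  }
  raw_chr <- as.character(raw)
  out <- unname(map[raw_chr])
  unknown <- !is.na(raw_chr) & is.na(out)
  if (any(unknown)) {
    # numeric levels already in code space pass through (idempotent recode)
    v <- suppressWarnings(as.numeric(raw_chr[unknown]))
    ok <- !is.na(v) & v %in% allowed
    out[which(unknown)[ok]] <- v[ok]
    if (any(!ok)) {
      abort(paste0("item '", item, "': unknown raw level(s) ",
                   paste(unique(raw_chr[unknown][!ok]), collapse = ", ")))
    }
  }
  out
}

#' Read an asset panel from CSV
#'
#' Two dialects are supported. **Long**: a single CSV with columns
#' `household_id, wave, item, value` (plus optional `stratum`, `ordinal`,
#' `missing`). When a `missing` column is present the file is taken to be an
#' already-recoded panel written by [write_panel()] and is restored directly.
#' Otherwise raw levels are recoded via the codebook; an empty `value` is a
#' household nonresponse, and an (item, wave) with no rows at all — or an
#' item outside its declared availability — is marked not-asked for every
#' household in that wave. **Wide**: `path` is a directory with one file per
#' wave named `<wave>.csv`, columns `household_id` (optional `stratum`,
#' `rooms`, `members`) plus one column per asked item; an absent item column
#' means the item was not asked in that wave; empty cells are nonresponse.
#'
#' @param path CSV file (long) or directory of per-wave CSVs (wide).
#' @param codebook An `asset_codebook`.
#' @return An `asset_panel`.
#' @export
read_panel <- function(path, codebook) {
  if (dir.exists(path)) {
    read_panel_wide(path, codebook)
  } else {
    read_panel_long(path, codebook)
  }
}

read_panel_long <- function(path, codebook) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if ("missing" %in% names(df)) {
    df$value <- as.numeric(df$value)
    if ("ordinal" %in% names(df)) df$ordinal <- as.numeric(df$ordinal)
    df$household_id <- utils::type.convert(df$household_id, as.is = TRUE)
    return(as_asset_panel(df, waves = codebook_waves(codebook)))
  }
  build_panel_from_raw(df, codebook)
}

read_panel_wide <- function(path, codebook) {
  waves <- codebook_waves(codebook)
  files <- file.path(path, paste0(waves, ".csv"))
  present <- file.exists(files)
  if (!any(present)) abort(paste0("no per-wave CSV files found in ", path))
  long <- purrr::map_dfr(which(present), function(i) {
    df <- readr::read_csv(files[i], comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    if (!"household_id" %in% names(df)) {
      abort(paste0(files[i], ": missing household_id column"))
    }
    if (all(c("rooms", "members") %in% names(df)) &&
        !"rooms_per_member" %in% names(df)) {
      df$rooms_per_member <- as.character(
        compute_crowding(as.numeric(df$rooms), as.numeric(df$members)))
      df$rooms <- NULL; df$members <- NULL
    }
    idcols <- intersect(c("household_id", "stratum"), names(df))
    tidyr::pivot_longer(df, cols = -dplyr::all_of(idcols),
                        names_to = "item", values_to = "value") |>
      dplyr::mutate(wave = waves[i])
  })
  build_panel_from_raw(long, codebook)
}

build_panel_from_raw <- function(df, codebook) {
  waves <- codebook_waves(codebook)
  df$household_id <- utils::type.convert(as.character(df$household_id),
                                         as.is = TRUE)
  if (!"stratum" %in% names(df)) df$stratum <- NA_character_
  df$wave <- as.character(df$wave)
  bad_wave <- setdiff(unique(df$wave), waves)
  if (length(bad_wave) > 0) {
    abort(paste0("undeclared wave label(s): ", paste(bad_wave, collapse = ", ")))
  }
  bad_item <- setdiff(unique(df$item), codebook$item)
  if (length(bad_item) > 0) {
    abort(paste0("undeclared item(s): ", paste(bad_item, collapse = ", ")))
  }
  if (anyDuplicated(df[c("household_id", "wave", "item")])) {
    abort("duplicate (household_id, wave, item) records in input")
  }

  waves_present <- intersect(waves, unique(df$wave))
  roster <- dplyr::distinct(df, .data$household_id, .data$wave, .data$stratum)
  grid <- tidyr::crossing(roster, item = codebook$item)

  obs <- df[c("household_id", "wave", "item", "value")]
  x <- dplyr::left_join(grid, obs, by = c("household_id", "wave", "item"))

  # availability: item must not appear outside its declared waves
  avail <- tidyr::unnest(codebook[c("item", "availability")],
                         cols = "availability")
  names(avail)[2] <- "wave"
  avail$asked <- TRUE
  x <- dplyr::left_join(x, avail, by = c("item", "wave"))
  x$asked <- !is.na(x$asked)
  off <- !x$asked & !is.na(x$value)
  if (any(off)) {
    ex <- x[off, ][1, ]
    abort(paste0("item '", ex$item, "' has data in wave ", ex$wave,
                 " but is not declared available there"))
  }

  out <- purrr::map_dfr(split(x, x$item), function(xi) {
    it <- cb_item(codebook, xi$item[1])
    asked_any <- tapply(!is.na(xi$value), xi$wave, any)
    xi$missing <- dplyr::case_when(
      !xi$asked ~ "not_asked",
      !asked_any[xi$wave] ~ "not_asked",  # column absent for the whole wave
      is.na(xi$value) ~ "nonresponse",
      TRUE ~ "observed")
    keep <- xi$missing == "observed"
    val <- rep(NA_real_, nrow(xi))
    ordv <- rep(NA_real_, nrow(xi))
    if (any(keep)) {
      br <- it$binary_recode[[1]]
      or <- it$ordinal_recode[[1]]
      allowed <- if (it$kind == "crowding") NULL else c(0, 1)
      val[keep] <- recode_level(xi$value[keep], br, it$item, c(0, 1))
      if (!is.null(or)) {
        ordv[keep] <- recode_level(xi$value[keep], or, it$item, c(0, 1, 2))
      }
      if (it$kind == "crowding") {
        if (any(!is.finite(val[keep]) | val[keep] <= 0)) {
          abort(paste0("item '", it$item, "': crowding must be finite and > 0"))
        }
      } else if (any(!val[keep] %in% c(0, 1))) {
        abort(paste0("item '", it$item, "': binary values must be 0/1"))
      }
    }
    xi$value <- val
    xi$ordinal <- ordv
    xi[c("household_id", "wave", "stratum", "item", "value", "ordinal",
         "missing")]
  })
  out <- dplyr::arrange(out, match(.data$wave, waves), .data$household_id,
                        match(.data$item, codebook$item))
  as_asset_panel(out, waves = waves)
}

#' Write an asset panel to CSV
#'
#' The long dialect (single file, default) writes the fully recoded panel —
#' `value`, `ordinal` and `missing` columns included — and round-trips
#' losslessly through [read_panel()]. The wide dialect writes one
#' `<wave>.csv` per wave into directory `path`, omitting not-asked item
#' columns and leaving nonresponse cells empty.
#'
#' @param panel An `asset_panel`.
#' @param path Output file (long) or directory (wide).
#' @param format `"long"` or `"wide"`.
#' @param meta Optional named list written as a `#`-comment header.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("long", "wide"), meta = NULL) {
  format <- match.arg(format)
  header <- if (!is.null(meta)) {
    paste0("# ", paste(names(meta), unlist(meta), sep = "=", collapse = " "),
           "\n")
  }
  if (format == "long") {
    writeLines(c(header, readr::format_csv(tibble::as_tibble(panel))), path,
               sep = "")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (w in intersect(panel_waves(panel), unique(panel$wave))) {
      pw <- panel[panel$wave == w & panel$missing != "not_asked", ]
      wide <- tidyr::pivot_wider(
        pw[c("household_id", "stratum", "item", "value")],
        names_from = "item", values_from = "value")
      f <- file.path(path, paste0(w, ".csv"))
      writeLines(c(header, readr::format_csv(wide)), f, sep = "")
    }
  }
  invisible(path)
}
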