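test_that("codebook validation enforces its invariants", {
  cb <- mini_codebook()
  expect_s3_class(cb, "asset_codebook")
  expect_equal(codebook_waves(cb), c("w1", "w2", "w3"))

  items <- tibble::as_tibble(cb)
  dup <- dplyr::bind_rows(items, items[1, ])
  expect_error(codebook(dup, codebook_waves(cb)), "unique")

  no_crowding <- items[items$kind != "crowding", ]
  expect_error(codebook(no_crowding, codebook_waves(cb)), "crowding")

  bad <- items
  # ordinal top level mapped to binary 0 violates the ordering agreement
  bad$binary_recode[[3]] <- setNames(c(0, 0, 0), c("dirt", "cement", "tile"))
  bad$ordinal_recode[[3]] <- setNames(c(0, 1, 2), c("dirt", "cement", "tile"))
  expect_error(codebook(bad, codebook_waves(cb)), "disagree")

  bad2 <- items
  bad2$availability[[1]] <- character()
  expect_error(codebook(bad2, codebook_waves(cb)), "non-empty")
})

test_that("default codebook matches the six-wave instrument design", {
  cb <- default_codebook()
  expect_equal(nrow(cb), 19)
  expect_equal(harmonized_item_set(cb), cb$item)
  expect_equal(cb$availability[[match("record_player", cb$item)]],
               c("1975", "1987"))
  # every not-asked benchmark (item, wave) combination has an imputation rule
  waves <- codebook_waves(cb)
  for (i in seq_len(nrow(cb))) {
    gap <- setdiff(waves, cb$availability[[i]])
    expect_setequal(gap, cb$impute_zero_waves[[i]])
  }
  ext <- default_codebook(extended = TRUE)
  expect_equal(nrow(ext), 25)
  expect_equal(harmonized_item_set(ext), cb$item)
  expect_equal(ext$availability[[match("washing_machine", ext$item)]],
               c("2015-16", "2017-18"))
})

test_that("crowding construction and binarization follow their rules", {
  expect_equal(compute_crowding(3, 4), 0.75)
  expect_equal(compute_crowding(2, 2), 1)
  expect_error(compute_crowding(1, 0), ">= 1")
  # strict inequality at the 0.75 cut
  expect_equal(binarize_crowding(c(0.75, 1.13, 0.61)), c(0, 1, 0))
  expect_error(binarize_crowding(Inf), "finite")
  expect_error(binarize_crowding(-1), "finite")
})

test_that("long write/read round-trips values, missing kinds and strata", {
  panel <- random_mini_panel(n = 15, seed = 42)
  panel$stratum[panel$wave == "w3"] <-
    ifelse(panel$household_id[panel$wave == "w3"] <= 5, "urban", "rural")
  # inject a household nonresponse
  i <- which(panel$item == "radio" & panel$wave == "w2" &
               panel$household_id == 3)
  panel$value[i] <- NA; panel$missing[i] <- "nonresponse"
  panel <- as_asset_panel(panel, waves = c("w1", "w2", "w3"))

  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f, meta = list(seed = 1))
  back <- read_panel(f, mini_codebook())
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(panel))
  expect_equal(sum(back$missing == "not_asked"),
               sum(panel$missing == "not_asked"))
})

test_that("wide dialect recodes raw levels and infers both missing kinds", {
  cb <- mini_codebook()
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(
    household_id = 1:3, radio = c("yes", "no", "yes"),
    floor = c("dirt", "cement", "tile"),
    electricity = c("0", "1", ""), rooms = c(2, 3, 4),
    members = c(4, 3, 2)), file.path(dir, "w1.csv"), na = "")
  readr::write_csv(tibble::tibble(
    household_id = 1:3, radio = c("1", "0", "1"),
    automobile = c("0", "0", "1"), floor = c("tile", "dirt", "cement"),
    electricity = c("1", "1", "0"),
    rooms_per_member = c(0.5, 1, 1.5)), file.path(dir, "w2.csv"), na = "")
  panel <- read_panel(dir, cb)

  g <- function(it, w) panel[panel$item == it & panel$wave == w, ]
  expect_equal(g("floor", "w1")$value, c(0, 0, 1))     # dirt/cement low, tile high
  expect_equal(g("floor", "w1")$ordinal, c(0, 1, 2))
  expect_equal(g("radio", "w1")$value, c(1, 0, 1))
  # automobile column absent in w1 => not asked for every household
  expect_true(all(g("automobile", "w1")$missing == "not_asked"))
  # empty electricity cell => household nonresponse, not zero
  expect_equal(g("electricity", "w1")$missing,
               c("observed", "observed", "nonresponse"))
  # crowding computed from rooms/members
  expect_equal(g("rooms_per_member", "w1")$value, c(0.5, 1, 2))
})

test_that("recoding is idempotent through a write/read cycle", {
  panel <- random_mini_panel(n = 10, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f1)
  once <- read_panel(f1, mini_codebook())
  write_panel(once, f2)
  twice <- read_panel(f2, mini_codebook())
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
})

test_that("malformed input is rejected with context", {
  cb <- mini_codebook()
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    household_id = 1, wave = "w1", item = "floor", value = "marble"), f)
  expect_error(read_panel(f, cb), "floor.*marble")

  readr::write_csv(tibble::tibble(
    household_id = c(1, 1), wave = "w1", item = "radio",
    value = c("1", "0")), f)
  expect_error(read_panel(f, cb), "duplicate")

  readr::write_csv(tibble::tibble(
    household_id = 1, wave = "w1", item = "automobile", value = "1"), f)
  expect_error(read_panel(f, cb), "not declared available")
})
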