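test_that("threshold calibration obeys its closed form", {
  # symmetric case: p = 0.5 at mu = 0 gives tau = 0 for any lambda/sigma
  expect_equal(calibrate_thresholds(0.5, 1.3, 0, 1), 0)
  expect_equal(calibrate_thresholds(0.5, 0.4, 0, 2.5), 0)
  # worked example: p = .92, lambda = 1, mu = 1, sigma = 1
  expect_equal(calibrate_thresholds(0.92, 1, 1, 1),
               1 + sqrt(2) * qnorm(0.08), tolerance = 1e-12)
  # the calibrated threshold reproduces the marginal in closed form...
  p <- 0.37; lam <- 1.2; mu <- -0.4; sg <- 1.3
  tau <- calibrate_thresholds(p, lam, mu, sg)
  expect_equal(1 - pnorm((tau - lam * mu) / sqrt(lam^2 * sg^2 + 1)), p,
               tolerance = 1e-12)
  # ...and by Monte Carlo
  set.seed(91)
  n <- 1e6
  w <- rnorm(n, mu, sg)
  expect_equal(mean(lam * w + rnorm(n) > tau), p, tolerance = 0.003)
  expect_error(calibrate_thresholds(1, 1, 0, 1), "strictly")
  expect_error(calibrate_thresholds(0, 1, 0, 1), "strictly")
})

test_that("the default spec reproduces the study design", {
  spec <- default_cohort_spec()
  expect_equal(spec$waves$n, c(547L, 755L, 617L, 820L, 1075L, 1145L))
  expect_true(all(diff(spec$waves$mu) > 0))
  panel <- cached_cohort()$panel
  counts <- panel |>
    dplyr::distinct(household_id, wave) |>
    dplyr::count(wave) |>
    dplyr::arrange(match(wave, spec$waves$wave))
  expect_equal(counts$n, spec$waves$n)

  asked <- function(it) {
    sort(unique(panel$wave[panel$item == it & panel$missing == "observed"]))
  }
  expect_equal(asked("record_player"), c("1975", "1987"))
  expect_equal(asked("washing_machine"), c("2015-16", "2017-18"))
  expect_equal(asked("radio"), sort(spec$waves$wave))

  urb <- panel |>
    dplyr::distinct(household_id, wave, stratum) |>
    dplyr::filter(stratum == "urban") |>
    dplyr::count(wave)
  expect_equal(urb$n[urb$wave == "2015-16"], 302)
  expect_equal(urb$n[urb$wave == "2017-18"], 329)
  expect_true(all(is.na(panel$stratum[panel$wave == "1967"])))
})

test_that("simulation is deterministic under the spec seed", {
  spec <- default_cohort_spec(seed = 7L, extended = FALSE)
  p1 <- simulate_panel(spec)
  p2 <- simulate_panel(spec)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  expect_identical(panel_truth(p1), panel_truth(p2))
  e1 <- simulate_external(spec, p1)
  e2 <- simulate_external(spec, p2)
  expect_identical(e1, e2)
})

test_that("simulated marginals match the calibration targets", {
  co <- cached_cohort()
  spec <- co$spec; panel <- co$panel
  obs <- panel |>
    dplyr::filter(missing == "observed", item != "rooms_per_member") |>
    dplyr::group_by(item, wave) |>
    dplyr::summarise(phat = mean(value), n = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(spec$marginals, by = c("item", "wave"))
  # ~120 cells are checked at once, so the familywise bound is 4 binomial
  # SDs, with at least 95% of cells inside the pointwise 3-SD band
  sds <- sqrt(obs$p * (1 - obs$p) / obs$n)
  z <- abs(obs$phat - obs$p) / pmax(sds, 0.5 / obs$n)
  expect_true(all(z <= 4))
  expect_gte(mean(z <= 3), 0.95)
  # latent wave means increase by construction
  tr <- panel_truth(panel)
  mw <- tapply(tr$wealth, factor(tr$wave, levels = spec$waves$wave), mean)
  expect_true(all(diff(mw) > 0))
  # crowding positive, tracks the printed per-wave means
  crw <- panel[panel$item == "rooms_per_member", ]
  expect_true(all(crw$value > 0))
  cm <- tapply(crw$value, factor(crw$wave, levels = spec$waves$wave), mean)
  expect_equal(as.numeric(cm), spec$waves$crowding_mean, tolerance = 0.05)
})

test_that("ordinal housing levels nest the binary coding", {
  panel <- cached_cohort()$panel
  ord <- panel[panel$item %in% c("floor", "roof", "walls") &
                 panel$missing == "observed", ]
  expect_true(all(ord$ordinal %in% 0:2))
  expect_equal(ord$value, as.numeric(ord$ordinal == 2))
  expect_true(any(ord$ordinal == 1))
})

test_that("external measures hit their copula targets", {
  spec <- default_cohort_spec(seed = 5L, extended = FALSE)
  panel <- simulate_panel(spec)
  ext <- simulate_external(spec, panel)
  tr <- panel_truth(panel)
  tr$wave_i <- match(tr$wave, spec$waves$wave)
  latest <- tr |>
    dplyr::group_by(household_id) |>
    dplyr::slice(which.max(wave_i)) |>
    dplyr::ungroup()
  att <- ext[ext$measure == "attained", ]
  m <- dplyr::inner_join(latest, att, by = "household_id")
  expect_equal(cor(m$wealth, m$value), 0.35, tolerance = 0.05)
  # discretization roughly preserves rank association
  expect_equal(cor(m$wealth, m$value, method = "spearman"),
               cor(m$wealth, m$value), tolerance = 0.04)

  # a zero target yields a null association
  spec0 <- default_cohort_spec(seed = 6L, extended = FALSE)
  spec0$schooling["attained"] <- 0
  p0 <- simulate_panel(spec0)
  e0 <- simulate_external(spec0, p0)
  t0 <- panel_truth(p0)
  t0$wave_i <- match(t0$wave, spec0$waves$wave)
  l0 <- t0 |> dplyr::group_by(household_id) |>
    dplyr::slice(which.max(wave_i)) |> dplyr::ungroup()
  m0 <- dplyr::inner_join(l0, e0[e0$measure == "attained", ],
                          by = "household_id")
  expect_lt(abs(cor(m0$wealth, m0$value)), 3 / sqrt(nrow(m0)))
})

test_that("cohort spec JSON round-trips the fields that drive simulation", {
  f <- withr::local_tempfile(fileext = ".json")
  spec <- default_cohort_spec(seed = 33L, extended = FALSE)
  write_cohort_spec(spec, f)
  back <- read_cohort_spec(f)
  expect_equal(back$seed, 33L)
  expect_equal(back$waves$n, spec$waves$n)
  expect_equal(back$items$lambda, spec$items$lambda)
  expect_identical(tibble::as_tibble(simulate_panel(back)),
                   tibble::as_tibble(simulate_panel(spec)))
})
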