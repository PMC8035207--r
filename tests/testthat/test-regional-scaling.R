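test_that("elevation bands are half-open intervals", {
  b <- assign_bands(c(500, 1199.9, 1200, 3511, 3599.9))
  expect_equal(as.character(b),
               c("500-1200", "500-1200", "1200-2000", "2800-3600",
                 "2800-3600"))
  expect_warning(b2 <- assign_bands(c(499, 3600)), "outside")
  expect_true(all(is.na(b2)))
})

test_that("the band bootstrap has sane degenerate and scaling behaviour", {
  out <- band_bootstrap(c(70, 70, 70), n_boot = 200, seed = 1)
  expect_equal(out$lower, 70)
  expect_equal(out$upper, 70)

  set.seed(2)
  x <- rnorm(40, 80, 15)
  out40 <- band_bootstrap(x, n_boot = 2000, seed = 3)
  expect_true(out40$lower <= out40$mean && out40$mean <= out40$upper)
  out10 <- band_bootstrap(x[1:10], n_boot = 2000, seed = 3)
  # CI width shrinks roughly as 1/sqrt(n): n 10 -> 40 is a factor ~2
  ratio <- (out10$upper - out10$lower) / (out40$upper - out40$lower)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)

  expect_warning(one <- band_bootstrap(55), "single-plot")
  expect_true(is.na(one$lower))
})

test_that("band totals apply the exact Mg/ha x km2 -> Pg conversion", {
  stocks <- data.frame(band = "500-1200", stock_initial = 100,
                       stock_final = 100)
  cover <- data.frame(band = "500-1200", cover_initial = 1, cover_final = 1)
  bt <- band_totals(stocks, cover)
  expect_equal(bt$total_initial_pg, 1e-5)
  expect_equal(bt$bands$total_initial_pg, 100 * 1 * 1e-7)
  expect_equal(bt$weighted_mean_initial, 100)
  expect_error(band_totals(stocks,
                           data.frame(band = "other", cover_initial = 1,
                                      cover_final = 1)),
               "mismatch")
})

test_that("weighted means stay within the band range and CIs propagate", {
  ab <- andes_band_summary()
  names(ab)[names(ab) == "stock_initial"] <- "stock_initial"
  bt <- band_totals(ab, ab[c("band", "cover_initial", "cover_final")])
  expect_gte(bt$weighted_mean_initial, min(ab$stock_initial))
  expect_lte(bt$weighted_mean_initial, max(ab$stock_initial))
  expect_true(all(bt$bands$total_initial_lo <= bt$bands$total_initial_pg))
  expect_true(all(bt$bands$total_initial_hi >= bt$bands$total_initial_pg))
})

test_that("deforestation emissions follow band-wise unit arithmetic", {
  stocks <- data.frame(band = "b1", stock_initial = 70)
  cover <- data.frame(band = "b1", cover_initial = 5000, cover_final = 4000)
  expect_equal(deforestation_emissions(stocks, cover),
               1000 * 100 * 70 * (44 / 12) / 1e9)
  # zero loss emits nothing; gains are flagged and contribute zero
  cover0 <- data.frame(band = "b1", cover_initial = 5000, cover_final = 5000)
  expect_equal(deforestation_emissions(stocks, cover0), 0)
  coverg <- data.frame(band = "b1", cover_initial = 5000, cover_final = 5100)
  expect_warning(e <- deforestation_emissions(stocks, coverg), "gain")
  expect_equal(e, 0)
})

test_that("plot stocks aggregate into bands under the epoch cut-year rule", {
  ps <- data.frame(
    plot_id = paste0("p", 1:6),
    elevation = c(600, 700, 1500, 1600, 2500, 3000),
    agc1 = c(80, 90, 70, 75, 60, 50),
    agc_final = c(85, 95, 72, 77, 62, 52),
    date_first = as.Date(c("2004-01-01", "2012-01-01", "2005-06-01",
                           "2006-01-01", "2008-01-01", "2007-01-01")),
    date_last = as.Date(c("2014-01-01", "2016-01-01", "2009-06-01",
                          "2013-01-01", "2015-01-01", "2014-01-01")))
  bs <- suppressWarnings(band_stocks(ps, n_boot = 100, seed = 4))
  # p2's first census is after the cut year: excluded from the initial epoch
  expect_equal(bs$n_initial[bs$band == "500-1200"], 1)
  expect_equal(bs$stock_initial[bs$band == "500-1200"], 80)
  # p3's last census is before the cut year: excluded from the final epoch
  expect_equal(bs$n_final[bs$band == "1200-2000"], 1)
  expect_equal(bs$stock_final[bs$band == "1200-2000"], 77)
  expect_equal(bs$n_initial[bs$band == "2800-3600"], 1)
})

test_that("synthetic cover tables obey the loss-rate contract", {
  ct <- generate_cover_table(c(500, 1200, 2000), c(1000, 800), c(0, 0.1))
  expect_equal(ct$cover_final, c(1000, 720))
  ct0 <- generate_cover_table(c(500, 1200), 100, 0)
  expect_equal(ct0$cover_initial, ct0$cover_final)
  expect_equal(generate_cover_table(c(500, 1200), 100, 0.10)$cover_final, 90)
  expect_error(generate_cover_table(c(500, 1200), 100, 1.2), "below 1")
  expect_error(generate_cover_table(c(500, 1200), -5, 0.1), "positive")
})
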