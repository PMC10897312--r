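test_that("flux summaries give means, conversions and CV", {
  rec <- tibble::tibble(area_label = "A", local_time = c(8, 9, 10),
                        a_umol_m2_s = 7)
  s <- flux_summary(rec)
  expect_equal(s$mean_a, 7)
  expect_equal(s$cv_pct, 0)

  rec2 <- tibble::tibble(area_label = "A", local_time = c(8, 9),
                         a_umol_m2_s = c(5, 15))
  s2 <- flux_summary(rec2)
  expect_equal(s2$mean_a, 10)
  expect_equal(s2$cv_pct, sqrt(50) / 10 * 100)  # sample SD sqrt(50)
  expect_equal(s2$cv_pct, 70.710678, tolerance = 1e-6)
  expect_equal(s2$mean_a_gC_h, umol_to_gC_per_h(10))

  # pooled mean equals the record-weighted mean of per-area means
  rec3 <- tibble::tibble(
    area_label = rep(c("A", "B"), c(3, 5)),
    local_time = 9,
    a_umol_m2_s = c(rnorm(3, 12), rnorm(5, 8))
  )
  by_area <- flux_summary(rec3, by = "area")
  pooled <- flux_summary(rec3)
  expect_equal(pooled$mean_a,
               sum(by_area$mean_a * by_area$n) / sum(by_area$n))

  expect_error(flux_summary(rec2[0, ]), "no flux records")
  neg <- tibble::tibble(area_label = "A", local_time = c(8, 9),
                        a_umol_m2_s = c(-3, 1))
  expect_error(flux_summary(neg), "mean <= 0")
})

test_that("flux unit conversion is exact and invertible", {
  # the printed field equivalence: 10.35 umol CO2 m-2 s-1 ~ 0.45 g C m-2 h-1
  expect_equal(round(umol_to_gC_per_h(10.35), 2), 0.45)
  expect_equal(umol_to_gC_per_h(10.35), 10.35e-6 * 12.011 * 3600)
  expect_equal(umol_to_gC_per_h(0), 0)
  expect_equal(umol_to_gC_per_h(1), 0.0432396)
  expect_equal(gC_per_h_to_umol(umol_to_gC_per_h(7.3)), 7.3,
               tolerance = 1e-12)
  expect_error(umol_to_gC_per_h(Inf), "finite")
})

test_that("daily canopy photosynthesis follows A * d * LAI", {
  # 10.35 umol m-2 s-1 over 11.6 h on unit LAI: 10.35e-6 * 41760 mol
  expect_equal(daily_canopy_photosynthesis(10.35, 11.6, 1),
               10.35e-6 * 11.6 * 3600)
  expect_equal(daily_canopy_photosynthesis(10.35, 11.6, 1), 0.432216,
               tolerance = 1e-9)
  expect_equal(daily_canopy_photosynthesis(10.35, 11.6, 0), 0)
  expect_equal(daily_canopy_photosynthesis(2 * 10.35, 11.6, 1.7),
               2 * daily_canopy_photosynthesis(10.35, 11.6, 1.7))
  expect_error(daily_canopy_photosynthesis(10, 11.6, -0.5), ">= 0")
})

test_that("annual per-pixel carbon matches the hand unit chain", {
  # independent chain: mol m-2 day-1 -> kg C pixel-1 yr-1 at 51.41 cm2
  pn <- 10.35e-6 * 11.6 * 3600          # mol CO2 m-2 day-1
  kg_expected <- pn * 365 * 12.011 * 51.41e-4 * 1e-3
  lai1 <- mf_grid(matrix(1, 2, 2), pixel_size = 0.1)
  cc <- carbon_constants(pixel_area = 51.41e-4)
  got <- annual_pixel_carbon(10.35, lai1, cc)
  expect_equal(got$values[1, 1], kg_expected, tolerance = 1e-12)
  expect_equal(got$values[1, 1], 0.009741, tolerance = 1e-4)

  lai0 <- mf_grid(matrix(0, 2, 2))
  expect_true(all(annual_pixel_carbon(10.35, lai0, cc)$values == 0))
  lai2 <- mf_grid(matrix(2, 2, 2))
  expect_equal(annual_pixel_carbon(10.35, lai2, cc)$values[1, 1],
               2 * kg_expected, tolerance = 1e-12)

  # pixel area falls back to pixel_size^2 from the georeference
  got_native <- annual_pixel_carbon(10.35, mf_grid(matrix(1, 2, 2),
                                                   pixel_size = 0.07),
                                    carbon_constants())
  expect_equal(attr(got_native, "pixel_area_m2"), 0.0049)
})

test_that("mangrove mask applies the three strict thresholds", {
  mk <- function(nir, red) {
    const_stack(b842 = nir, b668 = red, nrow = 2, ncol = 2)
  }
  expect_true(all(mangrove_mask(mk(0.3, 0.05))$values))   # NDVI ~ 0.71
  # thresholds are strict: a value exactly at the cut fails
  s_eq <- mk(0.3, 0.05)
  ndvi_val <- compute_index(s_eq, "NDVI")$values[1, 1]
  expect_false(any(mangrove_mask(s_eq, ndvi_min = ndvi_val)$values))
  expect_false(any(mangrove_mask(mk(0.1, 0.05))$values))   # NIR == cut
  expect_false(any(mangrove_mask(mk(0.5, 0.2))$values))    # red == cut
  expect_false(any(mangrove_mask(mk(0.09, 0.05))$values))  # NIR too low
  expect_false(any(mangrove_mask(mk(0.5, 0.25))$values))   # red too high
  s_na <- mk(0.3, 0.05); s_na$bands[["842"]][1, 1] <- NA
  expect_false(mangrove_mask(s_na)$values[1, 1])

  # raising any threshold never grows the masked area
  set.seed(606)
  rs <- random_stack(10, 10)
  base_n <- sum(mangrove_mask(rs)$values)
  for (args in list(list(ndvi_min = 0.3), list(nir_min = 0.3),
                    list(red_max = 0.1))) {
    expect_lte(sum(do.call(mangrove_mask, c(list(rs), args))$values),
               base_n)
  }
})

test_that("area aggregation reproduces totals, areas and rates", {
  # 300 x 300 pixels of 1 m2 summing to 224.0 ton C over 0.09 km2
  npix <- 300 * 300
  per_pixel_kg <- 224.0 * 1000 / npix
  carbon <- mf_grid(matrix(per_pixel_kg, 300, 300), pixel_size = 1)
  mask <- mf_grid(matrix(TRUE, 300, 300), pixel_size = 1)
  s <- area_carbon_summary(carbon, mask, carbon_constants(), label = "B")
  expect_equal(s$area_km2, 0.09)
  expect_equal(s$total_tonC_yr, 224.0)
  expect_equal(round(s$rate_tonC_km2_yr, 1), 2488.9)

  # hand sums on the 51.41 cm2 native pixel
  kg1 <- 10.35e-6 * 11.6 * 3600 * 365 * 12.011 * 51.41e-4 * 1e-3
  c100 <- mf_grid(matrix(kg1, 10, 10), pixel_size = 0.0717)
  m100 <- mf_grid(matrix(TRUE, 10, 10), pixel_size = 0.0717)
  cc <- carbon_constants(pixel_area = 51.41e-4)
  s100 <- area_carbon_summary(c100, m100, cc)
  expect_equal(s100$mangrove_pixels, 100L)
  expect_equal(s100$total_tonC_yr * 1000, 100 * kg1, tolerance = 1e-9)
  expect_equal(s100$area_km2 * 1e6, 0.5141, tolerance = 1e-12)

  # empty mask: zero total, undefined rate
  s0 <- area_carbon_summary(carbon, mf_grid(matrix(FALSE, 300, 300),
                                            pixel_size = 1),
                            carbon_constants())
  expect_equal(s0$total_tonC_yr, 0)
  expect_true(is.na(s0$rate_tonC_km2_yr))

  # totals invariant to pixel ordering (tiling/permutation)
  set.seed(9)
  v <- matrix(runif(100), 10, 10)
  msk <- matrix(runif(100) > 0.4, 10, 10)
  perm <- sample(100)
  s_a <- area_carbon_summary(mf_grid(v, pixel_size = 1),
                             mf_grid(msk, pixel_size = 1),
                             carbon_constants())
  s_b <- area_carbon_summary(mf_grid(matrix(v[perm], 10, 10),
                                     pixel_size = 1),
                             mf_grid(matrix(msk[perm], 10, 10),
                                     pixel_size = 1),
                             carbon_constants())
  expect_equal(s_a$total_tonC_yr, s_b$total_tonC_yr)
})

test_that("per-unit-LAI areal rate is the expected constant", {
  # a = 10.35, d = 11.6 give 1894.8 ton C km-2 yr-1 per unit LAI
  rate_per_lai <- 10.35e-6 * 11.6 * 3600 * 365 * 12.011  # g C m-2 yr-1
  expect_equal(rate_per_lai, 1894.8, tolerance = 1e-4)
  mean_lai <- 2.3
  carbon <- annual_pixel_carbon(10.35, mf_grid(matrix(mean_lai, 20, 20),
                                               pixel_size = 0.5),
                                carbon_constants())
  s <- area_carbon_summary(carbon, mf_grid(matrix(TRUE, 20, 20),
                                           pixel_size = 0.5),
                           carbon_constants())
  expect_equal(s$rate_tonC_km2_yr, mean_lai * rate_per_lai,
               tolerance = 1e-3)
})

test_that("average assimilation rate is the unweighted mean", {
  expect_equal(round(average_rate(c(1670.1, 2488.9, 4851.3)), 1), 3003.4)
  expect_equal(average_rate(42.5), 42.5)
  expect_equal(average_rate(c(7, 7, 7)), 7)
  expect_error(average_rate(numeric(0)), "no rates")
})
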