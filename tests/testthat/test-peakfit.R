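aCH_bands <- function() {
  tab <- default_band_table()
  tab[tab$name %in% c("aCH_2920", "aCH_2850"), ]
}

test_that("a zero spectrum yields zero amplitudes and zero RMSE", {
  g <- canonical_grid()
  s <- spectrum(g, rep(0, length(g)), stage = "blank_subtracted")
  f <- fit_window(s, aCH_bands(), c(2300, 3100))
  expect_equal(f$bands$amplitude, c(0, 0))
  expect_equal(f$rmse, 0, tolerance = 1e-12)
  expect_true(f$converged)
})

test_that("overlapping aliphatic CH bands are resolved to within 1 %", {
  g <- canonical_grid()
  truth <- tibble::tibble(
    name = c("aCH_2920", "aCH_2850"),
    amplitude = c(0.08, 0.05), center = c(2920, 2850), sigma = c(22, 20)
  )
  s <- band_spectrum(truth)
  f <- fit_window(s, aCH_bands(), c(2300, 3100))
  got <- f$bands[match(truth$name, f$bands$name), ]
  true_area <- truth$amplitude * truth$sigma * sqrt(2 * pi)
  expect_lt(max(abs(got$area / true_area - 1)), 0.01)
  expect_true(all(abs(got$center - truth$center) <= 10))
})

test_that("the OOP band height is recovered to within 1 %", {
  tab <- default_band_table()
  oop <- tab[tab$window_lo == 650, ]
  truth <- tibble::tibble(name = "rCH_oop_750", amplitude = 0.05,
                          center = 750, sigma = 8)
  f <- fit_window(band_spectrum(truth), oop, c(650, 900))
  h <- f$bands$height[f$bands$name == "rCH_oop_750"]
  expect_lt(abs(h / 0.05 - 1), 0.01)
  expect_equal(f$bands$height[f$bands$name == "nitrate_830"], 0,
               tolerance = 1e-8)
})

test_that("fitted parameters respect their bounds and the area identity", {
  truth <- full_table_truth()
  fits <- fit_all_regions(band_spectrum(truth))
  tab <- default_band_table()
  j <- match(fits$name, tab$name)
  expect_true(all(fits$amplitude >= 0))
  expect_true(all(abs(fits$center - tab$center[j]) <= tab$center_tol[j] + 1e-9))
  expect_true(all(fits$sigma >= tab$sigma_lo[j] - 1e-9 &
                    fits$sigma <= tab$sigma_hi[j] + 1e-9))
  # Gaussian area identity holds exactly for reported values
  expect_equal(fits$area, fits$amplitude * fits$sigma * sqrt(2 * pi))
})

test_that("full-table fit recovers every generating band within 5 %", {
  truth <- full_table_truth()
  fits <- fit_all_regions(band_spectrum(truth))
  j <- match(truth$name, fits$name)
  true_area <- truth$amplitude * truth$sigma * sqrt(2 * pi)
  rel <- abs(fits$area[j] / true_area - 1)
  expect_lt(max(rel), 0.05)
  expect_true(all(fits$converged))
})

test_that("fitted responses scale linearly with the spectrum", {
  truth <- full_table_truth()
  f1 <- fit_all_regions(band_spectrum(truth))
  f3 <- fit_all_regions(band_spectrum(dplyr::mutate(truth, amplitude = amplitude * 3)))
  j <- match(f1$name, f3$name)
  expect_lt(max(abs(f3$area[j] / (3 * f1$area) - 1)), 0.01)
})

test_that("a zero-amplitude extra band leaves other recoveries unchanged", {
  truth <- full_table_truth()
  without_nitrate <- dplyr::mutate(
    truth, amplitude = ifelse(name %in% c("nitrate_1400", "nitrate_830"),
                              0, amplitude))
  fits <- fit_all_regions(band_spectrum(without_nitrate))
  keep <- !fits$name %in% c("nitrate_1400", "nitrate_830")
  j <- match(fits$name[keep], truth$name)
  true_area <- truth$amplitude[j] * truth$sigma[j] * sqrt(2 * pi)
  expect_lt(max(abs(fits$area[keep] / true_area - 1)), 0.01)
  expect_lt(max(fits$area[!keep]), 1e-6)
})

test_that("fit windows validate their inputs", {
  g <- canonical_grid()
  s <- spectrum(g, rep(0, length(g)), stage = "blank_subtracted")
  expect_error(fit_window(s, aCH_bands(), c(2000, 2040)), "inside the fit window")
  tab <- default_band_table()
  tab$center[1] <- 5000
  tab$window_lo[1] <- 4900
  tab$window_hi[1] <- 5100
  expect_error(fit_all_regions(s, tab), "no fitting region")
})

test_that("acid signature needs both doublets above the noise", {
  g <- canonical_grid()
  flat <- spectrum(g, rep(0, length(g)), stage = "blank_subtracted")
  expect_false(detect_acid_signature(flat)$detected)

  noise_sd <- 0.001
  withr::with_seed(21, {
    noise <- rnorm(length(g), 0, noise_sd)
  })
  both <- gauss_ref(g, 5 * noise_sd, 2600, 30) +
    gauss_ref(g, 5 * noise_sd, 2400, 30) +
    gauss_ref(g, 20 * noise_sd, 2900, 150)
  det <- detect_acid_signature(spectrum(g, both + noise,
                                        stage = "blank_subtracted"))
  expect_true(det$detected)
  expect_gt(det$evidence$height_2600, det$evidence$threshold)

  single <- gauss_ref(g, 5 * noise_sd, 2600, 30)
  expect_false(detect_acid_signature(spectrum(g, single + noise,
                                              stage = "blank_subtracted"))$detected)
})
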