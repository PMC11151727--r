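test_that("spectrum construction validates grids and lengths", {
  s <- spectrum(c(4000, 3996), c(0, 0.1), id = "two")
  expect_s3_class(s, "ftir_spectrum")
  expect_equal(nrow(s), 2)
  expect_equal(spc_stage(s), "raw")

  expect_error(spectrum(c(4000, 3996), c(0, 0.1, 0.2)), "same length")
  expect_error(spectrum(c(2000, 2000, 1996), c(0, 0, 0)), "monotone")
  expect_error(spectrum(c(4000, 3996), c(0, NaN)), "finite")

  # the canonical acquisition grid: 4000..400 at 4 cm^-1 is 901 points
  grid <- canonical_grid()
  expect_equal(length(grid), (4000 - 400) / 4 + 1)
  expect_equal(grid[1], 4000)
  expect_equal(grid[length(grid)], 400)
})

test_that("CSV round trip preserves values to full precision", {
  g <- canonical_grid()
  s <- spectrum(g, sin(g / 300) * 0.37, id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path, id = "rt")
  expect_equal(s2$wavenumber, s$wavenumber)
  expect_equal(s2$absorbance, s$absorbance, tolerance = 1e-9)
  expect_equal(spc_stage(s2), "raw")
})

test_that("CSV reader reports the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,absorbance", "4000,0.0", "3996,abc"), path)
  expect_error(read_spectrum(path), "line 3")
  writeLines(c("wavenumber_cm-1,absorbance", "2000,0.0", "2000,0.1"), path)
  expect_error(read_spectrum(path), "monotone")
  writeLines(character(0), path)
  expect_error(read_spectrum(path), "Empty")
  expect_error(read_spectrum(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("minimal JCAMP-DX (AFFN) agrees with the CSV reader", {
  g <- seq(4000, 3960, by = -4)
  ab <- round(exp(-((g - 3980)^2) / 50) * 0.2, 6)
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic test block",
    "##JCAMP-DX=4.24",
    sprintf("##FIRSTX=%g", g[1]),
    sprintf("##LASTX=%g", g[length(g)]),
    sprintf("##NPOINTS=%d", length(g)),
    "##XYDATA=(X++(Y..Y))",
    paste(c(g[1], ab), collapse = " "),
    "##END="
  ), path)
  s <- read_spectrum(path, dialect = "jcampdx")
  expect_equal(s$wavenumber, g)
  expect_equal(s$absorbance, ab)
})

test_that("resampling is exact on affine spectra and near-exact on bands", {
  g2 <- seq(4000, 400, by = -2)
  ramp <- 0.5 - g2 / 10000
  s <- spectrum(g2, ramp)
  mid <- seq(3999, 401, by = -4)
  r <- resample_spectrum(s, mid)
  expect_equal(r$absorbance, 0.5 - mid / 10000, tolerance = 1e-12)

  # identity on same grid
  r2 <- resample_spectrum(s, g2)
  expect_equal(r2$absorbance, s$absorbance)

  # Gaussian band 2 -> 4 cm^-1 on an offset grid: interpolation error near
  # the peak stays under 0.5 % of the analytic height
  band <- spectrum(g2, gauss_ref(g2, 0.1, 2001, 12))
  tgt <- seq(3999, 401, by = -4)
  rb <- resample_spectrum(band, tgt)
  near <- abs(tgt - 2001) < 40
  err <- abs(rb$absorbance[near] - gauss_ref(tgt[near], 0.1, 2001, 12))
  expect_lt(max(err) / 0.1, 0.005)

  expect_error(resample_spectrum(s, seq(4200, 400, by = -4)), "span")
})

test_that("mean spectrum uses sample sd and supports energy weighting", {
  g <- canonical_grid()
  a <- spectrum(g, rep(0, length(g)), id = "a")
  b <- spectrum(g, rep(2, length(g)), id = "b")
  m1 <- mean_spectrum(list(a))
  expect_equal(unique(m1$sd), 0)
  expect_equal(m1$mean, a$absorbance)

  m2 <- mean_spectrum(list(a, b))
  expect_equal(unique(m2$mean), 1)
  expect_equal(unique(m2$sd), sd(c(0, 2)))  # n - 1 convention

  one <- spectrum(g, rep(1, length(g)))
  mw <- mean_spectrum(list(one), divide_by = 2)
  expect_equal(unique(mw$mean), 0.5)

  short <- spectrum(g[1:10], rep(0, 10))
  expect_error(mean_spectrum(list(a, short)), "grid")
})

test_that("mean of n copies returns the spectrum with zero sd", {
  g <- canonical_grid()
  s <- spectrum(g, sin(g / 500))
  m <- mean_spectrum(list(s, s, s))
  expect_equal(m$mean, s$absorbance)
  expect_equal(max(abs(m$sd)), 0)
})

test_that("spectra matrix drops the PTFE interference region", {
  g <- canonical_grid()
  sp <- list(a = spectrum(g, g * 0, id = "a"), b = spectrum(g, g * 0 + 1, id = "b"))
  X <- spectra_matrix(sp)
  wn <- as.numeric(colnames(X))
  expect_false(any(wn >= 1000 & wn <= 1300))
  expect_equal(rownames(X), c("a", "b"))
  X_all <- spectra_matrix(sp, exclude = NULL)
  expect_equal(ncol(X_all), length(g))
})

test_that("negative absorbances survive corrections and are flagged", {
  g <- canonical_grid()
  s <- spectrum(g, rep(c(-0.01, 0.03), length.out = length(g)),
                stage = "blank_subtracted")
  expect_equal(negative_fraction(s), 451 / 901)
  expect_lt(min(s$absorbance), 0)
})
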