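test_that("spline baseline reproduces smooth anchor-only signals", {
  g <- canonical_grid()
  x <- g / 1000
  cubic <- 0.3 + 0.1 * x - 0.02 * x^2 + 0.005 * x^3
  bl <- fit_baseline(spectrum(g, cubic), anchor_regions = list(c(400, 4000)))
  expect_lt(max(abs(bl$corrected$absorbance)), 1e-6)

  flat <- fit_baseline(spectrum(g, rep(0, length(g))))
  expect_lt(abs(flat$baseline_at_4000), 1e-8)
  expect_lt(max(abs(flat$baseline$absorbance)), 1e-8)
})

test_that("baseline correction recovers a band on a quadratic background", {
  g <- canonical_grid()
  base <- 0.2 + 0.05 * (g / 4000) + 0.03 * (g / 4000)^2
  y <- base + gauss_ref(g, 0.2, 1600, 30)
  bl <- fit_baseline(spectrum(g, y))  # default anchors exclude 1750-1450
  h <- bl$corrected$absorbance[which.min(abs(g - 1600))]
  expect_lt(abs(h - 0.2) / 0.2, 0.02)
  expect_equal(bl$baseline_at_4000, 0.28, tolerance = 1e-3)
})

test_that("baseline fitting validates anchors and smoothing", {
  g <- canonical_grid()
  s <- spectrum(g, rep(0.1, length(g)))
  expect_error(fit_baseline(s, anchor_regions = list(c(4000, 4000))),
               "grid points")
  expect_error(fit_baseline(s, smoothing = -1), "positive")
})

test_that("baseline correction is idempotent within 1 % of signal", {
  g <- canonical_grid()
  for (seed in 1:3) {
    gs <- generate_sample(default_archetypes()$red_oak, seed = seed)
    bl1 <- fit_baseline(gs$spectrum)
    twice <- fit_baseline(bl1$corrected)
    delta <- max(abs(twice$corrected$absorbance - bl1$corrected$absorbance))
    expect_lt(delta, 0.01 * max(abs(bl1$corrected$absorbance)))
  }
})

test_that("infinite smoothing tends to the least-squares line on anchors", {
  g <- canonical_grid()
  y <- 0.1 + 1e-4 * g + 1e-8 * g^2
  anchors <- list(c(3000, 4000), c(400, 1000))
  bl <- fit_baseline(spectrum(g, y), anchor_regions = anchors, smoothing = 2)
  keep <- (g >= 3000 & g <= 4000) | g <= 1000
  line <- lm(y[keep] ~ g[keep])
  pred <- coef(line)[1] + coef(line)[2] * g
  expect_lt(max(abs(bl$baseline$absorbance - pred)), 1e-3)
})

test_that("blank selection matches PTFE peak height with deterministic ties", {
  g <- canonical_grid()
  # flat-top profile makes the PTFE height exactly the nominal value
  ptfe_shape <- function(g) as.numeric(g >= 1100 & g <= 1200)
  mk <- function(h, id) spectrum(g, h * ptfe_shape(g), id = id,
                                 stage = "baselined", filter_kind = "blank")
  blanks <- list(b1 = mk(0.5, "b1"), b2 = mk(1.0, "b2"), b3 = mk(2.0, "b3"))
  sample <- mk(1.1, "s")
  expect_equal(select_blank(sample, blanks), "b2")
  expect_equal(select_blank(mk(2.0, "s"), blanks), "b3")
  # equidistant between 0.5 and 1.0 -> smallest id
  expect_equal(select_blank(mk(0.75, "s"), blanks), "b1")
  expect_error(select_blank(sample, list()), "empty")
})

test_that("blank subtraction recovers the generating scale", {
  g <- canonical_grid()
  blank <- baselined_blank(3)
  self <- subtract_blank(blank, blank)
  expect_equal(self$match$scale, 1, tolerance = 1e-9)
  expect_lt(max(abs(self$spectrum$absorbance)), 1e-9)

  signal <- gauss_ref(g, 0.1, 1600, 30)  # no support in the PTFE window
  for (s_true in c(0.3, 0.7, 2.0)) {
    samp <- spectrum(g, signal + s_true * blank$absorbance,
                     stage = "baselined")
    r <- subtract_blank(samp, blank)
    expect_lt(abs(r$match$scale - s_true), 0.01)
    expect_lt(max(abs(r$spectrum$absorbance - signal)), 1e-6)
  }

  zero <- spectrum(g, rep(0, length(g)), stage = "baselined")
  expect_error(subtract_blank(zero, zero), "energy")
})

test_that("blank subtraction is linear in added blank content", {
  g <- canonical_grid()
  blank <- baselined_blank(9)
  signal <- gauss_ref(g, 0.05, 1700, 25)
  base_scale <- subtract_blank(
    spectrum(g, signal + 0.5 * blank$absorbance, stage = "baselined"), blank
  )$match$scale
  for (cc in c(0.25, 1, 1.7)) {
    got <- subtract_blank(
      spectrum(g, signal + (0.5 + cc) * blank$absorbance, stage = "baselined"),
      blank
    )$match$scale
    expect_equal(got, base_scale + cc, tolerance = 1e-9)
  }
})

test_that("EC/OC baseline regression recovers generating coefficients", {
  set.seed(4)
  n <- 30
  ec <- runif(n, 5, 80)
  oc <- runif(n, 5, 60)
  b <- 0.002
  records <- tibble::tibble(baseline_at_4000 = 2.2 * b * ec + b * oc,
                            ec = ec, oc = oc)
  fit <- ec_baseline_regression(records)
  expect_equal(fit$ratio, 2.2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  records$ec <- 0
  expect_error(ec_baseline_regression(records), "degenerate|collinear")
  expect_error(ec_baseline_regression(records[1:2, ]), "3 records")
})
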