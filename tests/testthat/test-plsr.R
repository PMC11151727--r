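# Brute-force VIP evaluation, looped straight from the formula
# VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a ).
vip_oracle <- function(W, ssy) {
  p <- nrow(W)
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_along(ssy)) {
      acc <- acc + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    }
    out[j] <- sqrt(p * acc / sum(ssy))
  }
  out
}

test_that("a single informative column is recovered with one component", {
  withr::with_seed(10, {
    # orthonormal columns, each orthogonal to the constant (mean zero)
    X <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, -1]
  })
  y <- 3 * X[, 2]
  colnames(X) <- c("1000", "2000", "3000")
  m <- fit_plsr(X, y, n_components = 1)
  expect_lt(max(abs(m$residuals)), 1e-8)
  expect_equal(abs(m$weights[2, 1]), 1, tolerance = 1e-8)
})

test_that("full-rank NIPALS reproduces ordinary least squares", {
  withr::with_seed(11, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    beta <- c(2, -1, 0.5, 3)
    y <- drop(X %*% beta) + 1
  })
  colnames(X) <- paste(1:4)
  m <- fit_plsr(X, y, n_components = 4)
  ols <- lm(y ~ X)
  expect_lt(max(abs(m$fitted - fitted(ols))), 1e-8)
})

test_that("duplicating every sample leaves the model unchanged", {
  withr::with_seed(12, {
    X <- matrix(rnorm(10 * 5), 10, 5)
    y <- rnorm(10)
  })
  colnames(X) <- paste(1:5)
  m1 <- fit_plsr(X, y, n_components = 2)
  m2 <- fit_plsr(rbind(X, X), c(y, y), n_components = 2)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("degenerate responses are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("1", "2")))
  expect_error(fit_plsr(X, rep(1, 10)), "constant")
  expect_error(fit_plsr(X, rnorm(5)), "one value per row")
})

test_that("cross-validation picks a small model for uninformative data", {
  withr::with_seed(13, {
    X <- matrix(rnorm(30 * 12), 30, 12)
    y <- rnorm(30)
  })
  colnames(X) <- paste(seq_len(12))
  m <- fit_plsr(X, y, n_components = "cv", cv_seed = 99)
  expect_lte(m$n_components, 3)
  g <- glance(m)
  expect_gt(g$cv_rmse, 0.5 * sd(y))
})

test_that("VIP matches the brute-force formula and its normalization", {
  withr::with_seed(14, {
    X <- matrix(rnorm(12), 3, 4)
    y <- c(1.2, -0.5, 2.2)
  })
  colnames(X) <- c("700", "710", "720", "730")
  m <- fit_plsr(X, y, n_components = 1)
  v <- vip_scores(m)
  expect_equal(v$scores$vip, vip_oracle(m$weights, m$ssy), tolerance = 1e-10)
  expect_equal(sum(v$scores$vip^2), ncol(X), tolerance = 1e-10)

  # normalization identity across a range of fitted models
  withr::with_seed(15, {
    for (i in 1:5) {
      n <- sample(8:20, 1); p <- sample(4:15, 1)
      Xi <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste(1:p)))
      yi <- rnorm(n)
      mi <- fit_plsr(Xi, yi, n_components = min(3, p))
      vi <- vip_scores(mi)
      expect_equal(sum(vi$scores$vip^2), p, tolerance = 1e-8)
      expect_equal(vi$scores$vip, vip_oracle(mi$weights, mi$ssy),
                   tolerance = 1e-10)
    }
  })
})

test_that("a one-component model concentrated on one variable gives sqrt(p)", {
  # y depends on column 3 alone of an orthogonal design
  X <- diag(4)[, 1:4] * 2
  X <- rbind(X, -X)
  colnames(X) <- paste(1:4)
  y <- X[, 3]
  m <- fit_plsr(X, y, n_components = 1)
  v <- vip_scores(m)
  expect_equal(v$scores$vip[3], 2, tolerance = 1e-8)   # sqrt(p) = 2
  expect_equal(v$scores$vip[-3], rep(0, 3), tolerance = 1e-8)
  expect_equal(v$influential_bands$max_vip, 2, tolerance = 1e-8)
})

test_that("influential intervals map to named bands", {
  fake <- structure(
    list(scores = tibble::tibble(
      wavenumber = seq(4000, 400, by = -4),
      variable = seq_along(seq(4000, 400, by = -4)),
      vip = 0
    ), threshold = 1),
    class = "ftir_vip"
  )
  fake$scores$vip[fake$scores$wavenumber <= 760 &
                    fake$scores$wavenumber >= 740] <- 2
  fake$scores$vip[fake$scores$wavenumber <= 2000 &
                    fake$scores$wavenumber >= 1950] <- 1.5
  fake$influential_bands <- ftirfg:::vip_intervals(fake$scores, 1)
  rep <- band_report(fake)
  oop <- rep[rep$lo == 740, ]
  expect_match(oop$bands, "rCH_oop_750")
  expect_equal(rep$bands[rep$lo == 1952], "unassigned")
})

test_that("VIP attributes a band-built response to its generating windows", {
  # y constructed only from the aCOH and aCH bands of synthetic spectra
  study <- generate_study(30, seed = 5)
  truth <- study$truth
  processed <- purrr::imap(study$spectra, function(s, id) {
    fit_baseline(s)$corrected
  })
  X <- spectra_matrix(processed)
  y <- truth$aCOH + truth$aCH
  m <- fit_plsr(X, y, n_components = 3)
  v <- vip_scores(m)
  s <- v$scores
  in_window <- function(lo, hi) s$vip[s$wavenumber >= lo & s$wavenumber <= hi]
  expect_gt(max(in_window(3400, 3600)), 1)
  expect_gt(max(in_window(2820, 2980)), 1)
  expect_lt(max(in_window(730, 770)), 1)
})
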