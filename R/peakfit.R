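gauss <- function(x, amp, cen, sig) amp * exp(-((x - cen)^2) / (2 * sig^2))

# Sum-of-Gaussians plus local quadratic baseline, parameter vector layout:
# (amp_1..k, cen_1..k, sig_1..k, b0, b1, b2) with the polynomial on
# u = (x - mid) / halfwidth for conditioning.
multi_gauss <- function(par, x, k, mid, hw) {
  amps <- par[seq_len(k)]
  cens <- par[k + seq_len(k)]
  sigs <- par[2 * k + seq_len(k)]
  u <- (x - mid) / hw
  y <- par[3 * k + 1] + par[3 * k + 2] * u + par[3 * k + 3] * u^2
  for (i in seq_len(k)) y <- y + gauss(x, amps[i], cens[i], sigs[i])
  y
}

#' Fit fixed Gaussian bands in a spectral window
#'
#' Bounded nonlinear least squares (Levenberg--Marquardt) of a sum of
#' Gaussians plus a local quadratic residual-baseline term that absorbs
#' the smooth error left between anchor regions by the global
#' smoothing-spline baseline. Amplitudes are constrained non-negative,
#' centers to `center +/- center_tol`, and widths to their class bounds.
#' Non-convergence is flagged on the result, never thrown.
#'
#' @param x A blank-subtracted (or baselined) `ftir_spectrum`.
#' @param bands Band-table tibble (rows of [default_band_table()]); every
#'   band center must lie inside `window`.
#' @param window `c(lo, hi)` wavenumber interval to fit.
#' @return An object of class `ftir_fit`: list with `bands` (per-band
#'   tibble: amplitude, center, sigma, area = amplitude * sigma * sqrt(2*pi),
#'   height = amplitude, standard errors, `response`, `response_value`),
#'   `baseline` (b0, b1, b2), `rmse` (AU), `converged`, `window`, `id`.
#' @export
fit_window <- function(x, bands, window) {
  stopifnot(is_spectrum(x))
  bands <- tibble::as_tibble(bands)
  validate_band_table(bands)
  sel <- x$wavenumber >= min(window) & x$wavenumber <= max(window)
  if (sum(sel) < 3 * nrow(bands) + 3) {
    rlang::abort(sprintf(
      "Window [%g, %g] covers %d grid points; too few for %d bands.",
      min(window), max(window), sum(sel), nrow(bands)
    ))
  }
  if (any(bands$center < min(window) | bands$center > max(window))) {
    rlang::abort("Every band center must lie inside the fit window.")
  }
  wx <- x$wavenumber[sel]
  wy <- x$absorbance[sel]
  mid <- mean(range(wx))
  hw <- diff(range(wx)) / 2
  k <- nrow(bands)

  # Start the residual baseline near the low quantile: off-band level of a
  # blank-subtracted spectrum is ~0, and a median start biases amplitudes
  # low in windows dense with bands.
  base0 <- stats::quantile(wy, 0.1, names = FALSE)
  amp_at <- function(b0) vapply(bands$center, function(cc) {
    max(0, wy[which.min(abs(wx - cc))] - b0)
  }, 0)
  sig0 <- (bands$sigma_lo + bands$sigma_hi) / 2
  # The polynomial only absorbs small residual curvature left by the global
  # baseline; cap its coefficients so it cannot trade against broad bands.
  cap <- 0.02 + 0.05 * max(abs(wy))
  starts <- list(c(amp_at(base0), bands$center, sig0, base0, 0, 0),
                 c(amp_at(0), bands$center, sig0, 0, 0, 0))
  lower <- c(rep(0, k), bands$center - bands$center_tol, bands$sigma_lo,
             rep(-cap, 3))
  upper <- c(rep(Inf, k), bands$center + bands$center_tol, bands$sigma_hi,
             rep(cap, 3))

  resid_fn <- function(par) wy - multi_gauss(par, wx, k, mid, hw)
  ssr_fn <- function(par) sum(resid_fn(par)^2)
  grad_fn <- function(par) {
    r <- -resid_fn(par)   # model - data
    u <- (wx - mid) / hw
    gvec <- numeric(length(par))
    for (i in seq_len(k)) {
      a <- par[i]; c0 <- par[k + i]; s0 <- par[2 * k + i]
      e <- exp(-((wx - c0)^2) / (2 * s0^2))
      gvec[i] <- 2 * sum(r * e)
      gvec[k + i] <- 2 * sum(r * a * e * (wx - c0) / s0^2)
      gvec[2 * k + i] <- 2 * sum(r * a * e * (wx - c0)^2 / s0^3)
    }
    gvec[3 * k + 1] <- 2 * sum(r)
    gvec[3 * k + 2] <- 2 * sum(r * u)
    gvec[3 * k + 3] <- 2 * sum(r * u^2)
    gvec
  }

  # L-BFGS-B handles the box constraints robustly (bound clamping can stall
  # the Levenberg-Marquardt path); an LM polish from its optimum refines the
  # solution and supplies standard errors.
  fit <- NULL
  for (par0 in starts) {
    stage1 <- tryCatch(
      stats::optim(par0, ssr_fn, gr = grad_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    par1 <- if (is.null(stage1)) par0 else stage1$par
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = par1, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(cand) && !is.null(stage1)) {
      cand <- list(par = stage1$par, deviance = stage1$value, info = 1,
                   bare = TRUE)
    }
    if (!is.null(cand) &&
        (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
    if (!is.null(fit) && fit$deviance < 1e-18) break
  }
  if (is.null(fit)) {
    par <- starts[[1]]
    converged <- FALSE
    se <- rep(NA_real_, length(par))
  } else {
    par <- fit$par
    converged <- fit$info %in% 1:4 ||
      fit$deviance <= 1e-16 * (1 + sum(wy^2))
    se <- if (isTRUE(fit$bare)) rep(NA_real_, length(par)) else {
      tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
               error = function(e) rep(NA_real_, length(par)))
    }
  }

  amps <- pmax(par[seq_len(k)], 0)
  cens <- par[k + seq_len(k)]
  sigs <- par[2 * k + seq_len(k)]
  se_amp <- se[seq_len(k)]
  se_cen <- se[k + seq_len(k)]
  se_sig <- se[2 * k + seq_len(k)]
  area <- amps * sigs * sqrt(2 * pi)
  se_area <- sqrt((sigs * sqrt(2 * pi) * se_amp)^2 +
                    (amps * sqrt(2 * pi) * se_sig)^2)
  res <- resid_fn(par)
  out <- tibble::tibble(
    name = bands$name,
    amplitude = amps, center = cens, sigma = sigs,
    area = area, height = amps,
    se_amplitude = se_amp, se_center = se_cen, se_sigma = se_sig,
    se_area = se_area,
    response = bands$response,
    response_value = ifelse(bands$response == "height", amps, area)
  )
  structure(
    list(
      bands = out,
      baseline = c(b0 = par[3 * k + 1], b1 = par[3 * k + 2],
                   b2 = par[3 * k + 3]),
      rmse = sqrt(mean(res^2)),
      converged = converged,
      window = c(min(window), max(window)),
      id = spc_id(x)
    ),
    class = "ftir_fit"
  )
}

#' @export
print.ftir_fit <- function(x, ...) {
  cat(sprintf("<ftir_fit> id=%s window [%g, %g] cm^-1, RMSE %.3g AU, %s\n",
              x$id, x$window[1], x$window[2], x$rmse,
              if (x$converged) "converged" else "NOT converged"))
  print(x$bands[c("name", "amplitude", "center", "sigma", "area")])
  invisible(x)
}

#' @method tidy ftir_fit
#' @export
tidy.ftir_fit <- function(x, ...) {
  dplyr::mutate(x$bands, id = x$id, .before = 1)
}

#' @method glance ftir_fit
#' @export
glance.ftir_fit <- function(x, ...) {
  tibble::tibble(
    id = x$id, window_lo = x$window[1], window_hi = x$window[2],
    rmse = x$rmse, converged = x$converged,
    baseline_b0 = x$baseline[["b0"]], baseline_b1 = x$baseline[["b1"]],
    baseline_b2 = x$baseline[["b2"]]
  )
}

#' Fit every band region of a spectrum
#'
#' Orchestrates [fit_window()] over the default fitting regions
#' (3700--3100, 3100--2300, 1850--1350 and 900--650 cm^-1; the PTFE region
#' 1300--1000 cm^-1 is excluded by construction). The CH/acid region is
#' fitted first; the fitted broad carboxylic-acid OH Gaussian is then
#' subtracted from the working spectrum before the remaining regions are
#' fitted, because its tail reaches into the 3700--3100 cm^-1 window and
#' would otherwise bias the alcohol OH area.
#'
#' @param x A blank-subtracted `ftir_spectrum`.
#' @param band_table Band-table tibble, default [default_band_table()].
#' @param regions List of fit intervals, default [default_fit_regions()].
#' @return A tibble: one row per band (as [tidy.ftir_fit()]) plus a `region`
#'   column, with per-region `rmse` and `converged`.
#' @export
fit_all_regions <- function(x, band_table = default_band_table(),
                            regions = default_fit_regions()) {
  stopifnot(is_spectrum(x))
  validate_band_table(band_table)
  assign_region <- function(center) {
    for (i in seq_along(regions)) {
      if (center >= min(regions[[i]]) && center <= max(regions[[i]])) return(i)
    }
    NA_integer_
  }
  band_table$region_idx <- vapply(band_table$center, assign_region, 1L)
  if (anyNA(band_table$region_idx)) {
    rlang::abort(sprintf("Band %s falls in no fitting region.",
                         band_table$name[is.na(band_table$region_idx)][1]))
  }
  # CH/acid region (contains the broad OH, if defined) first, then the rest.
  broad_at <- band_table$region_idx[band_table$name == "COOH_OH_broad"]
  order_idx <- unique(c(broad_at, sort(unique(band_table$region_idx))))
  work <- x
  rows <- list()
  for (i in order_idx) {
    bands_i <- band_table[band_table$region_idx == i, ]
    fit <- fit_window(work, bands_i[names(default_band_table())], regions[[i]])
    rows[[length(rows) + 1]] <- dplyr::mutate(
      tidy(fit),
      region = sprintf("%g-%g", fit$window[2], fit$window[1]),
      region_rmse = fit$rmse, converged = fit$converged
    )
    if ("COOH_OH_broad" %in% bands_i$name) {
      b <- fit$bands[fit$bands$name == "COOH_OH_broad", ]
      tail_band <- gauss(work$wavenumber, b$amplitude, b$center, b$sigma)
      in_region <- work$wavenumber > min(regions[[i]]) &
        work$wavenumber < max(regions[[i]])
      tail_band[in_region] <- 0  # remove the tail outside the fitted window
      work <- spc_restamp(
        tibble::tibble(wavenumber = work$wavenumber,
                       absorbance = work$absorbance - tail_band),
        work
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Detect the dimerised carboxylic-acid OH signature
#'
#' The broad 3400--2400 cm^-1 acid OH carries characteristic doublets near
#' 2600 and 2400 cm^-1. Each doublet's prominence is its peak height above
#' the mean of the median levels on its two flanks (60--110 cm^-1 away), so
#' riding on the broad OH envelope or on a smooth uncorrected baseline does
#' not mask it. The signature is declared present only when both
#' prominences exceed `snr` times the noise estimate (sd of the second
#' difference in the quiet 1900--1800 cm^-1 window, scaled by sqrt(6)) and
#' an absolute floor; both-band agreement avoids triggering on single
#' interference spikes.
#'
#' @param x An `ftir_spectrum` (blank-subtracted preferred; the local
#'   detrending makes the screen usable on raw spectra too).
#' @param snr Signal-to-noise multiplier, default 3.
#' @param floor Minimum prominence in AU, default 5e-4.
#' @return List with `detected` (logical) and `evidence`, a one-row tibble
#'   (height_2600, height_2400, noise, threshold).
#' @export
detect_acid_signature <- function(x, snr = 3, floor = 5e-4) {
  stopifnot(is_spectrum(x))
  wn <- x$wavenumber
  ab <- x$absorbance
  strip <- function(lo, hi) ab[wn >= lo & wn <= hi]
  prom <- function(center, half = 40) {
    base <- mean(c(stats::median(strip(center + 60, center + 110)),
                   stats::median(strip(center - 110, center - 60))))
    max(strip(center - half, center + half)) - base
  }
  h2600 <- prom(2600)
  h2400 <- prom(2400)
  quiet <- strip(1800, 1900)
  noise <- if (length(quiet) > 4) stats::sd(diff(quiet, differences = 2)) / sqrt(6) else 0
  threshold <- max(snr * noise, floor)
  list(
    detected = isTRUE(h2600 > threshold && h2400 > threshold),
    evidence = tibble::tibble(height_2600 = h2600, height_2400 = h2400,
                              noise = noise, threshold = threshold)
  )
}
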