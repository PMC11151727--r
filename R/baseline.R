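#' Default baseline anchor regions
#'
#' Absorption-free windows used to pin the smoothing-spline baseline. They
#' avoid every vibrational band the package quantifies: the aCOH/acid OH
#' region, the CH stretches, the carbonyl/aromatic/nitrate region, the PTFE
#' region and the out-of-plane bends. When a dimerised carboxylic-acid OH
#' signature is present the 2750--2500 cm^-1 window sits on the broad acid
#' OH tail and is dropped (`drop_acid_window = TRUE`).
#'
#' @param drop_acid_window Drop the 2750--2500 cm^-1 window (set when the
#'   carboxylic-acid doublet signature is detected).
#' @return List of `c(lo, hi)` wavenumber intervals.
#' @export
default_anchor_regions <- function(drop_acid_window = FALSE) {
  regions <- list(
    c(3750, 4000),
    c(2500, 2750),
    c(1800, 1900),
    c(900, 980),
    c(620, 680)
  )
  if (drop_acid_window) regions <- regions[-2]
  regions
}

in_regions <- function(wn, regions) {
  hit <- rep(FALSE, length(wn))
  for (r in regions) hit <- hit | (wn >= min(r) & wn <= max(r))
  hit
}

#' Smoothing-spline baseline correction
#'
#' Fits a penalized cubic smoothing spline to the spectrum restricted to
#' anchor regions (windows free of organic absorption), evaluates it over
#' the full grid and subtracts it. The baseline captures light scattering by
#' the filter membrane and particles plus the broad electronic-transition
#' absorption of elemental carbon; its value at 4000 cm^-1 is retained as an
#' EC proxy for the [ec_baseline_regression()] diagnostic.
#'
#' @param x An `ftir_spectrum` (stage `"raw"`, or `"baselined"` when
#'   re-correcting).
#' @param anchor_regions List of `c(lo, hi)` wavenumber intervals; default
#'   [default_anchor_regions()].
#' @param smoothing `"auto"` (generalized cross-validation over the anchor
#'   points) or a positive `spar` value as in [stats::smooth.spline()].
#' @param drop_acid_window Passed to [default_anchor_regions()] when
#'   `anchor_regions` is not supplied; use [detect_acid_signature()] (or its
#'   raw-spectrum screen) to decide.
#' @return An object of class `ftir_baseline`: a list with `corrected`
#'   (stage `"baselined"`), `baseline`, `baseline_at_4000` (AU),
#'   `anchor_regions`, `smoothing` (the spar actually used) and
#'   `anchor_rmse` (AU, residual over anchors).
#' @export
fit_baseline <- function(x, anchor_regions = NULL, smoothing = "auto",
                         drop_acid_window = FALSE) {
  stopifnot(is_spectrum(x))
  if (is.null(anchor_regions)) {
    anchor_regions <- default_anchor_regions(drop_acid_window)
  }
  keep <- in_regions(x$wavenumber, anchor_regions)
  if (sum(keep) < 10) {
    rlang::abort(sprintf(
      "Anchor regions cover only %d grid points (need >= 10).", sum(keep)
    ))
  }
  if (!identical(smoothing, "auto")) {
    if (!is.numeric(smoothing) || smoothing <= 0) {
      rlang::abort("`smoothing` must be \"auto\" or a positive spar value.")
    }
  }
  xs <- x$wavenumber[keep]
  ys <- x$absorbance[keep]
  fit <- if (identical(smoothing, "auto")) {
    stats::smooth.spline(xs, ys, cv = FALSE, all.knots = TRUE)
  } else {
    stats::smooth.spline(xs, ys, spar = smoothing, all.knots = TRUE)
  }
  if (identical(smoothing, "auto") && length(anchor_regions) >= 3) {
    # With disjoint anchor windows a near-interpolating GCV fit amplifies
    # any trend at a window edge (e.g. a band tail touching an anchor) into
    # an overshoot across the unanchored gap; cap the effective degrees of
    # freedom at about two per window.
    df_max <- 2 * length(anchor_regions) + 2
    if (fit$df > df_max) {
      fit <- stats::smooth.spline(xs, ys, df = df_max, all.knots = TRUE)
    }
  }
  bl <- stats::predict(fit, x$wavenumber)$y
  corrected <- spectrum(x$wavenumber, x$absorbance - bl, id = spc_id(x),
                        stage = "baselined", filter_kind = spc_kind(x))
  baseline <- spectrum(x$wavenumber, bl, id = paste0(spc_id(x), "_baseline"),
                       stage = spc_stage(x), filter_kind = spc_kind(x))
  at4000 <- bl[which.max(x$wavenumber)]
  structure(
    list(
      corrected = corrected,
      baseline = baseline,
      baseline_at_4000 = at4000,
      anchor_regions = anchor_regions,
      smoothing = fit$spar,
      anchor_rmse = sqrt(mean((stats::predict(fit, xs)$y - ys)^2))
    ),
    class = "ftir_baseline"
  )
}

#' @export
print.ftir_baseline <- function(x, ...) {
  cat(sprintf(
    "<ftir_baseline> id=%s  baseline@4000 = %.4g AU, anchor RMSE = %.3g AU, spar = %.3f\n",
    spc_id(x$corrected), x$baseline_at_4000, x$anchor_rmse, x$smoothing
  ))
  invisible(x)
}

#' @method glance ftir_baseline
#' @export
glance.ftir_baseline <- function(x, ...) {
  tibble::tibble(
    id = spc_id(x$corrected),
    baseline_at_4000 = x$baseline_at_4000,
    anchor_rmse = x$anchor_rmse,
    spar = x$smoothing,
    negative_fraction = negative_fraction(x$corrected)
  )
}

#' PTFE reference-peak height
#'
#' Maximum absorbance over a window centred on the strong PTFE band near
#' 1150 cm^-1; used to match samples with blanks scanned on similar filter
#' batches.
#'
#' @param x An `ftir_spectrum`.
#' @param window `c(lo, hi)` wavenumber window.
#' @return Height in AU.
#' @export
ptfe_height <- function(x, window = c(1100, 1200)) {
  stopifnot(is_spectrum(x))
  sel <- x$wavenumber >= min(window) & x$wavenumber <= max(window)
  if (!any(sel)) rlang::abort("PTFE window does not intersect the grid.")
  max(x$absorbance[sel])
}

#' Select the best-matching blank for a sample
#'
#' Chooses, from a library of baseline-corrected blanks, the blank whose
#' PTFE reference-peak height is closest to the sample's. Ties break to the
#' lexicographically smallest blank id (deterministic).
#'
#' @param sample A baselined `ftir_spectrum`.
#' @param blanks Named list of baselined blank `ftir_spectrum` objects (names
#'   are blank ids; unnamed lists use each spectrum's own id).
#' @param window PTFE window passed to [ptfe_height()].
#' @return The selected blank id (character scalar).
#' @export
select_blank <- function(sample, blanks, window = c(1100, 1200)) {
  if (length(blanks) == 0) rlang::abort("Blank library is empty.")
  ids <- names(blanks) %||% vapply(blanks, spc_id, "")
  if (is.null(names(blanks))) names(blanks) <- ids
  h_sample <- ptfe_height(sample, window)
  h_blank <- vapply(blanks, ptfe_height, 0, window = window)
  d <- abs(h_blank - h_sample)
  best <- ids[d == min(d)]
  sort(best)[1]
}

#' Subtract a scaled blank spectrum
#'
#' Estimates the non-negative scale `s` minimising the squared residual
#' between sample and `s * blank` over the PTFE-dominated window
#' (1300--1000 cm^-1), and returns `sample - s * blank`. Fitting over the
#' whole window uses all PTFE band structure and is robust to noise; the
#' 1150 cm^-1 peak-height ratio is reported alongside as a diagnostic.
#'
#' @param sample,blank Baselined `ftir_spectrum` objects on one grid.
#' @param window Fit window, default `c(1000, 1300)` cm^-1.
#' @return List with `spectrum` (stage `"blank_subtracted"`) and `match`, a
#'   one-row tibble (blank_id, scale, height_ratio, residual_norm,
#'   ptfe_height_sample, ptfe_height_blank).
#' @export
subtract_blank <- function(sample, blank, window = c(1000, 1300)) {
  stopifnot(is_spectrum(sample), is_spectrum(blank))
  if (nrow(sample) != nrow(blank) ||
      !all(sample$wavenumber == blank$wavenumber)) {
    rlang::abort("Sample and blank must share one wavenumber grid.")
  }
  sel <- sample$wavenumber >= min(window) & sample$wavenumber <= max(window)
  bb <- sum(blank$absorbance[sel]^2)
  if (bb <= 0) {
    rlang::abort("Blank has no energy in the PTFE fit window; cannot scale.")
  }
  s <- max(0, sum(sample$absorbance[sel] * blank$absorbance[sel]) / bb)
  resid <- sample$absorbance - s * blank$absorbance
  out <- spectrum(sample$wavenumber, resid, id = spc_id(sample),
                  stage = "blank_subtracted", filter_kind = spc_kind(sample))
  hs <- ptfe_height(sample)
  hb <- ptfe_height(blank)
  match <- tibble::tibble(
    id = spc_id(sample),
    blank_id = spc_id(blank),
    scale = s,
    height_ratio = hs / hb,
    residual_norm = sqrt(sum(resid[sel]^2)),
    ptfe_height_sample = hs,
    ptfe_height_blank = hb
  )
  list(spectrum = out, match = match)
}

#' Regress the 4000 cm^-1 baseline value on EC and OC loadings
#'
#' Elemental carbon contributes to the infrared baseline through electronic
#' transition absorption, so the fitted spline baseline at 4000 cm^-1
#' carries EC information. This diagnostic fits
#' `baseline_at_4000 ~ ec + oc` by ordinary least squares and reports the
#' EC/OC coefficient ratio and R^2.
#'
#' @param records Data frame with numeric columns `baseline_at_4000` (AU),
#'   `ec` and `oc` (ug).
#' @return A one-row tibble: coef_ec, coef_oc, ratio, r_squared, n.
#' @export
ec_baseline_regression <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("baseline_at_4000", "ec", "oc")
  if (!all(need %in% names(records))) {
    rlang::abort("`records` needs columns baseline_at_4000, ec, oc.")
  }
  if (nrow(records) < 3) rlang::abort("Need at least 3 records.")
  if (stats::sd(records$ec) == 0 || stats::sd(records$oc) == 0 ||
      abs(stats::cor(records$ec, records$oc)) > 1 - 1e-12) {
    rlang::abort("EC and OC columns are degenerate or collinear.")
  }
  fit <- stats::lm(baseline_at_4000 ~ ec + oc, data = records)
  co <- stats::coef(fit)
  tibble::tibble(
    coef_ec = unname(co["ec"]),
    coef_oc = unname(co["oc"]),
    ratio = unname(co["ec"] / co["oc"]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = nrow(records)
  )
}
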