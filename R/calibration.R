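ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999)

#' Moles of aromatic CH bond in an anthracene deposit
#'
#' Anthracene (C14H10) standards deposited on PTFE filters anchor the
#' height-based calibration of the aromatic CH out-of-plane band. Each
#' anthracene molecule carries 10 CH bonds, so
#' `umol CH = mass / M(C14H10) * 10` with the molar mass computed from
#' standard atomic masses.
#'
#' @param mass_loading Areal mass loading in ug cm^-2 (must be positive).
#' @param deposit_area Deposit spot area in cm^2 (must be positive).
#' @return Moles of CH bond on the filter, in umol.
#' @export
#' @examples
#' anthracene_ch_umol(178.234, 1) # one umol of molecule -> 10 umol CH
anthracene_ch_umol <- function(mass_loading, deposit_area) {
  if (any(mass_loading <= 0) || any(deposit_area <= 0)) {
    rlang::abort("`mass_loading` and `deposit_area` must be positive.")
  }
  m_anthracene <- 14 * ATOMIC_MASS[["C"]] + 10 * ATOMIC_MASS[["H"]]
  mass_loading * deposit_area / m_anthracene * 10
}

#' Build a Beer--Lambert calibration line
#'
#' Least-squares line mapping band response (fitted peak height or area) to
#' moles of bond. Through-origin by default: a blank filter carries zero
#' analyte, so the line is forced through zero; an intercept fit is retained
#' for diagnostics. Absorbance errors are predominantly multiplicative over
#' the decades-wide loading ranges of deposit standards, so the default
#' `weighting = "proportional"` uses 1/umol^2 weights (each standard
#' contributes its response ratio); `"none"` gives ordinary least squares,
#' which is dominated by the heaviest standards. The slope is the empirical
#' absorptivity (response per umol of bond under the package's
#' normalization). R^2 is the squared correlation between observed and
#' fitted responses.
#'
#' @param standards Data frame with columns `response` (AU or AU cm^-1) and
#'   `umol` (umol of bond); at least 3 rows with distinct abscissae.
#' @param band_name Band the model calibrates.
#' @param response_kind `"height"` or `"area"`.
#' @param through_origin Force the line through the origin (default TRUE).
#' @param weighting `"proportional"` (1/umol^2, default) or `"none"`.
#' @return An object of class `ftir_calibration`.
#' @export
build_calibration <- function(standards, band_name = "rCH_oop_750",
                              response_kind = c("height", "area"),
                              through_origin = TRUE,
                              weighting = c("proportional", "none")) {
  response_kind <- match.arg(response_kind)
  weighting <- match.arg(weighting)
  standards <- tibble::as_tibble(standards)
  if (!all(c("response", "umol") %in% names(standards))) {
    rlang::abort("`standards` needs columns `response` and `umol`.")
  }
  if (nrow(standards) < 3) rlang::abort("Need at least 3 standards.")
  if (length(unique(standards$umol)) < 2) {
    rlang::abort("Standards have zero variance in abscissae.")
  }
  w <- if (weighting == "proportional") {
    if (any(standards$umol <= 0)) {
      rlang::abort("Proportional weighting requires positive abscissae.")
    }
    1 / standards$umol^2
  } else {
    rep(1, nrow(standards))
  }
  fit <- if (through_origin) {
    stats::lm(response ~ 0 + umol, data = standards, weights = w)
  } else {
    stats::lm(response ~ umol, data = standards, weights = w)
  }
  slope <- unname(stats::coef(fit)[["umol"]])
  if (slope <= 0) {
    rlang::abort("Calibration slope (absorptivity) must be positive.")
  }
  r2 <- stats::cor(standards$response, stats::fitted(fit))^2
  structure(
    list(
      band_name = band_name,
      response = response_kind,
      absorptivity = slope,
      se_absorptivity = suppressWarnings(
        summary(fit)$coefficients["umol", "Std. Error"]),
      r_squared = r2,
      n_standards = nrow(standards),
      forced_through_origin = through_origin,
      standards = standards
    ),
    class = "ftir_calibration"
  )
}

#' @export
print.ftir_calibration <- function(x, ...) {
  cat(sprintf(
    "<ftir_calibration> %s (%s): absorptivity %.4g per umol (R^2 = %.3f, n = %d%s)\n",
    x$band_name, x$response, x$absorptivity, x$r_squared, x$n_standards,
    if (x$forced_through_origin) ", through origin" else ""
  ))
  invisible(x)
}

#' @method tidy ftir_calibration
#' @export
tidy.ftir_calibration <- function(x, ...) {
  tibble::tibble(
    band_name = x$band_name, response = x$response,
    term = "absorptivity", estimate = x$absorptivity,
    std.error = x$se_absorptivity
  )
}

#' @method glance ftir_calibration
#' @export
glance.ftir_calibration <- function(x, ...) {
  tibble::tibble(
    band_name = x$band_name, response = x$response,
    absorptivity = x$absorptivity, r.squared = x$r_squared,
    n = x$n_standards, through_origin = x$forced_through_origin
  )
}

#' @method autoplot ftir_calibration
#' @export
autoplot.ftir_calibration <- function(object, ...) {
  ggplot2::ggplot(object$standards, ggplot2::aes(.data$umol, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$absorptivity,
                         intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Bond abundance (umol)",
      y = sprintf("Band %s response", object$response),
      title = sprintf("%s calibration: %.4g per umol, R^2 = %.3f",
                      object$band_name, object$absorptivity, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Default absorptivity table
#'
#' Empirical response-per-mole constants under the package normalization
#' (responses per filter deposit; moles in umol). The aromatic CH OOP value
#' 0.017 (height response per umol of CH bond) comes from an anthracene
#' standard calibration; the remaining values are configurable placeholder
#' constants in the lineage of published aerosol FTIR calibrations and
#' should be replaced by laboratory values where available.
#'
#' @return Tibble: `group`, `bands` (band names summed for the response,
#'   `+`-separated), `response`, `absorptivity`, `units`, `source`.
#' @export
default_absorptivity_table <- function() {
  tibble::tribble(
    ~group,     ~bands,                            ~response, ~absorptivity, ~units,                 ~source,
    "aCH",      "aCH_2920+aCH_2850+aCH3_2960",     "area",    4.0,           "AU cm-1 per umol CH",  "placeholder",
    "aCOH",     "aCOH_3500",                       "area",    8.0,           "AU cm-1 per umol OH",  "placeholder",
    "rCH",      "rCH_oop_750",                     "height",  0.017,         "AU per umol CH",       "anthracene standards",
    "carbonyl", "carbonyl_CO_1700",                "area",    6.0,           "AU cm-1 per umol C=O", "placeholder",
    "acid_OH",  "COOH_doublet_2600+COOH_doublet_2400", "area", 3.0,         "AU cm-1 per umol OH",  "placeholder"
  )
}

#' Read an absorptivity table CSV
#'
#' @param path CSV with the columns of [default_absorptivity_table()].
#' @return Tibble.
#' @export
read_absorptivity_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("group", "bands", "response", "absorptivity")
  if (!all(need %in% names(tab))) {
    rlang::abort(paste("Absorptivity table needs columns:",
                       paste(need, collapse = ", ")))
  }
  if (any(tab$absorptivity <= 0)) rlang::abort("Absorptivities must be positive.")
  tab
}

#' Invert a calibration: band response to moles of bond
#'
#' @param fits Tibble of fitted bands (from [fit_all_regions()] or
#'   [tidy()] of a [fit_window()] result).
#' @param model An `ftir_calibration`.
#' @return One-row tibble: `band_name`, `response_value`, `umol`, `flagged`
#'   (TRUE when a negative response was mapped to zero).
#' @export
apply_calibration <- function(fits, model) {
  stopifnot(inherits(model, "ftir_calibration"))
  row <- fits[fits$name == model$band_name, ]
  if (nrow(row) == 0) {
    rlang::abort(sprintf("Band %s not present in the fit results.",
                         model$band_name))
  }
  value <- if (model$response == "height") row$height[1] else row$area[1]
  tibble::tibble(
    band_name = model$band_name,
    response_value = value,
    umol = max(0, value) / model$absorptivity,
    flagged = value < 0
  )
}

#' Functional-group bond abundances from fitted bands
#'
#' Applies the absorptivity table to fitted band responses: aliphatic CH
#' from the summed CH-stretch areas, alcohol COH from the 3500 cm^-1 area,
#' aromatic CH from the OOP 750 cm^-1 height, and total carbonyl plus acid
#' OH, which [apportion_carbonyl()] splits into carboxylic COOH and
#' non-acid carbonyl. The acid OH is quantified from the sharp dimer
#' doublets at 2600 and 2400 cm^-1 rather than the broad 3400--2400 cm^-1
#' envelope: over a single fit window the broad envelope is nearly
#' collinear with the local residual-baseline polynomial, so its fitted
#' area is poorly identified, while the doublet areas are sharp and stable.
#' The broad envelope is still fitted (and its tail removed before the
#' 3700--3100 cm^-1 window is fitted).
#'
#' @param fits Band-fit tibble from [fit_all_regions()].
#' @param absorptivities Tibble as [default_absorptivity_table()].
#' @return Tibble: `fg` (aCH, aCOH, rCH, COOH, naCO), `umol`.
#' @export
fg_abundances <- function(fits, absorptivities = default_absorptivity_table()) {
  response_of <- function(group) {
    row <- absorptivities[absorptivities$group == group, ]
    if (nrow(row) == 0) return(NA_real_)
    bands <- strsplit(row$bands[1], "+", fixed = TRUE)[[1]]
    vals <- vapply(bands, function(b) {
      hit <- fits[fits$name == b, ]
      if (nrow(hit) == 0) {
        rlang::abort(sprintf("Band %s (needed for group %s) missing from fits.", b, group))
      }
      if (row$response[1] == "height") hit$height[1] else hit$area[1]
    }, 0)
    max(0, sum(vals)) / row$absorptivity[1]
  }
  carbonyl <- response_of("carbonyl")
  acid_oh <- response_of("acid_OH")
  split <- apportion_carbonyl(carbonyl, acid_oh)
  tibble::tibble(
    fg = c("aCH", "aCOH", "rCH", "COOH", "naCO"),
    umol = c(response_of("aCH"), response_of("aCOH"), response_of("rCH"),
             split$cooh, split$naco)
  )
}
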