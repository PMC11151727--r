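#' Default vibrational band table
#'
#' Fixed Gaussian band definitions used for multi-peak fitting. Centers
#' follow standard mid-infrared group-frequency assignments for combustion
#' aerosol on PTFE filters: alcohol OH near 3500, aromatic CH stretch near
#' 3050, aliphatic CH stretches at 2960/2920/2850, the broad dimerised
#' carboxylic-acid OH (3400--2400) with its doublets at 2600 and 2400,
#' carbonyl C=O near 1700, aromatic ring C=C at 1600, the lignin ring
#' stretch at 1515, inorganic nitrate at 1400 and 830, and the aromatic CH
#' out-of-plane (OOP) bend near 750 cm^-1. The OOP band reports fitted peak
#' height (its calibration is height-based); all other bands report area.
#' Center tolerance is 10 cm^-1 (20 for the broad OH bands); sigma bounds
#' reflect band class (sharp, medium, broad).
#'
#' @return A tibble with columns `name`, `center`, `center_tol`, `sigma_lo`,
#'   `sigma_hi`, `window_lo`, `window_hi`, `response`.
#' @export
default_band_table <- function() {
  tibble::tribble(
    ~name,               ~center, ~center_tol, ~sigma_lo, ~sigma_hi, ~window_lo, ~window_hi, ~response,
    "aCOH_3500",            3500,          20,        40,       200,       3100,       3700,   "area",
    "rCH_stretch_3050",     3050,          10,         5,        30,       2300,       3100,   "area",
    "aCH3_2960",            2960,          10,         5,        30,       2300,       3100,   "area",
    "aCH_2920",             2920,          10,         5,        30,       2300,       3100,   "area",
    "aCH_2850",             2850,          10,         5,        30,       2300,       3100,   "area",
    "COOH_OH_broad",        2900,          20,       100,       220,       2300,       3100,   "area",
    "COOH_doublet_2600",    2600,          10,        15,        60,       2300,       3100,   "area",
    "COOH_doublet_2400",    2400,          10,        15,        60,       2300,       3100,   "area",
    "carbonyl_CO_1700",     1700,          15,         5,        50,       1350,       1850,   "area",
    "aromatic_CC_1600",     1600,          10,        10,        60,       1350,       1850,   "area",
    "lignin_1515",          1515,          10,         5,        40,       1350,       1850,   "area",
    "nitrate_1400",         1400,          10,        10,        60,       1350,       1850,   "area",
    "nitrate_830",           830,          10,         5,        40,        650,        900,   "area",
    "rCH_oop_750",           750,          10,         4,        30,        650,        900,   "height"
  )
}

#' Default fitting regions
#'
#' The four windows fitted by [fit_all_regions()]. They cover the quantified
#' bands and exclude the PTFE interference region (1300--1000 cm^-1), which
#' is never used for functional-group reporting. The CH/acid region extends
#' to 2300 cm^-1 so the 2400 cm^-1 acid doublet is fitted with support on
#' both flanks.
#'
#' @return List of `c(lo, hi)` intervals.
#' @export
default_fit_regions <- function() {
  list(c(3100, 3700), c(2300, 3100), c(1350, 1850), c(650, 900))
}

#' Read or write a band table CSV
#'
#' @param path CSV file with the columns of [default_band_table()].
#' @return A band-table tibble.
#' @export
read_band_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- names(default_band_table())
  if (!all(need %in% names(tab))) {
    rlang::abort(paste("Band table must have columns:", paste(need, collapse = ", ")))
  }
  validate_band_table(tab)
  tab[need]
}

#' @rdname read_band_table
#' @param tab Band-table tibble.
#' @export
write_band_table <- function(tab, path) {
  readr::write_csv(tab, path)
  invisible(path)
}

validate_band_table <- function(tab) {
  bad <- tab$center < tab$window_lo | tab$center > tab$window_hi
  if (any(bad)) {
    rlang::abort(sprintf("Band %s has center outside its window.",
                         tab$name[bad][1]))
  }
  if (any(tab$sigma_lo <= 0 | tab$sigma_hi <= tab$sigma_lo)) {
    rlang::abort("Sigma bounds must satisfy 0 < sigma_lo < sigma_hi.")
  }
  if (any(!tab$response %in% c("area", "height"))) {
    rlang::abort("`response` must be \"area\" or \"height\".")
  }
  invisible(tab)
}
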