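# PTFE absorption template: fixed band cluster confined to 1300-1000 cm^-1,
# unit peak height. One shared template makes blank scaling well posed.
ptfe_template <- function(grid = canonical_grid()) {
  gauss(grid, 0.55, 1210, 25) + gauss(grid, 1.00, 1150, 22) +
    gauss(grid, 0.35, 1095, 28)
}

# Generator-side band shapes per functional group. Sigmas sit strictly
# inside the fit bounds of default_band_table(); responses use the same
# absorptivity constants the quantification applies, so noiseless recovery
# is an identity check of the whole chain.
generator_bands <- function(moles, extras, eps = default_absorptivity_table()) {
  eps_of <- function(g) eps$absorptivity[eps$group == g]
  area_amp <- function(area, sigma) area / (sigma * sqrt(2 * pi))
  m <- function(g) if (g %in% names(moles)) moles[[g]] else 0
  carbonyl_area <- (m("COOH") + m("naCO")) * eps_of("carbonyl")
  rows <- tibble::tribble(
    ~name,               ~center, ~sigma, ~amplitude,
    "aCOH_3500",            3500,     80, area_amp(m("aCOH") * eps_of("aCOH"), 80),
    "rCH_stretch_3050",     3050,     15, area_amp(m("rCH") * 0.3, 15),
    "aCH3_2960",            2960,     18, area_amp(m("aCH") * eps_of("aCH") * 0.2, 18),
    "aCH_2920",             2920,     22, area_amp(m("aCH") * eps_of("aCH") * 0.5, 22),
    "aCH_2850",             2850,     20, area_amp(m("aCH") * eps_of("aCH") * 0.3, 20),
    "COOH_OH_broad",        2900,    150, area_amp(m("COOH") * 12, 150),
    "COOH_doublet_2600",    2600,     30, area_amp(m("COOH") * eps_of("acid_OH") / 2, 30),
    "COOH_doublet_2400",    2400,     30, area_amp(m("COOH") * eps_of("acid_OH") / 2, 30),
    "carbonyl_CO_1700",     1700,     20, area_amp(carbonyl_area, 20),
    "aromatic_CC_1600",     1600,     30, area_amp(0.4 * m("rCH") + extras$cc1600_ec_area, 30),
    "lignin_1515",          1515,     12, area_amp(extras$lignin_area, 12),
    "nitrate_1400",         1400,     25, area_amp(extras$nitrate_area, 25),
    "nitrate_830",           830,     15, area_amp(extras$nitrate_area * 0.4, 15),
    "rCH_oop_750",           750,      8, m("rCH") * eps_of("rCH")
  )
  rows[rows$amplitude > 0, ]
}

eval_bands <- function(grid, bands) {
  y <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    y <- y + gauss(grid, bands$amplitude[i], bands$center[i], bands$sigma[i])
  }
  y
}

# Smooth scattering baseline plus carbon-loading term rising toward high
# wavenumber (electronic-transition absorption of EC; weaker OC term). The
# EC coefficient is 2.2x the OC coefficient, recoverable by the
# ec_baseline_regression diagnostic.
OC_BASELINE_COEF <- 0.002   # AU per ug OC at 4000 cm^-1
EC_BASELINE_COEF <- 2.2 * OC_BASELINE_COEF

synthetic_baseline <- function(grid, b0, b1, b2, ec_ug, oc_ug) {
  u <- grid / 4000
  b0 + b1 * u + b2 * u^2 +
    (EC_BASELINE_COEF * ec_ug + OC_BASELINE_COEF * oc_ug) * (0.4 + 0.6 * u)
}

#' Fuel archetypes for the synthetic generator
#'
#' Relative band-abundance patterns emulating combustion-aerosol spectra by
#' fuel: red oak with dominant alcohol OH (lignin/cellulose pyrolysis),
#' lignin ring stretch and occasional nitrate; kerosene dominated by
#' aromatic CH with a frequent dimerised carboxylic-acid signature;
#' charcoal with strong aliphatic CH and high, variable EC; alcohol and LPG
#' near blank level. Abundances are lognormal (positive, right-skewed, as
#' emission-factor distributions are); `mean_umol` are arithmetic means and
#' `gsd` geometric standard deviations; samples without the acid signature
#' (probability `1 - acid_prob`) carry only 5 % of the drawn COOH, so the
#' COOH means are inflated to keep the across-sample average at the level
#' implied by typical OM/OC ratios (about 1.7 for red oak, 1.8 for
#' kerosene, 1.6 for charcoal). EC levels are set so the red-oak EC/TC
#' ratio centres near 0.58.
#'
#' @return Named list of archetype lists.
#' @export
default_archetypes <- function() {
  list(
    red_oak = list(
      fuel = "red_oak",
      mean_umol = c(aCH = 1.5, aCOH = 0.7, rCH = 0.5, COOH = 0.30, naCO = 0.30),
      gsd = 1.8, ec_mean = 58, ec_gsd = 1.6, acid_prob = 0.3,
      lignin_area = 0.3, nitrate_prob = 0.4, nitrate_area = 0.3,
      stoves = c("three_stone", "rocket_ND", "gasifier_FD")
    ),
    kerosene = list(
      fuel = "kerosene",
      mean_umol = c(aCH = 0.25, aCOH = 0.45, rCH = 0.9, COOH = 0.30, naCO = 0.10),
      gsd = 1.8, ec_mean = 12, ec_gsd = 1.8, acid_prob = 0.8,
      lignin_area = 0, nitrate_prob = 0, nitrate_area = 0,
      stoves = c("wick", "pressure")
    ),
    charcoal = list(
      fuel = "charcoal",
      mean_umol = c(aCH = 1.6, aCOH = 0.45, rCH = 0.35, COOH = 0.21, naCO = 0.10),
      gsd = 1.8, ec_mean = 25, ec_gsd = 2.2, acid_prob = 0.2,
      lignin_area = 0, nitrate_prob = 0, nitrate_area = 0,
      stoves = c("charcoal_jiko", "charcoal_improved")
    ),
    alcohol = list(
      fuel = "alcohol",
      mean_umol = c(aCH = 0.02, aCOH = 0.02, rCH = 0.005, COOH = 0.005, naCO = 0.005),
      gsd = 1.5, ec_mean = 0.5, ec_gsd = 1.5, acid_prob = 0,
      lignin_area = 0, nitrate_prob = 0, nitrate_area = 0,
      stoves = c("alcohol_stove")
    ),
    lpg = list(
      fuel = "lpg",
      mean_umol = c(aCH = 0.02, aCOH = 0.01, rCH = 0.005, COOH = 0.005, naCO = 0.005),
      gsd = 1.5, ec_mean = 0.5, ec_gsd = 1.5, acid_prob = 0,
      lignin_area = 0, nitrate_prob = 0, nitrate_area = 0,
      stoves = c("lpg_stove")
    )
  )
}

rlnorm_mean <- function(n, mean, gsd) {
  sdlog <- log(gsd)
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic blank filter spectrum
#'
#' Smooth low-order scattering curve plus the fixed PTFE band cluster at a
#' randomized overall intensity, plus white noise. Deterministic given the
#' seed.
#'
#' @param seed Integer seed.
#' @param id Blank id.
#' @param noise_sd Gaussian noise sd in AU.
#' @return An `ftir_spectrum` (stage raw, filter_kind blank) with attribute
#'   `ptfe_intensity`.
#' @export
generate_blank <- function(seed, id = sprintf("blank%03d", seed),
                           noise_sd = 0) {
  grid <- canonical_grid()
  withr::with_seed(seed, {
    intensity <- stats::rlnorm(1, 0, 0.25)
    b0 <- stats::runif(1, 0.03, 0.10)
    b1 <- stats::runif(1, -0.02, 0.02)
    b2 <- stats::runif(1, 0, 0.02)
    ab <- synthetic_baseline(grid, b0, b1, b2, 0, 0) +
      intensity * ptfe_template(grid) +
      stats::rnorm(length(grid), 0, noise_sd)
    s <- spectrum(grid, ab, id = id, stage = "raw", filter_kind = "blank")
    attr(s, "ptfe_intensity") <- intensity
    s
  })
}

#' Generate one synthetic sample spectrum with its ground truth
#'
#' Forward model: EC/OC-dependent smooth baseline + scaled PTFE template +
#' Gaussian functional-group bands drawn from the archetype's lognormal
#' abundances + white noise. The truth record carries every generating
#' value so recovery tests are exact.
#'
#' The spectroscopically visible functional groups account for only part of
#' the organic carbon (uncharacterised groups and skeletal carbon carry the
#' rest), so the sample's total OC is `oc * (1 + oc_excess)`; the baseline's
#' carbon term and the pseudo-reference OC are tied to this total.
#'
#' @param archetype One element of [default_archetypes()].
#' @param seed Integer seed (full determinism).
#' @param id Sample id.
#' @param noise_sd Gaussian noise sd in AU.
#' @param oc_excess Relative OC carried by carbon invisible to the
#'   functional-group analysis; default 0.67.
#' @return List with `spectrum` (stage raw) and `truth` (one-row tibble,
#'   including both `oc`, the group-visible OC, and `oc_total`).
#' @export
generate_sample <- function(archetype, seed, id = sprintf("sample%03d", seed),
                            noise_sd = 0, oc_excess = 0.67) {
  if (!all(c("mean_umol", "gsd", "ec_mean", "ec_gsd") %in% names(archetype))) {
    rlang::abort("Invalid archetype: needs mean_umol, gsd, ec_mean, ec_gsd.")
  }
  grid <- canonical_grid()
  withr::with_seed(seed, {
    moles <- vapply(archetype$mean_umol, function(m) {
      if (m <= 0) 0 else rlnorm_mean(1, m, archetype$gsd)
    }, 0)
    acid <- stats::runif(1) < (archetype$acid_prob %||% 0)
    if (!acid) moles[["COOH"]] <- moles[["COOH"]] * 0.05
    ec <- rlnorm_mean(1, archetype$ec_mean, archetype$ec_gsd)
    has_nitrate <- stats::runif(1) < (archetype$nitrate_prob %||% 0)
    extras <- list(
      lignin_area = if ((archetype$lignin_area %||% 0) > 0) {
        rlnorm_mean(1, archetype$lignin_area, 1.5)
      } else 0,
      nitrate_area = if (has_nitrate) {
        rlnorm_mean(1, archetype$nitrate_area, 1.5)
      } else 0,
      cc1600_ec_area = 0.01 * ec
    )
    oc_true <- sum(moles * default_attribution_table()$carbon_per_bond[
      match(names(moles), default_attribution_table()$fg)
    ]) * ATOMIC_MASS[["C"]]
    oc_total <- oc_true * (1 + oc_excess)
    b0 <- stats::runif(1, 0.05, 0.12)
    b1 <- stats::runif(1, -0.02, 0.02)
    b2 <- stats::runif(1, 0, 0.02)
    ptfe_intensity <- stats::rlnorm(1, 0, 0.15)
    bands <- generator_bands(as.list(moles), extras)
    ab <- synthetic_baseline(grid, b0, b1, b2, ec, oc_total) +
      ptfe_intensity * ptfe_template(grid) +
      eval_bands(grid, bands) +
      stats::rnorm(length(grid), 0, noise_sd)
    truth <- tibble::tibble(
      id = id, fuel = archetype$fuel %||% NA_character_,
      aCH = moles[["aCH"]], aCOH = moles[["aCOH"]], rCH = moles[["rCH"]],
      COOH = moles[["COOH"]], naCO = moles[["naCO"]],
      oc = oc_true, oc_total = oc_total,
      pah = pah_mass(moles[["rCH"]]),
      ec = ec, acid = acid,
      ptfe_intensity = ptfe_intensity,
      b0 = b0, b1 = b1, b2 = b2,
      baseline_at_4000 = synthetic_baseline(4000, b0, b1, b2, ec, oc_total),
      lignin_area = extras$lignin_area, nitrate_area = extras$nitrate_area,
      noise_sd = noise_sd, seed = seed
    )
    list(
      spectrum = spectrum(grid, ab, id = id, stage = "raw"),
      truth = truth
    )
  })
}

#' Generate a full synthetic study
#'
#' Spectra, a blank library, sample metadata and collocated pseudo-reference
#' tables (thermal-optical OC/EC, gravimetric PM2.5, summed GC--MS PAH),
#' self-consistent and keyed by sample id, fully reproducible from the
#' seed. The pseudo-reference generators mirror the structure of collocated
#' measurements: reference OC is the spectroscopically visible OC inflated
#' by `delta_oc` (default 0.67, i.e. functional-group OC recovers ~60 % of
#' reference OC) with lognormal noise and a back-filter adsorption
#' artifact; the GC--MS PAH sum is the infrared PAH mass divided by
#' `pah_slope_k` (default 19.6: the targeted compound panel captures a
#' small fraction of total aromatic mass). GC--MS values are produced for
#' kerosene and red-oak samples only.
#'
#' @param n Number of samples.
#' @param archetype_weights Named sampling weights over
#'   [default_archetypes()]; default mirrors the study fuel mix (red oak
#'   69, charcoal 56, kerosene 21, alcohol 3, LPG 3 of 152).
#' @param delta_oc Relative reference-OC inflation.
#' @param pah_slope_k FTIR-to-GC-MS PAH ratio.
#' @param noise_sd Spectral noise sd (AU), default 0.002.
#' @param oc_ref_rel,ec_ref_rel,pah_ref_rel Relative lognormal noise of the
#'   reference tables.
#' @param n_blanks Size of the blank library.
#' @param seed Integer seed.
#' @return List: `spectra` (named list), `blanks` (named list), `meta`,
#'   `references`, `truth` (tibbles).
#' @export
generate_study <- function(n, archetype_weights = NULL,
                           delta_oc = 0.67, pah_slope_k = 19.6,
                           noise_sd = 0.002,
                           oc_ref_rel = 0.15, ec_ref_rel = 0.1,
                           pah_ref_rel = 0.15,
                           n_blanks = 6, seed = 1L) {
  arch <- default_archetypes()
  if (is.null(archetype_weights)) {
    archetype_weights <- c(red_oak = 69, charcoal = 56, kerosene = 21,
                           alcohol = 3, lpg = 3) / 152
  }
  stopifnot(all(names(archetype_weights) %in% names(arch)))
  if (n == 0) {
    return(list(spectra = list(), blanks = list(),
                meta = tibble::tibble(), references = tibble::tibble(),
                truth = tibble::tibble()))
  }
  plan <- withr::with_seed(seed, {
    fuels <- sample(names(archetype_weights), n, replace = TRUE,
                    prob = archetype_weights)
    tibble::tibble(
      idx = seq_len(n),
      fuel = fuels,
      phase = sample(c("CS", "HS", "SIM"), n, replace = TRUE),
      stove = vapply(fuels, function(f) sample(arch[[f]]$stoves, 1), ""),
      energy_delivered = round(stats::runif(n, 2, 10), 2),
      tunnel_flow = sample(c(4.0, 26.8), n, replace = TRUE,
                           prob = c(0.6, 0.4)),
      sample_flow = 16.7,
      duration = round(stats::runif(n, 30, 120)),
      deposit_area = 11.95,
      sample_seed = sample.int(2^30, n)
    )
  })
  ids <- sprintf("S%03d", plan$idx)
  samples <- purrr::map2(seq_len(n), plan$sample_seed, function(i, s) {
    generate_sample(arch[[plan$fuel[i]]], seed = s, id = ids[i],
                    noise_sd = noise_sd, oc_excess = delta_oc)
  })
  truth <- purrr::map_dfr(samples, "truth")
  spectra <- stats::setNames(purrr::map(samples, "spectrum"), ids)
  blanks <- stats::setNames(
    purrr::map(seq_len(n_blanks), function(i) {
      generate_blank(seed + 7000 + i, id = sprintf("B%02d", i),
                     noise_sd = noise_sd)
    }),
    sprintf("B%02d", seq_len(n_blanks))
  )
  references <- withr::with_seed(seed + 1L, {
    lnoise <- function(rel) {
      if (rel <= 0) rep(1, n) else stats::rlnorm(n, -log(1 + rel^2) / 2,
                                                 sqrt(log(1 + rel^2)))
    }
    oc_corrected <- truth$oc_total * lnoise(oc_ref_rel)
    back_ratio <- pmin(stats::rlnorm(n, log(0.2), 0.6), 1.79)
    pah_ref <- truth$pah / pah_slope_k * lnoise(pah_ref_rel)
    pah_ref[!truth$fuel %in% c("kerosene", "red_oak")] <- NA_real_
    tibble::tibble(
      id = ids,
      oc_front = oc_corrected * (1 + back_ratio),
      oc_back = oc_corrected * back_ratio,
      ec = truth$ec * lnoise(ec_ref_rel),
      pm25_mass = (truth$oc_total + truth$ec) * 1.05,
      pah_total = pah_ref
    )
  })
  meta <- dplyr::bind_cols(tibble::tibble(id = ids),
                           plan[c("fuel", "stove", "phase", "energy_delivered",
                                  "sample_flow", "tunnel_flow", "duration",
                                  "deposit_area")])
  list(spectra = spectra, blanks = blanks, meta = meta,
       references = references, truth = truth)
}

#' Generate synthetic anthracene calibration standards
#'
#' Emulates a set of anthracene (C14H10) deposits on PTFE filters used to
#' calibrate the aromatic CH out-of-plane band: areal mass loadings are
#' log-spaced over the given range, converted to CH bond moles, and the
#' height response is `absorptivity * umol` with multiplicative lognormal
#' noise.
#'
#' @param n Number of standards (default 12).
#' @param absorptivity True height response per umol CH (default 0.017).
#' @param loading_range Areal loading range in ug cm^-2, default
#'   `c(26.8, 1040)`.
#' @param deposit_area Deposit spot area in cm^2; default 0.785 (a 1 cm
#'   diameter masked spot).
#' @param rel_noise Relative response noise (lognormal), default 0.
#' @param seed Integer seed.
#' @return Tibble with `loading`, `umol`, `response`.
#' @export
generate_standards <- function(n = 12, absorptivity = 0.017,
                               loading_range = c(26.8, 1040),
                               deposit_area = 0.785,
                               rel_noise = 0, seed = 1L) {
  loading <- exp(seq(log(loading_range[1]), log(loading_range[2]),
                     length.out = n))
  umol <- anthracene_ch_umol(loading, deposit_area)
  fac <- if (rel_noise > 0) {
    withr::with_seed(seed, stats::rlnorm(n, -log(1 + rel_noise^2) / 2,
                                         sqrt(log(1 + rel_noise^2))))
  } else {
    rep(1, n)
  }
  tibble::tibble(loading = loading, umol = umol,
                 response = absorptivity * umol * fac)
}

#' Write a synthetic study to disk in the pipeline input layout
#'
#' Creates `spectra/<id>.csv`, `blanks/<id>.csv`, `blanks/index.csv`,
#' `meta.csv`, `references.csv` and `truth.csv` under `dir`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "blanks"), recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(study$spectra, function(s, id) {
    write_spectrum(s, file.path(dir, "spectra", paste0(id, ".csv")))
  })
  purrr::iwalk(study$blanks, function(s, id) {
    write_spectrum(s, file.path(dir, "blanks", paste0(id, ".csv")))
  })
  readr::write_csv(tibble::tibble(blank_id = names(study$blanks), batch = "synthetic"),
                   file.path(dir, "blanks", "index.csv"))
  readr::write_csv(study$meta, file.path(dir, "meta.csv"))
  readr::write_csv(study$references, file.path(dir, "references.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
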