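#' Default carbon and mass attribution table
#'
#' Converts moles of bond (or group) to organic carbon and organic matter
#' with minimal structural assumptions: aliphatic CH as methylene (half a
#' carbon and one hydrogen per CH bond); aromatic CH with an effective
#' C/H molar ratio of 1.4 (anthracene-like, consistent with the PAH
#' conversion); alcohol COH, carboxylic COOH and non-acid carbonyl each
#' carrying one carbon plus their oxygen/hydrogen payloads. Every group's
#' OM mass exceeds the mass of its attributed carbon, so OM >= OC holds for
#' any non-negative abundance vector. Composition outputs record the table
#' hash so results are traceable to the constants that produced them.
#'
#' @return Tibble: `fg`, `carbon_per_bond` (mol C per mol bond),
#'   `om_mass_per_bond` (g per mol bond).
#' @export
default_attribution_table <- function() {
  tibble::tribble(
    ~fg,    ~carbon_per_bond, ~om_mass_per_bond,
    "aCH",  0.5,              7.014,   # CH2 assumption: (C + 2H) / 2 bonds
    "rCH",  1.4,              17.823,  # H + 1.4 C, anthracene-like
    "aCOH", 1.0,              29.018,  # C + O + H
    "COOH", 1.0,              45.017,  # C + 2 O + H
    "naCO", 1.0,              28.010   # C + O
  )
}

attribution_hash <- function(tab) {
  dat <- paste(tab$fg, format(tab$carbon_per_bond, digits = 12),
               format(tab$om_mass_per_bond, digits = 12), collapse = ";")
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(dat)
  h <- 97
  for (b in bytes) h <- (h * 131 + b) %% 900000011
  sprintf("%09d", h)
}

#' Organic carbon, organic matter and OM/OC from bond abundances
#'
#' `oc = sum(umol * carbon_per_bond) * 12.011` and
#' `om = sum(umol * om_mass_per_bond)`, both in ug when abundances are in
#' umol. OM/OC is reported as `NA` (missing, not an error) when all
#' abundances are zero.
#'
#' @param abundances Tibble with columns `fg` and `umol` (non-negative).
#' @param table Attribution table, default [default_attribution_table()].
#' @return One-row tibble: `oc`, `om`, `om_oc`, per-group OM contributions
#'   (`om_<fg>`), `attribution_hash`.
#' @export
fg_to_oc_om <- function(abundances, table = default_attribution_table()) {
  abundances <- tibble::as_tibble(abundances)
  if (any(abundances$umol < 0, na.rm = TRUE)) {
    rlang::abort("Abundances must be non-negative.")
  }
  if (any(table$om_mass_per_bond <= 12.011 * table$carbon_per_bond)) {
    rlang::abort("Attribution table violates om_mass_per_bond > 12.011 * carbon_per_bond.")
  }
  joined <- dplyr::inner_join(abundances, table, by = "fg")
  if (nrow(joined) < nrow(abundances)) {
    missing <- setdiff(abundances$fg, table$fg)
    rlang::abort(paste("No attribution row for group(s):",
                       paste(missing, collapse = ", ")))
  }
  oc <- sum(joined$umol * joined$carbon_per_bond) * ATOMIC_MASS[["C"]]
  om_parts <- joined$umol * joined$om_mass_per_bond
  om <- sum(om_parts)
  out <- tibble::tibble(
    oc = oc, om = om,
    om_oc = if (oc > 0) om / oc else NA_real_
  )
  contrib <- stats::setNames(as.list(om_parts), paste0("om_", joined$fg))
  dplyr::bind_cols(out, tibble::as_tibble(contrib),
                   tibble::tibble(attribution_hash = attribution_hash(table)))
}

#' PAH mass from aromatic CH bond abundance
#'
#' Each measured aromatic CH bond is assigned one hydrogen plus an
#' effective 1.4 carbon atoms (the C/H molar ratio of anthracene, C14H10),
#' accounting for ring carbons that carry no hydrogen:
#' `mass = umol * (1.008 + c_to_h * 12.011)` ug.
#'
#' @param rch_umol Aromatic CH bond abundance, umol (non-negative).
#' @param c_to_h Effective C/H molar ratio, default 1.4.
#' @return Mass in ug.
#' @export
pah_mass <- function(rch_umol, c_to_h = 1.4) {
  if (any(rch_umol < 0)) rlang::abort("`rch_umol` must be non-negative.")
  if (c_to_h <= 0) rlang::abort("`c_to_h` must be positive.")
  rch_umol * (ATOMIC_MASS[["H"]] + c_to_h * ATOMIC_MASS[["C"]])
}

#' Back-filter artifact correction
#'
#' Subtracts the quartz back-filter value (vapour adsorption artifact) from
#' the front-filter value. Negative results are retained and flagged, never
#' clipped: back/front ratios above 1 occur in practice for semivolatile
#' material.
#'
#' @param front,back Masses in ug.
#' @return Tibble: `corrected` (ug), `flagged` (negative result).
#' @export
artifact_correct <- function(front, back) {
  corrected <- front - back
  tibble::tibble(corrected = corrected, flagged = corrected < 0)
}

#' Emission factor per megajoule of energy delivered
#'
#' Scales the filter deposit up to the dilution tunnel
#' (`tunnel_flow / sample_flow`, with the L vs m^3 conversion handled
#' internally) and divides by the energy delivered to the pot:
#' `EF = mass * (tunnel_flow * 1000 / sample_flow) / energy` reported in
#' mg MJ^-1 for mass in ug.
#'
#' @param mass_ug Mass on the filter deposit, ug.
#' @param sample_flow Filter sampling flow, L min^-1 (> 0).
#' @param tunnel_flow Dilution tunnel flow, m^3 min^-1 (> 0).
#' @param energy_mj Energy delivered to the pot, MJ (> 0).
#' @return Emission factor in mg MJ^-1.
#' @export
#' @examples
#' emission_factor(1000, sample_flow = 16.7, tunnel_flow = 4.0, energy_mj = 5)
emission_factor <- function(mass_ug, sample_flow, tunnel_flow, energy_mj) {
  if (any(sample_flow <= 0) || any(tunnel_flow <= 0) || any(energy_mj <= 0)) {
    rlang::abort("Flows and energy must be positive.")
  }
  dilution <- tunnel_flow * 1000 / sample_flow    # both in L min^-1
  mass_ug * dilution / energy_mj / 1000           # ug -> mg
}

#' Split total carbonyl into carboxylic and non-acid carbonyl
#'
#' Every carboxylic acid contributes one C=O and one (dimerised) OH, so the
#' acid OH abundance caps the carboxylic share of the fitted carbonyl:
#' `cooh = min(carbonyl, acid_oh)`, `naco = carbonyl - cooh`. Conserves
#' carbonyl moles by construction.
#'
#' @param carbonyl_umol Total fitted carbonyl C=O, umol (non-negative).
#' @param acid_oh_umol Acid OH abundance, umol (non-negative).
#' @return Tibble: `cooh`, `naco` (umol).
#' @export
apportion_carbonyl <- function(carbonyl_umol, acid_oh_umol) {
  if (any(carbonyl_umol < 0) || any(acid_oh_umol < 0)) {
    rlang::abort("Inputs must be non-negative.")
  }
  cooh <- pmin(carbonyl_umol, acid_oh_umol)
  tibble::tibble(cooh = cooh, naco = carbonyl_umol - cooh)
}

#' Full composition of one sample
#'
#' Combines bond abundances, the attribution table and sample metadata into
#' OC, OM, OM/OC, PAH mass, per-group OM contributions, EC/TC (when an EC
#' value is supplied) and emission factors for OM, OC and PAH.
#'
#' @param abundances Tibble (`fg`, `umol`) as from [fg_abundances()].
#' @param meta One-row data frame with `sample_flow` (L min^-1),
#'   `tunnel_flow` (m^3 min^-1), `energy_delivered` (MJ); optional.
#' @param ec_ug Collocated elemental-carbon mass (ug), optional.
#' @param table Attribution table.
#' @param c_to_h Effective C/H ratio for the PAH conversion.
#' @return One-row tibble with oc, om, om_oc, pah_mass, om_* contributions,
#'   ec_tc and ef_* columns (NA where inputs are missing).
#' @export
compose_sample <- function(abundances, meta = NULL, ec_ug = NA_real_,
                           table = default_attribution_table(),
                           c_to_h = 1.4) {
  base <- fg_to_oc_om(abundances, table)
  rch <- abundances$umol[abundances$fg == "rCH"]
  base$pah_mass <- if (length(rch)) pah_mass(rch[1], c_to_h) else NA_real_
  base$ec_tc <- if (is.finite(ec_ug) && (ec_ug + base$oc) > 0) {
    ec_ug / (ec_ug + base$oc)
  } else NA_real_
  if (!is.null(meta)) {
    ef <- function(m) emission_factor(m, meta$sample_flow[1],
                                      meta$tunnel_flow[1],
                                      meta$energy_delivered[1])
    base$ef_om <- ef(base$om)
    base$ef_oc <- ef(base$oc)
    base$ef_pah <- ef(base$pah_mass)
  } else {
    base$ef_om <- base$ef_oc <- base$ef_pah <- NA_real_
  }
  base
}

#' Compare FTIR and GC--MS PAH estimates
#'
#' Through-origin regression of per-sample FTIR (OOP-band derived) PAH mass
#' on the summed GC--MS PAH mass over paired sample ids, reporting the
#' slope, R^2 (squared correlation of observed and fitted) and the ratio of
#' totals. A slope well above 1 is expected when the infrared band responds
#' to aromatic compounds that the targeted GC--MS panel does not measure.
#'
#' @param ftir Data frame with columns `id` and `pah_ftir` (ug).
#' @param gcms Data frame with columns `id` and `pah_gcms` (ug).
#' @return One-row tibble: slope, r_squared, ratio_of_totals, n.
#' @export
compare_pah_estimates <- function(ftir, gcms) {
  joined <- dplyr::inner_join(tibble::as_tibble(ftir),
                              tibble::as_tibble(gcms), by = "id")
  if (nrow(joined) < 3) {
    rlang::abort("Fewer than 3 paired samples between FTIR and GC-MS tables.")
  }
  fit <- stats::lm(pah_ftir ~ 0 + pah_gcms, data = joined)
  tibble::tibble(
    slope = unname(stats::coef(fit)[["pah_gcms"]]),
    r_squared = stats::cor(joined$pah_ftir, stats::fitted(fit))^2,
    ratio_of_totals = sum(joined$pah_ftir) / sum(joined$pah_gcms),
    n = nrow(joined)
  )
}
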