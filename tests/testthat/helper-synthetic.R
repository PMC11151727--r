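# Shared fixtures built in code.

gauss_ref <- function(x, amp, cen, sig) amp * exp(-((x - cen)^2) / (2 * sig^2))

# A band-only spectrum (no baseline, no PTFE) on the canonical grid from a
# table of (name, amplitude, center, sigma); the table is the oracle.
band_spectrum <- function(truth, id = "bands", stage = "blank_subtracted") {
  g <- canonical_grid()
  y <- numeric(length(g))
  for (i in seq_len(nrow(truth))) {
    y <- y + gauss_ref(g, truth$amplitude[i], truth$center[i], truth$sigma[i])
  }
  spectrum(g, y, id = id, stage = stage)
}

# Generating amplitudes for every band in the default table, scaled so the
# spectrum resembles a wood-smoke deposit; sigmas sit inside the fit bounds.
full_table_truth <- function(scale = 1) {
  tibble::tribble(
    ~name,               ~amplitude, ~center, ~sigma,
    "aCOH_3500",             0.030,     3500,     80,
    "rCH_stretch_3050",      0.004,     3050,     15,
    "aCH3_2960",             0.012,     2960,     18,
    "aCH_2920",              0.030,     2920,     22,
    "aCH_2850",              0.018,     2850,     20,
    "COOH_OH_broad",         0.008,     2900,    150,
    "COOH_doublet_2600",     0.006,     2600,     30,
    "COOH_doublet_2400",     0.006,     2400,     30,
    "carbonyl_CO_1700",      0.040,     1700,     20,
    "aromatic_CC_1600",      0.020,     1600,     30,
    "lignin_1515",           0.010,     1515,     12,
    "nitrate_1400",          0.008,     1400,     25,
    "nitrate_830",           0.004,      830,     15,
    "rCH_oop_750",           0.010,      750,      8
  ) |>
    dplyr::mutate(amplitude = amplitude * scale)
}

baselined_blank <- function(seed, id = sprintf("B%02d", seed)) {
  fit_baseline(generate_blank(seed, id = id))$corrected
}
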