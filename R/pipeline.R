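#' Default pipeline parameters
#'
#' @return Named list of processing parameters: anchor regions, smoothing,
#'   PTFE window, band/absorptivity/attribution tables, PAH C/H ratio, VIP
#'   settings.
#' @export
default_pipeline_params <- function() {
  list(
    anchor_regions = default_anchor_regions(),
    smoothing = "auto",
    ptfe_window = c(1000, 1300),
    band_table = default_band_table(),
    absorptivities = default_absorptivity_table(),
    attribution = default_attribution_table(),
    c_to_h = 1.4,
    vip_components = "cv",
    vip_threshold = 1,
    vip_cv_seed = 1L
  )
}

process_sample <- function(raw, blanks_baselined, ref_row, meta_row, params) {
  screen <- detect_acid_signature(raw)
  anchors <- if (screen$detected) {
    default_anchor_regions(drop_acid_window = TRUE)
  } else {
    params$anchor_regions
  }
  bl <- fit_baseline(raw, anchor_regions = anchors,
                     smoothing = params$smoothing)
  blank_id <- select_blank(bl$corrected, blanks_baselined)
  sub <- subtract_blank(bl$corrected, blanks_baselined[[blank_id]],
                        window = params$ptfe_window)
  fits <- fit_all_regions(sub$spectrum, params$band_table)
  ab <- fg_abundances(fits, params$absorptivities)
  ec <- if (!is.null(ref_row) && nrow(ref_row)) ref_row$ec[1] else NA_real_
  comp <- compose_sample(ab, meta = meta_row, ec_ug = ec,
                         table = params$attribution, c_to_h = params$c_to_h)
  list(
    spectrum = sub$spectrum,
    baseline = bl,
    blank_match = sub$match,
    fits = fits,
    abundances = ab,
    composition = dplyr::bind_cols(
      tibble::tibble(id = spc_id(raw)),
      tidyr::pivot_wider(ab, names_from = "fg", values_from = "umol",
                         names_prefix = "umol_"),
      comp,
      tibble::tibble(baseline_at_4000 = bl$baseline_at_4000,
                     blank_scale = sub$match$scale,
                     acid_detected = screen$detected,
                     negative_fraction = negative_fraction(sub$spectrum),
                     fit_converged = all(fits$converged))
    )
  )
}

#' Run the full analysis on an in-memory study
#'
#' Per sample: acid-signature screen, smoothing-spline baseline, blank
#' selection and scaled subtraction, multi-peak fitting, calibration to
#' bond abundances and composition (OC, OM, OM/OC, PAH, emission factors).
#' Study level: functional-group OC vs reference OC regression (through
#' origin), FTIR-vs-GC-MS PAH comparison, EC-baseline regression
#' diagnostic, PLSR--VIP spectra for reference OC and for the GC--MS PAH
#' sum, and mean emission-factor spectra per fuel and phase. Failures are
#' recorded per sample and do not abort the remaining samples.
#'
#' @param study List as from [generate_study()] (or assembled from disk by
#'   [run_pipeline()]): `spectra`, `blanks`, `meta`, `references`.
#' @param params Parameter list, default [default_pipeline_params()].
#' @return List of result tables: `composition`, `fits`, `blank_matches`,
#'   `baseline_diagnostics`, `oc_regression`, `pah_comparison`,
#'   `ec_regression`, `vip_oc`, `vip_pah`, `group_means`, `errors`,
#'   `spectra_processed`.
#' @export
run_study <- function(study, params = default_pipeline_params()) {
  stopifnot(length(study$spectra) > 0, length(study$blanks) > 0)
  blanks_baselined <- purrr::map(study$blanks, function(b) {
    fit_baseline(b, anchor_regions = params$anchor_regions,
                 smoothing = params$smoothing)$corrected
  })
  errors <- list()
  results <- list()
  for (id in names(study$spectra)) {
    ref_row <- study$references[study$references$id == id, ]
    meta_row <- study$meta[study$meta$id == id, ]
    res <- tryCatch(
      process_sample(study$spectra[[id]], blanks_baselined,
                     ref_row, if (nrow(meta_row)) meta_row else NULL, params),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
    } else {
      results[[id]] <- res
    }
  }
  if (length(results) == 0) rlang::abort("Every sample failed; aborting study.")
  composition <- purrr::map_dfr(results, "composition")
  composition <- dplyr::left_join(composition,
                                  study$meta[c("id", "fuel", "phase")],
                                  by = "id")
  fits <- purrr::imap_dfr(results, function(r, id) {
    dplyr::mutate(r$fits, id = id, .before = 1)
  })
  blank_matches <- purrr::map_dfr(results, "blank_match")
  baseline_diag <- purrr::map_dfr(results, function(r) glance(r$baseline))

  refs <- study$references
  oc_tab <- dplyr::inner_join(
    composition[c("id", "oc")],
    dplyr::mutate(refs,
                  oc_ref = artifact_correct(refs$oc_front, refs$oc_back)$corrected)[
      c("id", "oc_ref", "ec")],
    by = "id"
  )
  oc_fit <- stats::lm(oc ~ 0 + oc_ref, data = oc_tab)
  oc_regression <- tibble::tibble(
    slope = unname(stats::coef(oc_fit)[["oc_ref"]]),
    r_squared = stats::cor(oc_tab$oc, stats::fitted(oc_fit))^2,
    n = nrow(oc_tab)
  )
  pah_comparison <- tryCatch(
    compare_pah_estimates(
      dplyr::rename(composition[c("id", "pah_mass")], pah_ftir = "pah_mass"),
      dplyr::rename(refs[!is.na(refs$pah_total), c("id", "pah_total")],
                    pah_gcms = "pah_total")
    ),
    error = function(e) tibble::tibble(slope = NA_real_, r_squared = NA_real_,
                                       ratio_of_totals = NA_real_, n = 0)
  )
  ec_regression <- tryCatch(
    ec_baseline_regression(
      dplyr::inner_join(
        composition[c("id", "baseline_at_4000")],
        dplyr::transmute(oc_tab, id = .data$id, oc = .data$oc_ref,
                         ec = .data$ec),
        by = "id"
      )
    ),
    error = function(e) NULL
  )

  X <- spectra_matrix(purrr::map(results, "spectrum"),
                      exclude = params$ptfe_window)
  fit_vip <- function(y_tab) {
    keep <- rownames(X) %in% y_tab$id
    y <- y_tab$y[match(rownames(X)[keep], y_tab$id)]
    if (sum(keep) < 6 || stats::sd(y) == 0) return(NULL)
    model <- fit_plsr(X[keep, , drop = FALSE], y,
                      n_components = params$vip_components,
                      cv_seed = params$vip_cv_seed)
    vip_scores(model, threshold = params$vip_threshold)
  }
  vip_oc <- fit_vip(tibble::tibble(id = oc_tab$id, y = oc_tab$oc_ref))
  pah_ref <- refs[!is.na(refs$pah_total), ]
  vip_pah <- fit_vip(tibble::tibble(id = pah_ref$id, y = pah_ref$pah_total))

  groups <- dplyr::inner_join(study$meta, tibble::tibble(id = names(results)),
                              by = "id")
  group_means <- purrr::map_dfr(
    split(groups, paste(groups$fuel, groups$phase, sep = ".")),
    function(g) {
      ms <- mean_spectrum(purrr::map(results[g$id], "spectrum"),
                          divide_by = g$energy_delivered)
      dplyr::mutate(ms, fuel = g$fuel[1], phase = g$phase[1], .before = 1)
    }
  )

  list(
    composition = composition, fits = fits, blank_matches = blank_matches,
    baseline_diagnostics = baseline_diag,
    oc_regression = oc_regression, pah_comparison = pah_comparison,
    ec_regression = ec_regression,
    vip_oc = vip_oc, vip_pah = vip_pah,
    group_means = group_means,
    errors = errors,
    spectra_processed = purrr::map(results, "spectrum")
  )
}

#' Load a study from a pipeline input directory
#'
#' Expects the layout written by [write_study()]: `spectra/*.csv`,
#' `blanks/*.csv` (with `blanks/index.csv`), `meta.csv`, `references.csv`.
#'
#' @param dir Input directory.
#' @return A study list usable by [run_study()].
#' @export
read_study <- function(dir) {
  need <- c("spectra", "blanks", "meta.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    rlang::abort(paste("Input directory is missing:",
                       paste(missing, collapse = ", ")))
  }
  read_dir <- function(sub) {
    files <- sort(list.files(file.path(dir, sub), pattern = "\\.csv$",
                             full.names = TRUE))
    files <- files[basename(files) != "index.csv"]
    specs <- purrr::map(files, read_spectrum)
    stats::setNames(
      purrr::map(specs, resample_spectrum),
      vapply(specs, spc_id, "")
    )
  }
  refs_path <- file.path(dir, "references.csv")
  list(
    spectra = read_dir("spectra"),
    blanks = read_dir("blanks"),
    meta = readr::read_csv(file.path(dir, "meta.csv"), show_col_types = FALSE),
    references = if (file.exists(refs_path)) {
      readr::read_csv(refs_path, show_col_types = FALSE)
    } else {
      tibble::tibble(id = character(0))
    }
  )
}

#' Run the pipeline from a config
#'
#' Thin disk-facing wrapper over [read_study()] and [run_study()]: loads
#' the inputs named in the config, runs every stage, writes all result
#' tables as CSV plus a structured line-delimited JSON log, and archives
#' the config verbatim into the output directory.
#'
#' @param config Path to a YAML config or an equivalent named list. Keys:
#'   `input_dir` (layout of [write_study()]), `output_dir`, and optional
#'   overrides `smoothing`, `vip_components`, `vip_threshold`, `c_to_h`,
#'   `band_table`, `absorptivity_table`, `attribution_table` (CSV paths).
#' @return The [run_study()] result list, invisibly, with
#'   `output_dir` attached.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NULL
  }
  if (is.null(config$input_dir) || is.null(config$output_dir)) {
    rlang::abort("Config needs `input_dir` and `output_dir`.")
  }
  if (!dir.exists(config$input_dir)) {
    rlang::abort(sprintf("Input directory does not exist: %s", config$input_dir))
  }
  params <- default_pipeline_params()
  for (key in c("smoothing", "vip_components", "vip_threshold", "c_to_h")) {
    if (!is.null(config[[key]])) params[[key]] <- config[[key]]
  }
  if (!is.null(config$band_table)) {
    params$band_table <- read_band_table(config$band_table)
  }
  if (!is.null(config$absorptivity_table)) {
    params$absorptivities <- read_absorptivity_table(config$absorptivity_table)
  }
  if (!is.null(config$attribution_table)) {
    params$attribution <- readr::read_csv(config$attribution_table,
                                          show_col_types = FALSE)
  }
  study <- read_study(config$input_dir)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- run_study(study, params)

  wcsv <- function(tab, name) {
    if (!is.null(tab) && nrow(tab)) {
      readr::write_csv(tab, file.path(out_dir, paste0(name, ".csv")))
    }
  }
  wcsv(res$composition, "composition")
  wcsv(res$fits, "band_fits")
  wcsv(res$blank_matches, "blank_matches")
  wcsv(res$baseline_diagnostics, "baseline_diagnostics")
  wcsv(res$oc_regression, "oc_regression")
  wcsv(res$pah_comparison, "pah_comparison")
  wcsv(res$ec_regression, "ec_regression")
  if (!is.null(res$vip_oc)) wcsv(tidy(res$vip_oc), "vip_oc")
  if (!is.null(res$vip_pah)) wcsv(tidy(res$vip_pah), "vip_pah")
  wcsv(res$group_means, "group_mean_spectra")
  dir.create(file.path(out_dir, "spectra_processed"), showWarnings = FALSE)
  purrr::iwalk(res$spectra_processed, function(s, id) {
    write_spectrum(s, file.path(out_dir, "spectra_processed",
                                paste0(id, ".csv")))
  })
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  log_lines <- c(
    jsonlite::toJSON(list(event = "run", package_version =
                            as.character(utils::packageVersion("ftirfg")),
                          n_samples = length(study$spectra),
                          n_blanks = length(study$blanks),
                          elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs"))),
                     auto_unbox = TRUE),
    purrr::imap_chr(res$errors, function(msg, id) {
      jsonlite::toJSON(list(event = "sample_error", id = id, message = msg),
                       auto_unbox = TRUE)
    })
  )
  writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  res$output_dir <- out_dir
  invisible(res)
}
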