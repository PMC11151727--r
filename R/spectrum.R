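#' Spectrum objects
#'
#' A spectrum is a tibble with columns `wavenumber` (cm^-1, strictly
#' monotone) and `absorbance` (absorbance units, AU), carrying metadata as
#' attributes: `id`, `stage` (one of `"raw"`, `"baselined"`,
#' `"blank_subtracted"`) and `filter_kind` (`"sample"` or `"blank"`).
#' Negative absorbances are legal (and expected after baseline and blank
#' corrections); they are never clipped.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone (either direction), within 400--4000.
#' @param absorbance Numeric vector of absorbances (AU), same length.
#' @param id Sample identifier.
#' @param stage Processing stage.
#' @param filter_kind Whether the filter is a sample or a blank.
#' @return A tibble of class `ftir_spectrum`.
#' @export
#' @examples
#' s <- spectrum(c(4000, 3996, 3992), c(0, 0.1, 0.2), id = "demo")
#' spc_stage(s)
spectrum <- function(wavenumber, absorbance, id = "spectrum",
                     stage = c("raw", "baselined", "blank_subtracted"),
                     filter_kind = c("sample", "blank")) {
  stage <- match.arg(stage)
  filter_kind <- match.arg(filter_kind)
  wavenumber <- as.double(wavenumber)
  absorbance <- as.double(absorbance)
  if (length(wavenumber) != length(absorbance)) {
    rlang::abort("`wavenumber` and `absorbance` must have the same length.")
  }
  if (length(wavenumber) < 2) {
    rlang::abort("A spectrum needs at least two points.")
  }
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) {
    bad <- which(sign(d) != sign(d[1]) | d == 0)[1] + 1L
    rlang::abort(sprintf(
      "`wavenumber` must be strictly monotone; violation at point %d (%.6g cm^-1).",
      bad, wavenumber[bad]
    ))
  }
  if (!all(is.finite(absorbance))) {
    rlang::abort("`absorbance` must be finite.")
  }
  out <- tibble::tibble(wavenumber = wavenumber, absorbance = absorbance)
  class(out) <- c("ftir_spectrum", class(out))
  attr(out, "id") <- as.character(id)
  attr(out, "stage") <- stage
  attr(out, "filter_kind") <- filter_kind
  out
}

#' @rdname spectrum
#' @param x Object to test or coerce.
#' @export
is_spectrum <- function(x) inherits(x, "ftir_spectrum")

#' @rdname spectrum
#' @export
spc_id <- function(x) attr(x, "id") %||% "spectrum"

#' @rdname spectrum
#' @export
spc_stage <- function(x) attr(x, "stage") %||% "raw"

#' @rdname spectrum
#' @export
spc_kind <- function(x) attr(x, "filter_kind") %||% "sample"

spc_restamp <- function(df, template, stage = spc_stage(template),
                        id = spc_id(template), kind = spc_kind(template)) {
  spectrum(df$wavenumber, df$absorbance, id = id, stage = stage,
           filter_kind = kind)
}

#' Fraction of negative absorbance points
#'
#' Quality flag recorded after corrections; negatives are preserved, never
#' clipped, because clipping biases downstream peak fits.
#'
#' @param x An `ftir_spectrum`.
#' @return Fraction in `[0, 1]`.
#' @export
negative_fraction <- function(x) {
  stopifnot(is_spectrum(x))
  mean(x$absorbance < 0)
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ftir_spectrum> id=%s stage=%s kind=%s  %d points, %.0f-%.0f cm^-1\n",
    spc_id(x), spc_stage(x), spc_kind(x), nrow(x),
    max(x$wavenumber), min(x$wavenumber)
  ))
  NextMethod()
}

#' Canonical acquisition grid
#'
#' The descending 4000 to 400 cm^-1 grid at 4 cm^-1 spacing (901 points)
#' matching transmission-mode acquisition at 4 cm^-1 resolution. Readers and
#' the simulator normalise spectra to this grid so blank matching and matrix
#' assembly are well defined.
#'
#' @return Numeric vector of length 901, descending.
#' @export
canonical_grid <- function() {
  seq(4000, 400, by = -4)
}

#' Read a spectrum from disk
#'
#' CSV files must have two numeric columns headed
#' `wavenumber_cm-1,absorbance`. JCAMP-DX support covers the plain AFFN
#' `##XYDATA=(X++(Y..Y))` form only.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"jcampdx"`.
#' @param id Spectrum id; defaults to the file name without extension.
#' @return An `ftir_spectrum` with `stage = "raw"`, grid left in file order.
#' @export
read_spectrum <- function(path, dialect = c("csv", "jcampdx"), id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("Spectrum file not found: %s", path))
  }
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) rlang::abort(sprintf("Empty spectrum file: %s", path))
    start <- if (grepl("[A-Za-z]", lines[1])) 2L else 1L
    if (length(lines) < start) {
      rlang::abort(sprintf("No data rows in %s", path))
    }
    body <- lines[start:length(lines)]
    parts <- strsplit(body, ",")
    bad <- which(vapply(parts, length, 1L) < 2)
    if (length(bad)) {
      rlang::abort(sprintf("Line %d of %s is not a two-column numeric row.",
                           bad[1] + start - 1L, path))
    }
    wn <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    ab <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    nn <- which(is.na(wn) | is.na(ab))
    if (length(nn)) {
      rlang::abort(sprintf("Non-numeric value on line %d of %s.",
                           nn[1] + start - 1L, path))
    }
  } else {
    parsed <- read_jcampdx(path)
    wn <- parsed$wavenumber
    ab <- parsed$absorbance
  }
  spectrum(wn, ab, id = id, stage = "raw")
}

# Minimal JCAMP-DX: AFFN (X++(Y..Y)) tables; compressed encodings rejected.
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xy_at <- grep("^##XYDATA=", lines)
  if (!length(xy_at)) rlang::abort(sprintf("No ##XYDATA block in %s", path))
  end_at <- grep("^##END", lines)
  end_at <- if (length(end_at)) end_at[end_at > xy_at[1]][1] else length(lines) + 1L
  body <- lines[(xy_at[1] + 1L):(end_at - 1L)]
  if (any(grepl("[A-DF-Zif%@a-d]", gsub("[eE][+-]?[0-9]+", "", body)))) {
    rlang::abort("Compressed JCAMP-DX encodings (SQZ/DIF/DUP) are not supported; use AFFN.")
  }
  xfac <- get_field("XFACTOR"); if (is.na(xfac)) xfac <- 1
  yfac <- get_field("YFACTOR"); if (is.na(yfac)) yfac <- 1
  rows <- strsplit(trimws(body), "[ \t,]+")
  wn <- numeric(0); ab <- numeric(0)
  for (r in rows) {
    v <- as.numeric(r)
    if (anyNA(v) || length(v) < 2) rlang::abort("Malformed JCAMP-DX data row.")
    x0 <- v[1] * xfac
    ys <- v[-1] * yfac
    np <- get_field("NPOINTS"); fx <- get_field("FIRSTX"); lx <- get_field("LASTX")
    dx <- if (!is.na(np) && !is.na(fx) && !is.na(lx) && np > 1) (lx - fx) / (np - 1) else NA_real_
    if (is.na(dx)) rlang::abort("JCAMP-DX file lacks FIRSTX/LASTX/NPOINTS.")
    wn <- c(wn, x0 + dx * (seq_along(ys) - 1))
    ab <- c(ab, ys)
  }
  list(wavenumber = wn, absorbance = ab)
}

#' Write a spectrum as two-column CSV
#'
#' @param x An `ftir_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(is_spectrum(x))
  lines <- c("wavenumber_cm-1,absorbance",
             sprintf("%.10g,%.10g", x$wavenumber, x$absorbance))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; the target must lie within the source span (no
#' extrapolation).
#'
#' @param x An `ftir_spectrum`.
#' @param target_grid Numeric wavenumber grid, strictly monotone.
#' @return An `ftir_spectrum` on `target_grid`, same stage and metadata.
#' @export
resample_spectrum <- function(x, target_grid = canonical_grid()) {
  stopifnot(is_spectrum(x))
  lo <- min(x$wavenumber); hi <- max(x$wavenumber)
  if (min(target_grid) < lo || max(target_grid) > hi) {
    rlang::abort(sprintf(
      "Target grid [%.6g, %.6g] exceeds source span [%.6g, %.6g]; refusing to extrapolate.",
      min(target_grid), max(target_grid), lo, hi
    ))
  }
  o <- order(x$wavenumber)
  ab <- stats::approx(x$wavenumber[o], x$absorbance[o], xout = target_grid,
                      method = "linear", ties = "ordered")$y
  spectrum(target_grid, ab, id = spc_id(x), stage = spc_stage(x),
           filter_kind = spc_kind(x))
}

#' Pointwise mean and standard deviation of a set of spectra
#'
#' All spectra must share one grid. The standard deviation is the sample sd
#' (n - 1 denominator) throughout the package. Optional weights divide each
#' spectrum before averaging; passing the energy delivered (MJ) per sample
#' expresses the result as an emission-factor spectrum (AU per MJ).
#'
#' @param spectra List of `ftir_spectrum` objects on a common grid.
#' @param divide_by Optional positive scalar per spectrum (e.g. energy in
#'   MJ); each spectrum is divided by its value before averaging.
#' @return A tibble with columns `wavenumber`, `mean`, `sd`, `n`.
#' @export
mean_spectrum <- function(spectra, divide_by = NULL) {
  stopifnot(length(spectra) >= 1, all(vapply(spectra, is_spectrum, TRUE)))
  grid <- spectra[[1]]$wavenumber
  same <- vapply(spectra, function(s) {
    nrow(s) == length(grid) && all(s$wavenumber == grid)
  }, TRUE)
  if (!all(same)) {
    rlang::abort("All spectra must share one wavenumber grid (resample first).")
  }
  mat <- vapply(spectra, function(s) s$absorbance, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  if (!is.null(divide_by)) {
    stopifnot(length(divide_by) == length(spectra), all(divide_by > 0))
    mat <- sweep(mat, 2, divide_by, "/")
  }
  n <- ncol(mat)
  tibble::tibble(
    wavenumber = grid,
    mean = rowMeans(mat),
    sd = if (n > 1) apply(mat, 1, stats::sd) else rep(0, length(grid)),
    n = n
  )
}

#' Assemble a spectra matrix for multivariate analysis
#'
#' Stacks blank-subtracted spectra into a samples-by-wavenumbers matrix on
#' the common grid, excluding the PTFE interference region (1300--1000
#' cm^-1 by default) where filter absorption masks organic bands.
#'
#' @param spectra Named list of `ftir_spectrum` on one grid.
#' @param exclude Wavenumber interval `c(lo, hi)` to drop, or `NULL`.
#' @return A numeric matrix with sample ids as rownames and wavenumbers as
#'   column names.
#' @export
spectra_matrix <- function(spectra, exclude = c(1000, 1300)) {
  stopifnot(length(spectra) >= 1)
  grid <- spectra[[1]]$wavenumber
  keep <- rep(TRUE, length(grid))
  if (!is.null(exclude)) {
    keep <- grid < min(exclude) | grid > max(exclude)
  }
  X <- t(vapply(spectra, function(s) s$absorbance[keep], numeric(sum(keep))))
  rownames(X) <- unname(vapply(spectra, spc_id, ""))
  colnames(X) <- grid[keep]
  X
}

#' @importFrom rlang %||%
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Conventional presentation: wavenumber decreasing left to right.
#'
#' @param object An `ftir_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ftir_spectrum
#' @export
autoplot.ftir_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$absorbance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance (AU)",
      title = sprintf("%s [%s]", spc_id(object), spc_stage(object))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
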