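# Post-processing of stick CD spectra (excitation wavelengths + rotatory
# strengths): Gaussian broadening, per-molecule normalization and
# population weighting into a composite dimer spectrum.

#' Stick CD spectrum
#'
#' @param wavelength excitation wavelengths (nm, positive).
#' @param strength rotatory strengths (signed, arbitrary CD units).
#' @param n_molecules 1 for a monomer, 2 for a dimer; intensities are
#'   reported per molecule downstream.
#' @param label geometry label (e.g. "monomer", "I".."IV").
#' @return Object of class `stick_spectrum`.
#' @export
stick_spectrum <- function(wavelength, strength, n_molecules = 1,
                           label = "monomer") {
  stopifnot(length(wavelength) == length(strength))
  if (any(wavelength <= 0)) stop("wavelengths must be positive")
  if (!n_molecules %in% c(1, 2)) stop("`n_molecules` must be 1 or 2")
  structure(data.frame(wavelength = wavelength, strength = strength),
            class = c("stick_spectrum", "data.frame"),
            n_molecules = n_molecules, label = label)
}

#' Gaussian broadening of a stick spectrum
#'
#' Convolves each stick with an area-preserving Gaussian of the given FWHM
#' and scales by 1/n_molecules, so the signed area of the smooth curve
#' equals the summed rotatory strength per molecule.
#'
#' @param sticks a [stick_spectrum()].
#' @param fwhm full width at half maximum of the broadening Gaussian (nm).
#' @param grid wavelength grid (nm); defaults to the stick range padded by
#'   4 standard deviations at 0.2 nm resolution.
#' @return Object of class `smooth_spectrum` (data.frame `wavelength`,
#'   `intensity`), with attributes `fwhm`, `n_molecules`, `label` and
#'   `truncated` (TRUE when the grid does not cover every stick +/- 3
#'   sigma).
#' @export
gaussian_broaden <- function(sticks, fwhm = 12, grid = NULL) {
  stopifnot(inherits(sticks, "stick_spectrum"))
  if (fwhm <= 0) stop("`fwhm` must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  nm <- attr(sticks, "n_molecules")
  if (is.null(grid))
    grid <- seq(min(sticks$wavelength) - 4 * sigma,
                max(sticks$wavelength) + 4 * sigma, by = 0.2)
  truncated <- min(grid) > min(sticks$wavelength) - 3 * sigma ||
    max(grid) < max(sticks$wavelength) + 3 * sigma
  if (truncated)
    warning("grid does not cover all sticks +/- 3 sigma; ",
            "band areas will be truncated")
  intensity <- rep(0, length(grid))
  for (i in seq_len(nrow(sticks)))
    intensity <- intensity +
      sticks$strength[i] * dnorm(grid, sticks$wavelength[i], sigma)
  structure(data.frame(wavelength = grid, intensity = intensity / nm),
            class = c("smooth_spectrum", "data.frame"),
            fwhm = fwhm, n_molecules = nm, label = attr(sticks, "label"),
            truncated = truncated)
}

#' Population-weighted composite spectrum
#'
#' Normalizes the weights to sum 1 and forms the pointwise weighted sum.
#' All spectra must share an identical wavelength grid; no silent
#' resampling.
#'
#' @param spectra list of `smooth_spectrum` objects on a common grid.
#' @param weights non-negative weights (e.g. basin populations).
#' @return A `smooth_spectrum`.
#' @export
population_weight <- function(spectra, weights) {
  stopifnot(length(spectra) == length(weights), length(spectra) >= 1)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("at least one weight must be positive")
  grid <- spectra[[1]]$wavelength
  for (s in spectra)
    if (length(s$wavelength) != length(grid) ||
        any(abs(s$wavelength - grid) > 1e-9))
      stop("spectra are on different wavelength grids; resample explicitly")
  w <- weights / sum(weights)
  intensity <- Reduce(`+`, Map(function(s, wi) wi * s$intensity,
                               spectra, w))
  structure(data.frame(wavelength = grid, intensity = intensity),
            class = c("smooth_spectrum", "data.frame"),
            weights = w,
            label = paste0("composite(",
                           paste(vapply(spectra, attr, "", "label"),
                                 collapse = "+"), ")"))
}

#' Read a stick spectrum from a two-column text file
#'
#' Whitespace-delimited wavelength/strength pairs with `#` metadata lines
#' (`# n_molecules: 2`, `# label: II`).
#'
#' @param path file path.
#' @return A [stick_spectrum()].
#' @export
read_sticks <- function(path) {
  lines <- readLines(path)
  meta <- .parse_hash_headers(lines)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  vals <- lapply(body, function(l) suppressWarnings(
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  bad <- which(vapply(vals, function(v) length(v) != 2 || anyNA(v),
                      logical(1)))
  if (length(bad)) {
    lineno <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))[bad[1]]
    stop("malformed stick entry at line ", lineno, " of ", path)
  }
  m <- do.call(rbind, vals)
  stick_spectrum(m[, 1], m[, 2],
                 n_molecules = as.numeric(meta[["n_molecules"]] %||% 1),
                 label = meta[["label"]] %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
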