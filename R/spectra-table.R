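#' Spectral tables
#'
#' plumfuse stores a set of spectra as a *wide tibble*: a `sample_id` column
#' followed by one numeric column per wavelength, named by the wavelength in
#' nanometres (`"400"`, `"401"`, ...). This mirrors the on-disk CSV layout and
#' keeps every dplyr verb applicable. `spectra_tbl()` builds one from a matrix,
#' `spectra_matrix()` recovers the matrix (rownames = sample ids), and
#' `spectra_wavelengths()` the numeric grid.
#'
#' @param intensities Numeric matrix, samples x wavelengths.
#' @param wavelengths Ascending numeric wavelength grid (nm).
#' @param sample_ids Unique character sample identifiers.
#' @return `spectra_tbl()`: a tibble with `sample_id` plus one column per
#'   wavelength. `spectra_matrix()`: a numeric matrix. `spectra_wavelengths()`:
#'   a numeric vector.
#' @examples
#' sp <- spectra_tbl(matrix(1:6, 2), c(500, 600, 700), c("a", "b"))
#' spectra_wavelengths(sp)
#' spectra_matrix(sp)
#' @export
spectra_tbl <- function(intensities, wavelengths, sample_ids) {
  intensities <- as.matrix(intensities)
  check_grid(wavelengths)
  if (ncol(intensities) != length(wavelengths)) {
    abort("column count of `intensities` must equal length of `wavelengths`",
          class = "plumfuse_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    abort("sample ids must be unique", class = "plumfuse_format_error")
  }
  out <- as_tibble(intensities, .name_repair = "minimal")
  names(out) <- format_wl(wavelengths)
  dplyr::bind_cols(tibble(sample_id = as.character(sample_ids)), out)
}

#' @rdname spectra_tbl
#' @param spectra A spectral tibble as produced by [spectra_tbl()].
#' @export
spectra_matrix <- function(spectra) {
  stopifnot(is.data.frame(spectra), "sample_id" %in% names(spectra))
  m <- as.matrix(spectra[setdiff(names(spectra), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- spectra$sample_id
  m
}

#' @rdname spectra_tbl
#' @export
spectra_wavelengths <- function(spectra) {
  as.numeric(setdiff(names(spectra), "sample_id"))
}

format_wl <- function(wavelengths) {
  format(wavelengths, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

check_grid <- function(wavelengths) {
  if (length(wavelengths) == 0 || any(!is.finite(wavelengths)) ||
      any(diff(wavelengths) <= 0)) {
    abort("wavelength grid must be finite and strictly increasing",
          class = "plumfuse_format_error")
  }
  invisible(wavelengths)
}

# reference spectra (dark current, white board) are long tibbles on one grid
reference_tbl <- function(wavelengths, intensity) {
  check_grid(wavelengths)
  tibble(wavelength_nm = as.numeric(wavelengths), intensity = as.numeric(intensity))
}

check_same_grid <- function(spectra, ...) {
  wl <- spectra_wavelengths(spectra)
  for (ref in list(...)) {
    if (length(ref$wavelength_nm) != length(wl) ||
        any(abs(ref$wavelength_nm - wl) > 1e-9)) {
      abort("wavelength grids do not match", class = "plumfuse_format_error")
    }
  }
  invisible(wl)
}
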