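#' Read and write the plumfuse CSV dialects
#'
#' Spectra are stored wide: first column `sample_id`, remaining header fields
#' the wavelengths in nm. Reference (dark/white) spectra are single-spectrum
#' long tables `wavelength_nm,intensity`. SSC tables are
#' `sample_id,ssc_brix`. Visual feature tables are `sample_id` plus the 16
#' frozen feature columns.
#'
#' @param spectra,ref,ssc,features Tibbles of the respective shapes.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name plumfuse_io
NULL

#' @rdname plumfuse_io
#' @export
write_spectra_csv <- function(spectra, path) {
  readr::write_csv(spectra, path)
  invisible(path)
}

#' @rdname plumfuse_io
#' @export
read_spectra_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sample_id = readr::col_character(),
                                                 .default = readr::col_double()))
  check_grid(as.numeric(setdiff(names(out), "sample_id")))
  out
}

#' @rdname plumfuse_io
#' @export
write_reference_csv <- function(ref, path) {
  readr::write_csv(ref, path)
  invisible(path)
}

#' @rdname plumfuse_io
#' @export
read_reference_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double()))
}

#' @rdname plumfuse_io
#' @export
write_ssc_csv <- function(ssc, path) {
  readr::write_csv(ssc, path)
  invisible(path)
}

#' @rdname plumfuse_io
#' @export
read_ssc_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sample_id = readr::col_character(),
                                                 .default = readr::col_double()))
  if (!all(c("sample_id", "ssc_brix") %in% names(out))) {
    abort("SSC table must have columns `sample_id` and `ssc_brix`",
          class = "plumfuse_schema_error")
  }
  out
}

#' @rdname plumfuse_io
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname plumfuse_io
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Write / read a plain-text `key = value` manifest
#'
#' @param x A named list of scalar values.
#' @param path File path.
#' @return `read_manifest()` returns a named character vector.
#' @export
write_manifest <- function(x, path) {
  lines <- purrr::imap_chr(x, function(v, k) {
    paste0(k, " = ", paste(format(v, digits = 15, trim = TRUE), collapse = ","))
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}
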