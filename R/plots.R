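#' Plot a set of spectra
#'
#' Line plot of intensity (or reflectance) against wavelength, one line per
#' sample.
#'
#' @param spectra A wide spectral tibble.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, alpha = 0.4) {
  long <- tidyr::pivot_longer(spectra, -"sample_id",
                              names_to = "wavelength_nm",
                              values_to = "intensity") |>
    dplyr::mutate(wavelength_nm = as.numeric(.data$wavelength_nm))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$intensity,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot an RMSECV trace from latent-variable selection
#'
#' @param trace A tibble with `n_latent` and `rmsecv` (from
#'   [select_n_latent()]).
#' @return A ggplot object.
#' @export
plot_rmsecv <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(.data$n_latent, .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "RMSECV (°Brix)") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-reference plot for a pipeline run
#'
#' Scatter of predicted against measured SSC for all three models, faceted by
#' model, test partition highlighted.
#'
#' @param object A `plum_run` result from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plum_run
#' @export
autoplot.plum_run <- function(object, ...) {
  preds <- attr(object, "predictions")
  ggplot2::ggplot(preds, ggplot2::aes(.data$y_true, .data$y_pred,
                                      color = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "measured SSC (°Brix)",
                  y = "predicted SSC (°Brix)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
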