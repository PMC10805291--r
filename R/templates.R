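#' Visual pigment absorbance template
#'
#' Generates a photoreceptor spectral-sensitivity curve from the standard
#' rhodopsin (A1) or porphyropsin (A2) visual-pigment absorbance templates:
#' the alpha band as a sum-of-exponentials function of normalized frequency
#' `x = peak_nm / lambda`, plus (by default) the Gaussian beta band of the
#' same templates. The curve is peak-normalized to 1 before any
#' relativization. A2 pigments are broader than A1 pigments at the same peak.
#'
#' @param peak_nm Alpha-band peak wavelength in nm, within the grid range.
#' @param chromophore `"A1"` or `"A2"`.
#' @param grid A [grid_policy()].
#' @param beta Include the beta band (default `TRUE`).
#'
#' @return A `qc_spectrum` of kind `"sensitivity"` on the grid, max value 1.
#' @examples
#' uv <- receptor_template(350, "A1")
#' @export
receptor_template <- function(peak_nm, chromophore = c("A1", "A2"),
                              grid = grid_policy(), beta = TRUE) {
  chromophore <- match.arg(chromophore)
  wl <- grid_wavelengths(grid)
  if (peak_nm < min(wl) || peak_nm > max(wl)) {
    abort(sprintf("`peak_nm` = %g is outside the grid %g-%g nm.",
                  peak_nm, min(wl), max(wl)))
  }
  x <- peak_nm / wl
  if (chromophore == "A1") {
    a <- 0.8795 + 0.0459 * exp(-(peak_nm - 300)^2 / 11940)
    v <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
    if (beta) {
      lmb <- 189 + 0.315 * peak_nm
      bw <- -40.5 + 0.195 * peak_nm
      v <- v + 0.26 * exp(-((wl - lmb) / bw)^2)
    }
  } else {
    A <- 62.7 + 1.834 * exp((peak_nm - 625) / 54.2)
    a <- 0.875 + 0.0268 * exp((peak_nm - 665) / 40.7)
    v <- 1 / (exp(A * (a - x)) + exp(41.5 * (0.9101 - x)) +
                exp(-14.9 * (1.1123 - x)) + 0.754)
    if (beta) {
      lmb <- 216.7 + 0.287 * peak_nm
      bw <- 317 - 1.149 * peak_nm + 0.00124 * peak_nm^2
      v <- v + 0.37 * exp(-((wl - lmb) / bw)^2)
    }
  }
  spectrum(wl, v / max(v), "sensitivity")
}

#' Synthetic receptor set from pigment templates
#'
#' Convenience wrapper building a relativized [channel_set()] of template
#' receptors at the given peaks.
#'
#' @param peaks_nm Named or unnamed vector of peak wavelengths.
#' @param chromophore `"A1"` or `"A2"`, recycled over peaks.
#' @param name Set name.
#' @inheritParams receptor_template
#' @return A relativized `channel_set`.
#' @export
template_receptor_set <- function(peaks_nm, chromophore = "A1",
                                  name = "template", grid = grid_policy(),
                                  beta = TRUE) {
  chromophore <- rep_len(chromophore, length(peaks_nm))
  labs <- names(peaks_nm) %||% paste0("p", round(peaks_nm))
  channels <- purrr::map2(
    as.numeric(peaks_nm), chromophore,
    ~ receptor_template(.x, .y, grid, beta)
  )
  relativize(channel_set(name, setNames(channels, labs)), grid)
}
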