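#' Wavelength grid policy
#'
#' The canonical wavelength grid on which spectra are resampled and catch
#' integrals evaluated. The default covers 300--700 nm at 1 nm, the range over
#' which camera and receptor catches are integrated.
#'
#' @param min_nm,max_nm Grid end points in nanometres.
#' @param step_nm Grid step in nanometres; must divide `max_nm - min_nm`.
#'
#' @return An object of class `grid_policy`.
#' @examples
#' g <- grid_policy()
#' head(grid_wavelengths(g))
#' @export
grid_policy <- function(min_nm = 300, max_nm = 700, step_nm = 1) {
  if (!(min_nm < max_nm)) abort("`min_nm` must be below `max_nm`.")
  if (step_nm <= 0) abort("`step_nm` must be positive.")
  n_steps <- (max_nm - min_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    abort("`step_nm` must divide the range `max_nm - min_nm`.")
  }
  structure(
    list(min_nm = min_nm, max_nm = max_nm, step_nm = step_nm),
    class = "grid_policy"
  )
}

#' @rdname grid_policy
#' @param grid A `grid_policy`.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "grid_policy"))
  seq(grid$min_nm, grid$max_nm, by = grid$step_nm)
}

#' @export
print.grid_policy <- function(x, ...) {
  cat(sprintf(
    "<grid_policy> %g-%g nm, step %g nm (%d points)\n",
    x$min_nm, x$max_nm, x$step_nm, length(grid_wavelengths(x))
  ))
  invisible(x)
}

spectrum_kinds <- c("reflectance", "illuminant", "sensitivity")

#' Wavelength-sampled spectrum
#'
#' A spectrum is a tibble with columns `wavelength` (nm, strictly increasing)
#' and `value` (nonnegative), tagged with a `kind`: `"reflectance"` (unitless,
#' typically in \[0, 1.1\]), `"illuminant"` (relative photon flux), or
#' `"sensitivity"` (relative spectral sensitivity). Reflectances above 1.1
#' trigger a warning rather than an error so that super-white standards remain
#' representable.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of nonnegative values, same length.
#' @param kind One of `"reflectance"`, `"illuminant"`, `"sensitivity"`.
#'
#' @return A tibble of class `qc_spectrum` with attribute `kind`.
#' @examples
#' s <- spectrum(300:700, rep(0.5, 401), "reflectance")
#' spectrum_kind(s)
#' @export
spectrum <- function(wavelength, value, kind) {
  kind <- match.arg(kind, spectrum_kinds)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    abort("`wavelength` and `value` must have the same length.")
  }
  if (anyNA(wavelength) || anyNA(value)) abort("Spectrum must not contain NA.")
  if (length(wavelength) && any(diff(wavelength) <= 0)) {
    abort("`wavelength` must be strictly increasing.")
  }
  if (any(value < 0)) abort("Spectrum values must be nonnegative.")
  if (kind == "reflectance" && any(value > 1.1)) {
    warn("Reflectance exceeds 1.1; keeping values (super-white standard?).")
  }
  out <- new_tibble(
    list(wavelength = wavelength, value = value),
    nrow = length(wavelength),
    class = "qc_spectrum"
  )
  attr(out, "kind") <- kind
  out
}

#' @rdname spectrum
#' @param x A `qc_spectrum`.
#' @export
spectrum_kind <- function(x) {
  stopifnot(inherits(x, "qc_spectrum"))
  attr(x, "kind")
}

#' @rdname spectrum
#' @param df A data frame with columns `wavelength` (or `wavelength_nm`) and
#'   `value`.
#' @export
as_spectrum <- function(df, kind) {
  wl_col <- intersect(c("wavelength", "wavelength_nm"), names(df))[1]
  if (is.na(wl_col) || !"value" %in% names(df)) {
    abort("Need columns `wavelength`/`wavelength_nm` and `value`.")
  }
  ord <- order(df[[wl_col]])
  spectrum(df[[wl_col]][ord], df$value[ord], kind)
}

assert_kind <- function(x, kind, arg = deparse(substitute(x))) {
  if (!inherits(x, "qc_spectrum")) {
    abort(sprintf("`%s` must be a qc_spectrum.", arg))
  }
  if (spectrum_kind(x) != kind) {
    abort(sprintf(
      "`%s` has kind '%s' but kind '%s' is required.",
      arg, spectrum_kind(x), kind
    ))
  }
  invisible(x)
}

#' Resample a spectrum onto a grid
#'
#' Linear interpolation onto the grid wavelengths. Outside the support of the
#' source spectrum the value is 0: reflectances, sensitivities and narrowband
#' illuminants all physically vanish where they were not measured.
#'
#' @param x A [spectrum()].
#' @param grid A [grid_policy()].
#'
#' @return A `qc_spectrum` on the grid wavelengths, same kind.
#' @export
resample <- function(x, grid = grid_policy()) {
  stopifnot(inherits(x, "qc_spectrum"))
  wl <- grid_wavelengths(grid)
  if (nrow(x) < 2) abort("Spectrum needs at least 2 samples to resample.")
  if (max(x$wavelength) < min(wl) || min(x$wavelength) > max(wl)) {
    abort(sprintf(
      "Spectrum support %g-%g nm does not overlap grid %g-%g nm.",
      min(x$wavelength), max(x$wavelength), min(wl), max(wl)
    ))
  }
  v <- approx(x$wavelength, x$value, xout = wl, rule = 1)$y
  v[is.na(v)] <- 0
  spectrum(wl, v, spectrum_kind(x))
}

#' Quantum catch of a sensor or photoreceptor
#'
#' Discrete catch integral of reflectance x sensitivity x illuminant over the
#' grid: the relative response of a camera sensor (camera catch) or an animal
#' photoreceptor (quantum catch). With a relativized sensitivity (values
#' summing to 1 on the grid) and an ideal illuminant the catch of a flat 100%
#' reflector is exactly 1, which anchors the normalization convention used
#' throughout the package.
#'
#' @param reflectance `qc_spectrum` of kind `"reflectance"`.
#' @param sensitivity `qc_spectrum` of kind `"sensitivity"`, relativized.
#' @param illuminant `qc_spectrum` of kind `"illuminant"`, or `NULL` for the
#'   ideal isoluminant illuminant (photon flux 1 at every wavelength).
#' @param grid A [grid_policy()].
#'
#' @return A single nonnegative number.
#' @examples
#' g <- grid_policy()
#' s <- relativize(channel_set("cam", list(g1 = gaussian_sensitivity(550, 80))))
#' flat <- spectrum(c(300, 700), c(1, 1), "reflectance")
#' quantum_catch(flat, channel_spectra(s)$g1) # 1
#' @export
quantum_catch <- function(reflectance, sensitivity, illuminant = NULL,
                          grid = grid_policy()) {
  assert_kind(reflectance, "reflectance")
  assert_kind(sensitivity, "sensitivity")
  r <- resample(reflectance, grid)$value
  s <- resample(sensitivity, grid)$value
  i <- if (is.null(illuminant)) {
    rep(1, length(r))
  } else {
    assert_kind(illuminant, "illuminant")
    resample(illuminant, grid)$value
  }
  sum(r * s * i)
}

#' Read and write spectra as CSV
#'
#' Two-column files `wavelength_nm,value` with a header row.
#'
#' @param path File path.
#' @param kind Spectrum kind, see [spectrum()].
#' @return `read_spectrum_csv()` returns a `qc_spectrum`; `write_spectrum_csv()`
#'   returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, kind) {
  df <- read.csv(path, check.names = FALSE)
  as_spectrum(df, kind)
}

#' @rdname read_spectrum_csv
#' @param x A `qc_spectrum`.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "qc_spectrum"))
  write.csv(
    data.frame(wavelength_nm = x$wavelength, value = x$value),
    path, row.names = FALSE
  )
  invisible(path)
}
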