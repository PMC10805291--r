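#' A single monochromator sweep measurement
#'
#' One step of a sensor-sensitivity sweep: the monochromator was set to
#' `set_wavelength_nm`, the resulting narrowband irradiance spectrum was
#' measured as photon flux, and the illuminated and dark regions of the frame
#' were read out per camera channel (0--255 pixel scale).
#'
#' @param set_wavelength_nm Nominal wavelength of the step, nm.
#' @param irradiance `qc_spectrum` of kind `"illuminant"` (photon flux).
#' @param lit Named numeric vector: mean pixel value of the illuminated
#'   region, one entry per channel.
#' @param dark Named numeric vector: mean pixel value of an equally sized
#'   dark region, same channels.
#' @return An object of class `sweep_measurement`.
#' @export
sweep_measurement <- function(set_wavelength_nm, irradiance, lit, dark) {
  assert_kind(irradiance, "illuminant")
  if (!identical(names(lit), names(dark))) {
    abort("`lit` and `dark` must cover the same channels, in order.")
  }
  if (any(lit < 0) || any(dark < 0)) abort("Pixel values must be nonnegative.")
  structure(
    list(set_wavelength_nm = set_wavelength_nm, irradiance = irradiance,
         lit = lit, dark = dark),
    class = "sweep_measurement"
  )
}

#' Second-order diffraction wavelength
#'
#' A grating monochromator set to a first-order wavelength also passes light
#' at half that wavelength in second order; sweep points whose half-wavelength
#' falls inside a channel's sensitive band are therefore suspect. Scatter
#' detected at set wavelengths >= 721 nm corresponds to second-order peaks at
#' >= 360.5 nm.
#'
#' @param first_order_nm Set wavelength, nm (> 0).
#' @return `first_order_nm / 2`.
#' @examples
#' second_order_wavelength(721) # 360.5
#' @export
second_order_wavelength <- function(first_order_nm) {
  if (any(first_order_nm <= 0)) abort("`first_order_nm` must be positive.")
  first_order_nm / 2
}

#' Estimate camera sensor sensitivity from a sweep
#'
#' For each sweep step and channel, sensitivity is the dark-subtracted pixel
#' value divided by the summed photon flux in a window around the set
#' wavelength: `S = (P_lit - P_dark) / sum(I(k), k in [set - w, set + w])`.
#' Summing the flux over the main peak rather than taking a single reading
#' suppresses the influence of second-order scatter. Negative differences
#' (dark-frame fluctuation) are clipped to 0 and flagged; steps whose
#' second-order wavelength lands inside `flag_band_nm` are flagged as
#' second-order suspects.
#'
#' @param sweep List of [sweep_measurement()] objects (>= 2).
#' @param window_nm Half-width of the inclusive flux window, nm (default 20).
#' @param statistic Ignored here (region statistics are taken upstream); kept
#'   for interface symmetry with patch extraction.
#' @param flag_band_nm Optional `c(lo, hi)` band (nm); sweep wavelengths whose
#'   half-wavelength falls inside it are flagged `second_order_suspect`.
#'
#' @return A list of class `sensitivity_estimate`: `channel_set` (the
#'   unrelativized estimate on the sweep wavelengths) and `flags`, a tibble
#'   with one row per sweep point (`wavelength`, `clipped` per channel,
#'   `second_order_suspect`).
#' @export
estimate_sensitivity <- function(sweep, window_nm = 20, statistic = "mean",
                                 flag_band_nm = NULL) {
  if (length(sweep) < 2) abort("Need at least 2 sweep measurements.")
  stopifnot(all(vapply(sweep, inherits, logical(1), "sweep_measurement")))
  labs <- names(sweep[[1]]$lit)
  wl_set <- vapply(sweep, function(m) m$set_wavelength_nm, numeric(1))
  ord <- order(wl_set)
  sweep <- sweep[ord]; wl_set <- wl_set[ord]

  flux <- vapply(sweep, function(m) {
    irr <- m$irradiance
    sel <- irr$wavelength >= m$set_wavelength_nm - window_nm &
      irr$wavelength <= m$set_wavelength_nm + window_nm
    sum(irr$value[sel])
  }, numeric(1))
  if (any(flux <= 0)) {
    abort(sprintf(
      "Zero photon flux in the window around %s nm.",
      paste(wl_set[flux <= 0], collapse = ", ")
    ))
  }

  raw <- vapply(sweep, function(m) m$lit[labs] - m$dark[labs],
                numeric(length(labs)))
  raw <- matrix(raw, nrow = length(labs))  # channels x steps
  S <- sweep(raw, 2, flux, "/")
  clipped <- S < 0
  S[clipped] <- 0

  channels <- lapply(seq_along(labs), function(i) {
    spectrum(wl_set, S[i, ], "sensitivity")
  })
  flags <- tibble(wavelength = wl_set)
  for (i in seq_along(labs)) flags[[paste0("clipped_", labs[i])]] <- clipped[i, ]
  flags$second_order_suspect <- if (is.null(flag_band_nm)) {
    FALSE
  } else {
    so <- second_order_wavelength(wl_set)
    so >= flag_band_nm[1] & so <= flag_band_nm[2]
  }
  structure(
    list(
      channel_set = channel_set("estimated", setNames(channels, labs)),
      flags = flags
    ),
    class = "sensitivity_estimate"
  )
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat("<sensitivity_estimate>\n")
  print(x$channel_set)
  n_so <- sum(x$flags$second_order_suspect)
  if (n_so) cat(sprintf("  %d sweep point(s) flagged as second-order suspects\n", n_so))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sensitivity_estimate <- function(x, ...) {
  as_tibble(x$channel_set)
}
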