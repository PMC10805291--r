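#' Named set of sensitivity spectra
#'
#' A channel set bundles the spectral sensitivities of one viewer: the
#' channels of a camera (e.g. `uv_r`, `vis_b`, `vis_g`, `vis_r`) or the
#' photoreceptors of an animal (e.g. honeybee `uv`, `b`, `g`). A relativized
#' set has each channel scaled so its values sum to 1 on the canonical grid,
#' which makes the flat-white catch of every channel exactly 1.
#'
#' @param name Viewer name.
#' @param channels Named list of `qc_spectrum` objects of kind
#'   `"sensitivity"`; names are the channel labels and must be unique.
#' @param relativized Logical; whether channels already sum to 1 on the grid.
#'
#' @return An object of class `channel_set`.
#' @export
channel_set <- function(name, channels, relativized = FALSE) {
  if (is.null(names(channels)) || anyDuplicated(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("`channels` must be a fully and uniquely named list.")
  }
  for (lab in names(channels)) {
    assert_kind(channels[[lab]], "sensitivity", arg = lab)
  }
  structure(
    list(name = name, channels = channels, relativized = isTRUE(relativized)),
    class = "channel_set"
  )
}

#' @rdname channel_set
#' @param x A `channel_set`.
#' @export
channel_labels <- function(x) {
  stopifnot(inherits(x, "channel_set"))
  names(x$channels)
}

#' @rdname channel_set
#' @export
channel_spectra <- function(x) {
  stopifnot(inherits(x, "channel_set"))
  x$channels
}

#' @rdname channel_set
#' @export
is_relativized <- function(x) {
  stopifnot(inherits(x, "channel_set"))
  x$relativized
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf(
    "<channel_set> '%s': %d channel(s) [%s]%s\n",
    x$name, length(x$channels), paste(names(x$channels), collapse = ", "),
    if (x$relativized) ", relativized" else ""
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.channel_set <- function(x, ...) {
  purrr::imap_dfr(x$channels, function(s, lab) {
    tibble(
      set = x$name, channel = lab,
      wavelength = s$wavelength, value = s$value
    )
  })
}

#' Relativize a channel set
#'
#' Resamples every channel onto the grid and divides it by its own sum, so
#' that each channel's sensitivity sums to exactly 1. Idempotent.
#'
#' @param cs A [channel_set()].
#' @param grid A [grid_policy()].
#'
#' @return A relativized `channel_set` on the grid.
#' @export
relativize <- function(cs, grid = grid_policy()) {
  stopifnot(inherits(cs, "channel_set"))
  channels <- purrr::imap(cs$channels, function(s, lab) {
    r <- resample(s, grid)
    tot <- sum(r$value)
    if (tot <= 0) {
      abort(sprintf("Channel '%s' is all zero on the grid; cannot relativize.", lab))
    }
    spectrum(r$wavelength, r$value / tot, "sensitivity")
  })
  channel_set(cs$name, channels, relativized = TRUE)
}

#' Catches of every channel in a set
#'
#' @param reflectance `qc_spectrum` of kind `"reflectance"`.
#' @param cs A relativized [channel_set()].
#' @param illuminant Optional illuminant spectrum (`NULL` = ideal).
#' @param grid A [grid_policy()].
#'
#' @return Named numeric vector of catches, one per channel.
#' @export
channel_catches <- function(reflectance, cs, illuminant = NULL,
                            grid = grid_policy()) {
  stopifnot(inherits(cs, "channel_set"))
  if (!cs$relativized) {
    abort("`cs` must be relativized before computing catches; see relativize().")
  }
  vapply(
    cs$channels,
    function(s) quantum_catch(reflectance, s, illuminant, grid),
    numeric(1)
  )
}

#' Read a multi-channel sensitivity CSV
#'
#' Expects a `wavelength_nm` column plus one column per channel label.
#'
#' @param path File path.
#' @param name Name for the resulting [channel_set()].
#' @return A `channel_set` (not relativized).
#' @export
read_channels_csv <- function(path, name) {
  df <- read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    abort("Multi-channel CSV needs a `wavelength_nm` column.")
  }
  labs <- setdiff(names(df), "wavelength_nm")
  if (!length(labs)) abort("No channel columns found.")
  channels <- lapply(labs, function(lab) {
    spectrum(df$wavelength_nm, df[[lab]], "sensitivity")
  })
  channel_set(name, setNames(channels, labs))
}

#' @rdname read_channels_csv
#' @param cs A `channel_set`.
#' @export
write_channels_csv <- function(cs, path) {
  stopifnot(inherits(cs, "channel_set"))
  wls <- lapply(cs$channels, function(s) s$wavelength)
  if (length(unique(wls)) != 1) {
    abort("Channels must share one wavelength grid to be written; relativize() first.")
  }
  df <- data.frame(wavelength_nm = wls[[1]], check.names = FALSE)
  for (lab in names(cs$channels)) df[[lab]] <- cs$channels[[lab]]$value
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
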