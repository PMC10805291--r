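# False-colour rendering of animal-catch images.

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Trichromat false colour
#'
#' Maps a 3-receptor catch image (UV, blue, green — e.g. a honeybee) to
#' display RGB by shifting each channel one step down: green catch to red,
#' blue catch to green, UV catch to blue. A UV-and-green reflector therefore
#' renders magenta.
#'
#' @param ac `image_plane` in the `"animal_catch"` domain with channels in
#'   (UV, B, G) order.
#' @return `image_plane` in the `"display"` domain, values in \[0, 1\].
#' @export
trichromat_false_color <- function(ac) {
  a <- as_bare_array(ac)
  if (dim(a)[3] != 3) abort("Trichromat false colour needs exactly 3 channels.")
  out <- array(0, dim(a))
  out[, , 1] <- a[, , 3]  # green catch -> R
  out[, , 2] <- a[, , 2]  # blue catch  -> G
  out[, , 3] <- a[, , 1]  # UV catch    -> B
  image_plane(clip01(out), "display", c("R", "G", "B"))
}

#' Tetrachromat false colour
#'
#' Maps a 4-receptor catch image (UV, B, G, R — e.g. a UV-sensitive bird) to
#' display RGB: the B/G/R catches pass through, and the UV catch is overlaid
#' additively into red and blue (magenta) with weight `uv_weight`.
#'
#' @param ac `image_plane`, channels in (UV, B, G, R) order.
#' @param uv_weight Additive UV overlay weight (default 0.5).
#' @return `image_plane` in the `"display"` domain.
#' @export
tetrachromat_false_color <- function(ac, uv_weight = 0.5) {
  a <- as_bare_array(ac)
  if (dim(a)[3] != 4) abort("Tetrachromat false colour needs exactly 4 channels.")
  out <- array(0, c(dim(a)[1:2], 3))
  out[, , 1] <- a[, , 4] + uv_weight * a[, , 1]
  out[, , 2] <- a[, , 3]
  out[, , 3] <- a[, , 2] + uv_weight * a[, , 1]
  image_plane(clip01(out), "display", c("R", "G", "B"))
}

#' Dichromat false colour
#'
#' Maps a 2-receptor catch image (short, long — e.g. a dog or mouse) to RGB:
#' blue = short receptor, green = long receptor, red = their average, so the
#' colours run from purple through an achromatic midpoint to yellow-green.
#'
#' @param ac `image_plane`, channels in (short, long) order.
#' @return `image_plane` in the `"display"` domain.
#' @export
dichromat_false_color <- function(ac) {
  a <- as_bare_array(ac)
  if (dim(a)[3] != 2) abort("Dichromat false colour needs exactly 2 channels.")
  out <- array(0, c(dim(a)[1:2], 3))
  out[, , 1] <- (a[, , 1] + a[, , 2]) / 2
  out[, , 2] <- a[, , 2]
  out[, , 3] <- a[, , 1]
  image_plane(clip01(out), "display", c("R", "G", "B"))
}

#' RNL opponent-space false colour
#'
#' Colours each pixel by its position in the receptor-noise-limited opponent
#' space: hue from the angle over the two leading opponent axes, saturation
#' from the chromatic distance to the achromatic point (capped at `d_max`
#' JND), lightness from the noise-weighted mean log catch. Achromatic pixels
#' render gray; UV-dominated pixels fall in the magenta/purple family with
#' the default key. Hue and saturation are invariant to scaling a pixel's
#' catches, since the chromatic coordinates are log-catch contrasts.
#'
#' @param ac `image_plane` in the `"animal_catch"` domain.
#' @param params [rnl_params()] matching the channel count.
#' @param d_max Saturation cap in JND (default 10).
#' @param lightness_range Log-catch range mapped onto lightness \[0.15, 0.9\].
#' @return `image_plane` in the `"display"` domain. Nonpositive-catch pixels
#'   are masked to 0 and counted in attribute `"n_masked"`.
#' @export
rnl_false_color <- function(ac, params, d_max = 10,
                            lightness_range = c(-4, 0)) {
  stopifnot(inherits(params, "rnl_params"))
  a <- as_bare_array(ac)
  d <- dim(a)
  n <- d[3]
  if (length(params$noise) != n) {
    abort("`params` receptor count must match the image channels.")
  }
  flat <- matrix(a, d[1] * d[2], n)
  ok <- rowSums(flat <= 0) == 0
  e <- unname(params$noise)
  f <- matrix(0, nrow(flat), n)
  f[ok, ] <- log(flat[ok, , drop = FALSE])

  # orthonormal basis of the chromatic hyperplane under the RNL metric:
  # principal axes of the metric restricted to contrasts
  M <- rnl_metric(e)
  eig <- eigen(M, symmetric = TRUE)
  k <- min(2, n - 1)
  basis <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  xy <- f %*% basis                    # JND-scaled opponent coordinates
  if (k == 1) xy <- cbind(xy, 0)
  # centre each pixel's coordinates are already contrast-like because the
  # basis annihilates the achromatic direction; the achromatic point is 0
  dist <- sqrt(rowSums(xy^2))
  hue <- (atan2(xy[, 2], xy[, 1]) / (2 * pi)) %% 1
  sat <- pmin(dist / d_max, 1)
  light_raw <- f %*% (1 / e^2) / sum(1 / e^2)
  lr <- lightness_range
  light <- 0.15 + 0.75 * clip01((light_raw - lr[1]) / (lr[2] - lr[1]))

  rgb <- hsl_to_rgb(hue, sat, as.numeric(light))
  rgb[!ok, ] <- 0
  out <- image_plane(array(rgb, c(d[1], d[2], 3)), "display",
                     c("R", "G", "B"))
  attr(out, "n_masked") <- sum(!ok)
  out
}

# vectorized HSL -> RGB, all components in [0, 1]
hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  hp <- h * 6
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- l - c_ / 2
  seg <- pmin(floor(hp), 5)
  r <- g <- b <- numeric(length(h))
  pick <- function(sel, rr, gg, bb) {
    r[sel] <<- rr[sel]; g[sel] <<- gg[sel]; b[sel] <<- bb[sel]
  }
  zero <- numeric(length(h))
  pick(seg == 0, c_, x, zero); pick(seg == 1, x, c_, zero)
  pick(seg == 2, zero, c_, x); pick(seg == 3, zero, x, c_)
  pick(seg == 4, x, zero, c_); pick(seg == 5, c_, zero, x)
  cbind(r + m, g + m, b + m)
}

#' Display gamma correction
#'
#' Element-wise power transform for display of linear catch images (e.g.
#' exponent 0.5 for camera catches, 0.3 for animal catches).
#'
#' @param image Numeric array or `image_plane`, values >= 0.
#' @param exponent Positive exponent; 1 is the identity.
#' @return Same shape and class as `image`.
#' @export
display_gamma <- function(image, exponent) {
  if (exponent <= 0) abort("`exponent` must be positive.")
  v <- if (inherits(image, "image_plane")) as_bare_array(image) else image
  if (any(v < 0)) abort("Gamma correction needs nonnegative values.")
  out <- v^exponent
  if (inherits(image, "image_plane")) with_plane(image, out) else out
}

#' Render-settings sidecar
#'
#' Writes the mapping and gamma used for a false-colour render next to the
#' image so renders are reproducible.
#'
#' @param path Image path; the sidecar is written at `<path>.json`.
#' @param mapping Mapping name (e.g. `"trichromat"`, `"rnl"`).
#' @param gamma Display gamma exponent.
#' @param extra Optional named list of further settings.
#' @return The sidecar path, invisibly.
#' @export
write_render_sidecar <- function(path, mapping, gamma = 1, extra = list()) {
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    c(list(mapping = mapping, gamma = gamma), extra),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}
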