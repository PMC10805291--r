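#' S-Log3 curve constants
#'
#' Constants of the logarithmic encoding used by the cameras. The decode
#' (linearization) curve is `r = c1 * c2^x + c3` for `x >= c4` and
#' `r = c5 * x + c6` below, where `x` is the encoded pixel value in \[0, 1\],
#' optionally pre-multiplied by the input scale `s`. As printed, the two
#' branches meet with a small (~0.003) discontinuity at `c4`; the constants
#' are applied verbatim rather than re-derived to remove it.
#'
#' @param c1,c2,c3,c4,c5,c6 Curve constants.
#' @param s Input scale applied to the encoded value before the curve.
#' @return A list of class `slog3_constants`.
#' @export
slog3_constants <- function(c1 = 0.0047058, c2 = 8166.69, c3 = -0.01,
                            c4 = 0.1673609, c5 = 0.1914153077,
                            c6 = -0.014023696, s = 0.92578125) {
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, s = s),
            class = "slog3_constants")
}

#' Linearize S-Log3-encoded pixel values
#'
#' Converts encoded values in \[0, 1\] to linear (relative RAW) values. The
#' mapping is total on \[0, 1\] and strictly increasing. Vectorized, so it
#' applies directly to whole images.
#'
#' @param x Encoded values in \[0, 1\] (vector, matrix, array or
#'   `image_plane`).
#' @param k A [slog3_constants()] object.
#' @param apply_scale Multiply `x` by the input scale `k$s` first
#'   (default `TRUE`; the scale improves the round-trip error on both stills
#'   and video frames).
#' @return Linear values, same shape as `x`.
#' @export
slog3_to_linear <- function(x, k = slog3_constants(), apply_scale = TRUE) {
  was_plane <- inherits(x, "image_plane")
  v <- if (was_plane) as_bare_array(x) else x
  xp <- if (apply_scale) k$s * v else v
  r <- ifelse(xp >= k$c4, k$c1 * k$c2^xp + k$c3, k$c5 * xp + k$c6)
  if (was_plane) with_plane(x, array(r, dim(x)), domain = "camera_catch") else r
}

#' Encode linear values to S-Log3
#'
#' Exact inverse of [slog3_to_linear()]; used by the synthetic renderer to
#' emulate what the camera writes to an 8-bit file.
#'
#' @param r Linear values.
#' @inheritParams slog3_to_linear
#' @return Encoded values (in \[0, 1\] for in-gamut `r`), same shape.
#' @export
linear_to_slog3 <- function(r, k = slog3_constants(), apply_scale = TRUE) {
  was_plane <- inherits(r, "image_plane")
  v <- if (was_plane) as_bare_array(r) else r
  r_break <- k$c1 * k$c2^k$c4 + k$c3  # value of the log branch at the break
  use_log <- v >= r_break
  xp <- (v - k$c6) / k$c5
  xp[use_log] <- log((v[use_log] - k$c3) / k$c1) / log(k$c2)
  x <- if (apply_scale) xp / k$s else xp
  if (was_plane) with_plane(r, array(x, dim(r)), domain = "encoded") else x
}
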