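#' Pixel block tagged with its domain
#'
#' Images move through three domains: `"encoded"` (S-Log3-encoded values in
#' \[0, 1\], as read from 8-bit files), `"camera_catch"` (linear, normalized
#' so a 100% reflector reads 1.0), and `"animal_catch"` (photoreceptor
#' quantum catches). A fourth domain, `"display"`, marks false-colour RGB
#' renders. The pixel block is a plain H x W x C numeric array.
#'
#' @param data Numeric H x W x C array (or H x W matrix, promoted to C = 1).
#' @param domain One of `"encoded"`, `"camera_catch"`, `"animal_catch"`,
#'   `"display"`.
#' @param channels Optional character vector of channel labels, length C.
#'
#' @return An `image_plane`: the array with `domain` and `channels` attributes.
#' @export
image_plane <- function(data, domain, channels = NULL) {
  domain <- match.arg(domain,
                      c("encoded", "camera_catch", "animal_catch", "display"))
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be an H x W x C array.")
  }
  if (!is.null(channels) && length(channels) != dim(data)[3]) {
    abort("`channels` length must match the third array dimension.")
  }
  structure(data,
            domain = domain, channels = channels,
            class = c("image_plane", "array"))
}

#' @rdname image_plane
#' @param x An `image_plane`.
#' @export
image_domain <- function(x) attr(x, "domain")

#' @rdname image_plane
#' @export
image_channels <- function(x) attr(x, "channels")

#' @export
print.image_plane <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_plane> %d x %d x %d, domain '%s'%s\n", d[1], d[2], d[3],
    attr(x, "domain"),
    if (!is.null(attr(x, "channels"))) {
      paste0(" [", paste(attr(x, "channels"), collapse = ", "), "]")
    } else ""
  ))
  invisible(x)
}

# strip class/attrs back to a bare array
as_bare_array <- function(x) {
  array(as.numeric(x), dim(x))
}

with_plane <- function(template, data, domain = image_domain(template),
                       channels = image_channels(template)) {
  image_plane(data, domain, channels)
}

#' Read / write an 8-bit image as an encoded image plane
#'
#' PNG I/O for stills; values are scaled to \[0, 1\]. Reading returns an
#' `image_plane` in the `"encoded"` domain.
#'
#' @param path File path.
#' @param channels Optional channel labels for the result.
#' @return `read_image_png()` returns an `image_plane`; `write_image_png()`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path, channels = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  image_plane(a, "encoded", channels)
}

#' @rdname read_image_png
#' @param x An `image_plane` (or numeric array) with values in \[0, 1\].
#' @export
write_image_png <- function(x, path) {
  a <- pmin(pmax(as_bare_array(x), 0), 1)
  png::writePNG(a, path)
  invisible(path)
}

#' Quantize an image to 8-bit codes and back
#'
#' Rounds each value in \[0, 1\] to the nearest of the 256 8-bit codes, the
#' quantization a real JPG/PNG write-read cycle applies.
#'
#' @param x Numeric array or `image_plane` with values in \[0, 1\].
#' @return Same shape, values on the 256-level grid `k/255`.
#' @export
quantize_8bit <- function(x) {
  q <- round(pmin(pmax(x, 0), 1) * 255) / 255
  if (inherits(x, "image_plane")) with_plane(x, array(q, dim(x))) else q
}
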