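# Planar geometry: homography estimation (normalized DLT), point mapping,
# and bilinear warping. Pixel coordinates are 0-based, x right, y down;
# (0, 0) is the centre of the top-left pixel.

#' Fit a homography from point correspondences
#'
#' Least-squares homography mapping `src` points onto `dst` points, via the
#' normalized direct linear transform. Used both for the coarse UV-to-VIS
#' alignment (from manually matched points) and for locating the colour card
#' (from fiducial-marker corners).
#'
#' @param src,dst Numeric n x 2 matrices (or data frames) of matching points,
#'   n >= 4, not collinear.
#'
#' @return A 3 x 3 homography matrix, normalized so `H[3, 3] == 1`.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) abort("`src` and `dst` must pair up.")
  if (nrow(src) < 4) {
    abort(sprintf("Need at least 4 point pairs, got %d.", nrow(src)))
  }
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
                3, 3, byrow = TRUE)
    list(p = cbind(p, 1) %*% t(T), T = T)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (k in seq_len(n)) {
    X <- ns$p[k, ]; x <- nd$p[k, 1]; y <- nd$p[k, 2]
    A[2 * k - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * k, ]     <- c(0, 0, 0, -X, y * X)
  }
  ev <- eigen(crossprod(A), symmetric = TRUE)
  if (ev$values[8] < 1e-20 * max(ev$values[1], 1e-300)) {
    abort("Degenerate point configuration (collinear or coincident points).")
  }
  H <- matrix(ev$vectors[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(H[3, 3]) < 1e-12) abort("Degenerate homography (H[3,3] ~ 0).")
  H / H[3, 3]
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography.
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2)
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

# Bilinear sample of a single-channel matrix at (x, y) 0-based coords.
# Out-of-image samples return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  # clamp the +1 neighbour at the border so edge pixels stay sampleable
  x0c <- pmin(pmax(x0, 0), w - 1); y0c <- pmin(pmax(y0, 0), h - 1)
  x1c <- pmin(x0c + 1, w - 1); y1c <- pmin(y0c + 1, h - 1)
  idx <- function(yy, xx) yy + h * xx + 1  # column-major linear index
  v <- (1 - fx) * (1 - fy) * img[idx(y0c, x0c)] +
    fx * (1 - fy) * img[idx(y0c, x1c)] +
    (1 - fx) * fy * img[idx(y1c, x0c)] +
    fx * fy * img[idx(y1c, x1c)]
  v[!inside] <- fill
  v
}

#' Warp an image by a homography
#'
#' Backward warp with bilinear interpolation: output pixel (x, y) samples the
#' input at `H^-1 (x, y)`. Border value is 0 and a validity mask marking
#' pixels whose sample fell wholly inside the source is attached as attribute
#' `"valid"`, so downstream patch statistics can exclude border fill.
#'
#' @param img `image_plane` or numeric array.
#' @param H 3 x 3 homography mapping source coords to destination coords.
#' @param dim_out Output `c(height, width)`; default the input size.
#' @return Warped image of the same class, with a logical `"valid"` attribute.
#' @export
warp_image <- function(img, H, dim_out = NULL) {
  a <- as_bare_array(if (is.matrix(img)) array(img, c(dim(img), 1)) else img)
  d <- dim(a)
  if (is.null(dim_out)) dim_out <- d[1:2]
  Hinv <- solve(H)
  xy <- cbind(
    rep(0:(dim_out[2] - 1), each = dim_out[1]),
    rep(0:(dim_out[1] - 1), times = dim_out[2])
  )
  uv <- apply_homography(Hinv, xy)
  valid <- matrix(
    uv[, 1] >= 0 & uv[, 1] <= d[2] - 1 & uv[, 2] >= 0 & uv[, 2] <= d[1] - 1,
    dim_out[1], dim_out[2]
  )
  out <- array(0, c(dim_out, d[3]))
  for (c in seq_len(d[3])) {
    out[, , c] <- matrix(bilinear_sample(a[, , c], uv[, 1], uv[, 2]),
                         dim_out[1], dim_out[2])
  }
  res <- if (inherits(img, "image_plane")) with_plane(img, out) else out
  attr(res, "valid") <- valid
  res
}

#' Elementary homography constructors
#'
#' @param tx,ty Translation in pixels.
#' @return A 3 x 3 homography matrix.
#' @export
translation_matrix <- function(tx, ty) {
  matrix(c(1, 0, tx, 0, 1, ty, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' @rdname translation_matrix
#' @param a11,a12,a21,a22 Linear part of the affine map.
#' @export
affine_matrix <- function(a11, a12, tx, a21, a22, ty) {
  matrix(c(a11, a12, tx, a21, a22, ty, 0, 0, 1), 3, 3, byrow = TRUE)
}
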