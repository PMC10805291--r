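# Colour-card layout, fiducial-marker detection, and patch extraction.
#
# The card carries 4 square binary fiducial markers in its corners and a set
# of colour/grayscale patches of known reflectance. Marker bit patterns are
# data (a dictionary carried by the layout), not code.

#' Fiducial marker dictionary
#'
#' A named set of square binary bit patterns. Patterns must be
#' rotation-asymmetric and mutually distinct under rotation so a detected
#' marker identifies both its id and its orientation.
#'
#' @param name Dictionary family name.
#' @param patterns Named list (names = marker ids) of n x n 0/1 matrices
#'   (1 = white bit).
#' @return An object of class `marker_dictionary`.
#' @export
marker_dictionary <- function(name, patterns) {
  n <- unique(vapply(patterns, nrow, integer(1)))
  if (length(n) != 1 || any(vapply(patterns, ncol, integer(1)) != n)) {
    abort("All patterns must be square matrices of one size.")
  }
  # distinctness under rotation (also forbids self-symmetric patterns)
  keys <- character(0)
  for (id in names(patterns)) {
    for (r in 0:3) {
      k <- paste(rotate90(patterns[[id]], r), collapse = "")
      if (k %in% keys) {
        abort(sprintf("Pattern '%s' collides with another under rotation.", id))
      }
      keys <- c(keys, k)
    }
  }
  structure(list(name = name, patterns = patterns, n_bits = n),
            class = "marker_dictionary")
}

rotate90 <- function(m, times = 1) {
  for (i in seq_len(times %% 4)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Deterministic demo dictionary
#'
#' Generates `n_ids` rotation-distinct random bit patterns from a fixed seed.
#'
#' @param n_ids Number of marker ids.
#' @param n_bits Bits per side.
#' @param seed RNG seed (fixed default so the dictionary is stable data).
#' @return A [marker_dictionary()].
#' @export
demo_marker_dictionary <- function(n_ids = 4, n_bits = 4, seed = 7) {
  rng <- make_rng(seed)
  patterns <- list()
  keys <- character(0)
  while (length(patterns) < n_ids) {
    m <- matrix(as.integer(rng$unif(n_bits^2) > 0.5), n_bits, n_bits)
    ks <- vapply(0:3, function(r) paste(rotate90(m, r), collapse = ""),
                 character(1))
    if (anyDuplicated(ks) || any(ks %in% keys)) next
    keys <- c(keys, ks)
    patterns[[as.character(length(patterns))]] <- m
  }
  marker_dictionary("demo", patterns)
}

#' Colour-card layout
#'
#' Card-frame description: origin at the top-left marker's outer corner,
#' x right, y down, in card units (any physical unit; only ratios matter).
#'
#' @param dictionary A [marker_dictionary()].
#' @param markers Tibble with columns `id`, `x`, `y`, `size`: the outer
#'   top-left corner and side length of each of the 4 markers, in card units.
#' @param patches Tibble with columns `patch_id`, `x`, `y`, `w`, `h`.
#' @param reflectances Named list of `qc_spectrum` (kind `"reflectance"`),
#'   one per `patch_id`.
#' @return An object of class `card_layout`.
#' @export
card_layout <- function(dictionary, markers, patches, reflectances) {
  stopifnot(inherits(dictionary, "marker_dictionary"))
  markers <- as_tibble(markers); patches <- as_tibble(patches)
  if (nrow(markers) != 4 || anyDuplicated(markers$id)) {
    abort("A card layout needs exactly 4 distinct markers.")
  }
  if (!all(as.character(markers$id) %in% names(dictionary$patterns))) {
    abort("Every marker id must exist in the dictionary.")
  }
  missing_refl <- setdiff(as.character(patches$patch_id), names(reflectances))
  if (length(missing_refl)) {
    abort(sprintf("Missing reflectance for patch(es): %s.",
                  paste(missing_refl, collapse = ", ")))
  }
  for (id in names(reflectances)) {
    assert_kind(reflectances[[id]], "reflectance", arg = id)
  }
  structure(
    list(dictionary = dictionary, markers = markers, patches = patches,
         reflectances = reflectances),
    class = "card_layout"
  )
}

#' @export
print.card_layout <- function(x, ...) {
  cat(sprintf(
    "<card_layout> dictionary '%s', markers [%s], %d patches\n",
    x$dictionary$name, paste(x$markers$id, collapse = ", "), nrow(x$patches)
  ))
  invisible(x)
}

# Outer corners of one marker in card coords, order TL, TR, BR, BL.
marker_corners_card <- function(m) {
  rbind(
    c(m$x, m$y), c(m$x + m$size, m$y),
    c(m$x + m$size, m$y + m$size), c(m$x, m$y + m$size)
  )
}

otsu_threshold <- function(v) {
  h <- tabulate(pmin(pmax(floor(v * 256), 0), 255) + 1, 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- 0
  (which.max(sigma) - 0.5) / 256
}

to_intensity <- function(image) {
  a <- as_bare_array(image)
  if (dim(a)[3] == 1) a[, , 1] else apply(a, c(1, 2), mean)
}

# Sub-pixel edge localization: for points along a roughly known edge line,
# find where the intensity crosses the mid-level between the two sides,
# sampling along the edge normal. Returns refined points (or NULL).
refine_edge_points <- function(intensity, point, dir, len, n_samples = 9) {
  normal <- c(-dir[2], dir[1])
  along <- seq(-0.35 * len, 0.35 * len, length.out = n_samples)
  offs <- seq(-2, 2, by = 0.5)
  pts <- NULL
  for (a in along) {
    base <- point + a * dir
    sx <- base[1] + offs * normal[1]
    sy <- base[2] + offs * normal[2]
    v <- bilinear_sample(intensity, sx, sy, fill = NA)
    if (anyNA(v)) next
    mid <- (min(v) + max(v)) / 2
    if (max(v) - min(v) < 0.05) next
    cross <- which(diff(sign(v - mid)) != 0)
    if (!length(cross)) next
    i <- cross[which.min(abs(offs[cross]))]   # crossing nearest the line
    t <- (mid - v[i]) / (v[i + 1] - v[i])
    o <- offs[i] + t * (offs[i + 1] - offs[i])
    pts <- rbind(pts, base + o * normal)
  }
  if (is.null(pts) || nrow(pts) < 3) return(NULL)
  pts
}

# Given component pixel coords (x, y), estimate the 4 corners of the quad:
# extremes along the two diagonals, then refine each edge by a total
# least-squares line fit to the component's boundary pixels — sharpened to
# sub-pixel intensity crossings — and intersect adjacent edges.
quad_corners <- function(xs, ys, boundary_xy, intensity = NULL) {
  s <- xs + ys; d <- xs - ys
  init <- rbind(
    c(xs[which.min(s)], ys[which.min(s)]),  # TL
    c(xs[which.max(d)], ys[which.max(d)]),  # TR
    c(xs[which.max(s)], ys[which.max(s)]),  # BR
    c(xs[which.min(d)], ys[which.min(d)])   # BL
  )
  edges <- lapply(1:4, function(i) {
    p <- init[i, ]; q <- init[(i %% 4) + 1, ]
    v <- q - p; len <- sqrt(sum(v^2)); v <- v / len
    rel <- sweep(boundary_xy, 2, p)
    along <- rel %*% v
    perp <- abs(rel %*% c(-v[2], v[1]))
    sel <- along > 0.15 * len & along < 0.85 * len & perp < 1.8
    pts <- boundary_xy[sel, , drop = FALSE]
    if (nrow(pts) < 2) return(NULL)
    ctr <- colMeans(pts)
    e <- eigen(stats::cov(pts))
    dir <- e$vectors[, 1]
    if (!is.null(intensity)) {
      sub <- refine_edge_points(intensity, ctr, dir, len)
      if (!is.null(sub)) {
        ctr <- colMeans(sub)
        e <- eigen(stats::cov(sub))
        dir <- e$vectors[, 1]
      }
    }
    list(point = ctr, dir = dir)
  })
  if (any(vapply(edges, is.null, logical(1)))) return(init)
  corners <- matrix(0, 4, 2)
  for (i in 1:4) {
    e1 <- edges[[((i - 2) %% 4) + 1]]  # edge ending at corner i
    e2 <- edges[[i]]                   # edge starting at corner i
    A <- cbind(e1$dir, -e2$dir)
    if (abs(det(A)) < 1e-9) { corners[i, ] <- init[i, ]; next }
    t <- solve(A, e2$point - e1$point)
    corners[i, ] <- e1$point + t[1] * e1$dir
  }
  corners
}

decode_marker <- function(intensity, corners, dictionary) {
  n <- dictionary$n_bits
  ncell <- n + 2  # dark border one cell wide on each side
  H <- fit_homography(
    rbind(c(0, 0), c(ncell, 0), c(ncell, ncell), c(0, ncell)), corners
  )
  centers <- expand.grid(cx = seq_len(ncell) - 0.5, cy = seq_len(ncell) - 0.5)
  pts <- apply_homography(H, as.matrix(centers))
  vals <- matrix(bilinear_sample(intensity, pts[, 1], pts[, 2], fill = NA),
                 ncell, ncell)  # vals[i, j]: cell column i, row j
  if (anyNA(vals)) return(NULL)
  thr <- (min(vals) + max(vals)) / 2
  bits <- vals > thr
  border <- bits[c(1, ncell), ] | t(bits)[c(1, ncell), ]
  if (mean(c(bits[c(1, ncell), ], bits[, c(1, ncell)])) > 0.2) return(NULL)
  inner <- t(bits[2:(ncell - 1), 2:(ncell - 1)]) * 1L  # row = y, col = x
  for (id in names(dictionary$patterns)) {
    for (r in 0:3) {
      if (identical(rotate90(inner, r), dictionary$patterns[[id]])) {
        # rotating the read pattern r times CCW matched: the card's TL corner
        # is r steps around the detected quad
        return(list(id = id, corners = corners[((0:3 + r) %% 4) + 1, ]))
      }
    }
  }
  NULL
}

#' Detect the colour card in an image
#'
#' Thresholds the frame, finds dark square candidate regions, decodes their
#' bit patterns against the layout's dictionary, and fits the card-to-image
#' homography from the 16 outer corners of the 4 markers.
#'
#' @param image `image_plane` of a single camera frame (typically the VIS
#'   frame; markers may be invisible in UV).
#' @param layout A [card_layout()].
#' @param min_area Minimum candidate area in pixels.
#' @return A 3 x 3 homography mapping card-frame coordinates to image pixels.
#' @export
detect_card <- function(image, layout, min_area = 64) {
  intensity <- to_intensity(image)
  thr <- otsu_threshold(as.numeric(intensity))
  dark <- intensity < thr
  lab <- EBImage::bwlabel(dark * 1)
  labm <- matrix(as.integer(lab), nrow(dark), ncol(dark))
  found <- list()
  for (comp in setdiff(unique(as.integer(labm)), 0L)) {
    idx <- which(labm == comp)
    if (length(idx) < min_area) next
    ys <- (idx - 1) %% nrow(labm)         # 0-based row = y
    xs <- (idx - 1) %/% nrow(labm)        # 0-based col = x
    bw <- diff(range(xs)) + 1; bh <- diff(range(ys)) + 1
    if (bw < 6 || bh < 6) next
    if (bw / bh > 2 || bh / bw > 2) next
    if (length(idx) / (bw * bh) < 0.35) next   # squares w/ white bits cut out
    # boundary pixels: component pixels with a non-component 4-neighbour
    on <- matrix(FALSE, nrow(labm) + 2, ncol(labm) + 2)
    on[cbind(ys + 2, xs + 2)] <- TRUE
    inner_mask <- on[cbind(ys + 1, xs + 2)] & on[cbind(ys + 3, xs + 2)] &
      on[cbind(ys + 2, xs + 1)] & on[cbind(ys + 2, xs + 3)]
    bxy <- cbind(xs, ys)[!inner_mask, , drop = FALSE]
    corners <- quad_corners(xs, ys, bxy, intensity)
    dec <- decode_marker(intensity, corners, layout$dictionary)
    if (!is.null(dec)) found[[dec$id]] <- dec$corners
  }
  want <- as.character(layout$markers$id)
  if (!all(want %in% names(found))) {
    abort(sprintf(
      "Found marker id(s) [%s] but layout needs [%s]; missing: %s.",
      paste(names(found), collapse = ", "), paste(want, collapse = ", "),
      paste(setdiff(want, names(found)), collapse = ", ")
    ))
  }
  card_pts <- do.call(rbind, lapply(seq_len(4), function(i) {
    marker_corners_card(layout$markers[i, ])
  }))
  img_pts <- do.call(rbind, found[as.character(layout$markers$id)])
  fit_homography(card_pts, img_pts)
}

#' Extract patch pixel statistics
#'
#' Each patch rectangle is shrunk toward its centre by `shrink` per side
#' (guarding against bleed from neighbouring patches), projected into the
#' image, and summarized per channel over the covered pixels.
#'
#' @param image `image_plane`.
#' @param layout A [card_layout()].
#' @param H Card-to-image homography, e.g. from [detect_card()].
#' @param shrink Fraction in \[0, 0.45\] removed from each side.
#' @param trim Trim fraction for the trimmed mean (default 0.1).
#' @return A tibble with one row per patch and channel: `patch_id`,
#'   `channel`, `mean`, `trimmed_mean`, `n_pixels`, `saturation_fraction`,
#'   `outside` (patch projected (partly) outside the image).
#' @export
extract_patches <- function(image, layout, H, shrink = 0.25, trim = 0.1) {
  if (shrink < 0 || shrink > 0.45) abort("`shrink` must be in [0, 0.45].")
  a <- as_bare_array(image)
  labs <- image_channels(image) %||% paste0("ch", seq_len(dim(a)[3]))
  valid <- attr(image, "valid")
  h <- dim(a)[1]; w <- dim(a)[2]
  purrr::map_dfr(seq_len(nrow(layout$patches)), function(i) {
    p <- layout$patches[i, ]
    x0 <- p$x + shrink * p$w; x1 <- p$x + (1 - shrink) * p$w
    y0 <- p$y + shrink * p$h; y1 <- p$y + (1 - shrink) * p$h
    # sample the shrunk rect densely relative to its pixel footprint
    corners <- apply_homography(H, rbind(c(x0, y0), c(x1, y0),
                                         c(x1, y1), c(x0, y1)))
    span <- max(diff(range(corners[, 1])), diff(range(corners[, 2])))
    nsamp <- max(8, ceiling(span * 2))
    g <- as.matrix(expand.grid(
      x = seq(x0, x1, length.out = nsamp),
      y = seq(y0, y1, length.out = nsamp)
    ))
    pix <- round(apply_homography(H, g))
    inside <- pix[, 1] >= 0 & pix[, 1] <= w - 1 & pix[, 2] >= 0 & pix[, 2] <= h - 1
    outside <- any(!inside)
    pix <- unique(pix[inside, , drop = FALSE])
    if (!is.null(valid) && nrow(pix)) {
      ok <- valid[cbind(pix[, 2] + 1, pix[, 1] + 1)]
      pix <- pix[ok, , drop = FALSE]
    }
    if (!nrow(pix)) {
      return(tibble(
        patch_id = as.character(p$patch_id), channel = labs, mean = NA_real_,
        trimmed_mean = NA_real_, n_pixels = 0L, saturation_fraction = NA_real_,
        outside = TRUE
      ))
    }
    purrr::map_dfr(seq_along(labs), function(ch) {
      v <- a[, , ch][cbind(pix[, 2] + 1, pix[, 1] + 1)]
      tibble(
        patch_id = as.character(p$patch_id), channel = labs[ch],
        mean = mean(v), trimmed_mean = mean(v, trim = trim),
        n_pixels = nrow(pix),
        saturation_fraction = mean(v >= 1 - 0.5 / 255),
        outside = outside
      )
    })
  })
}

#' Ideal catches of the card's patches
#'
#' Target catches of every patch for a relativized channel set under ideal
#' illumination; the right-hand side of the normalization regression.
#'
#' @param layout A [card_layout()].
#' @param cs Relativized [channel_set()].
#' @param grid A [grid_policy()].
#' @param patch_ids Optional subset of patches.
#' @return Tibble with `patch_id`, `channel`, `target`.
#' @export
patch_target_catches <- function(layout, cs, grid = grid_policy(),
                                 patch_ids = NULL) {
  ids <- patch_ids %||% as.character(layout$patches$patch_id)
  purrr::map_dfr(ids, function(id) {
    cc <- channel_catches(layout$reflectances[[id]], cs, NULL, grid)
    tibble(patch_id = id, channel = names(cc), target = unname(cc))
  })
}

#' Save / load a card layout as JSON
#'
#' The layout is fully self-describing: marker ids, dictionary bit patterns,
#' marker and patch geometry, and per-patch reflectances as relative paths to
#' two-column CSV files next to the JSON.
#'
#' @param layout A [card_layout()].
#' @param path JSON file path; reflectance CSVs go into a `spectra/`
#'   directory beside it.
#' @return `read_card_layout_json()` returns a `card_layout`.
#' @export
write_card_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "card_layout"))
  spectra_dir <- file.path(dirname(path), "spectra")
  dir.create(spectra_dir, showWarnings = FALSE, recursive = TRUE)
  refl_paths <- vapply(names(layout$reflectances), function(id) {
    p <- file.path("spectra", paste0(id, ".csv"))
    write_spectrum_csv(layout$reflectances[[id]],
                       file.path(dirname(path), p))
    p
  }, character(1))
  jsonlite::write_json(
    list(
      dictionary = list(
        name = layout$dictionary$name,
        n_bits = layout$dictionary$n_bits,
        patterns = lapply(layout$dictionary$patterns, function(m) {
          unname(apply(m, 1, function(r) paste(r, collapse = "")))
        })
      ),
      markers = layout$markers,
      patches = dplyr::mutate(
        layout$patches,
        reflectance_csv = unname(refl_paths[as.character(.data$patch_id)])
      )
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' @rdname write_card_layout_json
#' @export
read_card_layout_json <- function(path) {
  j <- jsonlite::read_json(path)
  patterns <- lapply(j$dictionary$patterns, function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]])
    }))
  })
  dict <- marker_dictionary(j$dictionary$name, patterns)
  markers <- dplyr::bind_rows(lapply(j$markers, as_tibble))
  markers$id <- as.character(markers$id)
  patches <- dplyr::bind_rows(lapply(j$patches, as_tibble))
  refl <- setNames(lapply(seq_len(nrow(patches)), function(i) {
    read_spectrum_csv(file.path(dirname(path), patches$reflectance_csv[i]),
                      "reflectance")
  }), as.character(patches$patch_id))
  card_layout(dict, markers,
              patches[, c("patch_id", "x", "y", "w", "h")], refl)
}
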