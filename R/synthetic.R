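# Synthetic optical simulator: reflectance libraries, camera and receptor
# sensitivity sets, rendered dual-camera frames and videos with a colour
# card, misalignment, frame offset and noise, and monochromator sweeps —
# everything the pipeline consumes, with known ground truth.
#
# All randomness flows through an explicit seeded generator object; there is
# no hidden global state.

#' Explicit seeded random generator
#'
#' Wraps R's Mersenne Twister behind an object so simulator randomness is
#' reproducible and never leaks into (or depends on) the caller's RNG state.
#'
#' @param seed Integer seed.
#' @return A list of draw functions: `unif`, `norm`, `int`, `sample`.
#' @export
make_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    genv <- globalenv()
    old <- if (exists(".Random.seed", genv, inherits = FALSE)) {
      get(".Random.seed", genv)
    } else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, genv)
    res <- expr
    state <<- get(".Random.seed", genv)
    if (is.null(old)) {
      rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, genv)
    }
    res
  }
  list(
    unif = function(n, min = 0, max = 1) with_state(runif(n, min, max)),
    norm = function(n, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    int = function(n, from, to) {
      with_state(sample(seq.int(from, to), n, replace = TRUE))
    },
    sample = function(x, size = length(x), replace = FALSE) {
      with_state(sample(x, size, replace))
    }
  )
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian reflectance spectrum
#'
#' @param peak_nm Peak wavelength, nm.
#' @param fwhm_nm Full width at half maximum, nm (> 0).
#' @param amplitude Peak reflectance in (0, 1].
#' @param grid A [grid_policy()].
#' @return `qc_spectrum` of kind `"reflectance"` on the grid.
#' @export
gaussian_reflectance <- function(peak_nm, fwhm_nm, amplitude = 1,
                                 grid = grid_policy()) {
  if (fwhm_nm <= 0) abort("`fwhm_nm` must be positive.")
  if (amplitude <= 0 || amplitude > 1) abort("`amplitude` must be in (0, 1].")
  wl <- grid_wavelengths(grid)
  spectrum(wl, amplitude * exp(-(wl - peak_nm)^2 / (2 * fwhm_to_sd(fwhm_nm)^2)),
           "reflectance")
}

#' Gaussian sensitivity spectrum
#'
#' @inheritParams gaussian_reflectance
#' @return `qc_spectrum` of kind `"sensitivity"` (peak value 1).
#' @export
gaussian_sensitivity <- function(peak_nm, fwhm_nm, grid = grid_policy()) {
  wl <- grid_wavelengths(grid)
  spectrum(wl, exp(-(wl - peak_nm)^2 / (2 * fwhm_to_sd(fwhm_nm)^2)),
           "sensitivity")
}

sigmoid <- function(x, mid, width) 1 / (1 + exp(-(x - mid) / width))

#' Synthetic smooth reflectance library
#'
#' Mixtures of 1-3 Gaussians plus an optional sigmoidal red/blue edge,
#' scaled into \[0, 1\] — smooth, nonnegative spectra emulating the
#' statistics of natural materials (floral and otherwise), which is exactly
#' the regularity the camera-to-receptor transformation exploits. The
#' default size mirrors a library of 2,494 spectra with a 90/10 train/test
#' split.
#'
#' @param n Number of spectra (default 2494).
#' @param seed Seed for the library's generator.
#' @param fwhm_range Range of component FWHMs, nm.
#' @param grid A [grid_policy()].
#' @return List of `n` reflectance spectra.
#' @export
synth_library <- function(n = 2494, seed = 1, fwhm_range = c(90, 260),
                          grid = grid_policy()) {
  if (n < 1) abort("`n` must be >= 1.")
  rng <- make_rng(seed)
  wl <- grid_wavelengths(grid)
  lapply(seq_len(n), function(i) {
    v <- rep(rng$unif(1, 0, 0.15), length(wl))       # flat base
    for (k in seq_len(rng$int(1, 1, 3))) {
      pk <- rng$unif(1, 280, 720)
      fw <- rng$unif(1, fwhm_range[1], fwhm_range[2])
      amp <- rng$unif(1, 0.1, 1)
      v <- v + amp * exp(-(wl - pk)^2 / (2 * fwhm_to_sd(fw)^2))
    }
    if (rng$unif(1) < 0.4) {                          # sigmoidal edge
      mid <- rng$unif(1, 350, 650)
      width <- rng$unif(1, 25, 80)
      dir <- if (rng$unif(1) < 0.7) 1 else -1
      v <- v + rng$unif(1, 0.2, 0.8) * sigmoid(dir * wl, dir * mid, width)
    }
    top <- max(v)
    if (top > 1) v <- v / (top + 1e-6) * rng$unif(1, 0.75, 1)
    spectrum(wl, pmin(pmax(v, 0), 1), "reflectance")
  })
}

#' Synthetic dual-camera sensitivity sets
#'
#' A UV camera with three highly overlapping bands below ~400 nm and a VIS
#' camera with blue/green/red bands above ~425 nm, leaving the inter-camera
#' sensitivity gap near 390-425 nm that a beam-splitter system has. Returns
#' the per-camera sets plus the default 4-channel fitting set (UV red channel
#' + the three VIS channels), all relativized.
#'
#' @param grid A [grid_policy()].
#' @param gap Two-sided cut: UV channels are suppressed above `gap[1]` nm,
#'   VIS channels below `gap[2]` nm.
#' @return List with `channel_set`s `uv`, `vis`, and `combined`.
#' @export
synth_camera <- function(grid = grid_policy(), gap = c(390, 425)) {
  wl <- grid_wavelengths(grid)
  # shortpass cut above the gap plus the silicon sensor's deep-UV roll-off
  uv_cut <- (1 - sigmoid(wl, gap[1], 4)) * sigmoid(wl, 330, 8)
  vis_cut <- sigmoid(wl, gap[2], 4)
  band <- function(pk, fw, cut) {
    v <- exp(-(wl - pk)^2 / (2 * fwhm_to_sd(fw)^2)) * cut
    spectrum(wl, v, "sensitivity")
  }
  uv <- channel_set("uv_cam", list(
    uv_r = band(355, 70, uv_cut),
    uv_g = band(349, 68, uv_cut),
    uv_b = band(361, 72, uv_cut)
  ))
  vis <- channel_set("vis_cam", list(
    vis_b = band(465, 80, vis_cut),
    vis_g = band(535, 85, vis_cut),
    vis_r = band(610, 115, vis_cut)
  ))
  combined <- channel_set("camera", list(
    uv_r = band(355, 70, uv_cut),
    vis_b = band(465, 80, vis_cut),
    vis_g = band(535, 85, vis_cut),
    vis_r = band(610, 115, vis_cut)
  ))
  list(
    uv = relativize(uv, grid),
    vis = relativize(vis, grid),
    combined = relativize(combined, grid)
  )
}

#' Example animal receptor sets
#'
#' Template-based receptor sets for a UV/blue/green trichromat bee-like
#' viewer and a UV-sensitive tetrachromat bird-like viewer.
#'
#' @param viewer `"bee"` (peaks 344, 436, 544 nm) or `"bird"`
#'   (370, 445, 508, 565 nm).
#' @param grid A [grid_policy()].
#' @return A relativized [channel_set()].
#' @export
example_receptors <- function(viewer = c("bee", "bird"),
                              grid = grid_policy()) {
  viewer <- match.arg(viewer)
  if (viewer == "bird") {
    return(template_receptor_set(c(uv = 370, b = 445, g = 508, r = 565),
                                 "A1", name = viewer, grid = grid))
  }
  # the honeybee UV receptor is narrower and less far-UV-sensitive than the
  # generic pigment template; emulate that with a deep-UV roll-off
  wl <- grid_wavelengths(grid)
  uv_t <- receptor_template(344, "A1", grid)
  uv <- spectrum(wl, uv_t$value * sigmoid(wl, 320, 6), "sensitivity")
  relativize(channel_set(viewer, list(
    uv = uv,
    b = receptor_template(436, "A1", grid),
    g = receptor_template(544, "A1", grid)
  )), grid)
}

#' Demo colour-card layout
#'
#' A card with 4 fiducial markers in its corners, an 8-step grayscale (99%
#' down to 2% flat reflectance) for normalization, and `n_colors` smooth
#' colour patches for validation. Card units are abstract; the card spans
#' roughly 100 x 72 units.
#'
#' @param n_colors Number of colour patches (default 12).
#' @param seed Seed for the colour patch reflectances.
#' @param grid A [grid_policy()].
#' @return A [card_layout()].
#' @export
demo_card_layout <- function(n_colors = 12, seed = 42, grid = grid_policy()) {
  dict <- demo_marker_dictionary()
  marker_size <- 12
  markers <- tibble(
    id = c("0", "1", "2", "3"),
    x = c(0, 88, 88, 0), y = c(0, 0, 60, 60),
    size = marker_size
  )
  wl <- grid_wavelengths(grid)
  gray_levels <- c(0.99, 0.80, 0.60, 0.40, 0.20, 0.10, 0.05, 0.02)
  grays <- tibble(
    patch_id = paste0("gray_", seq_along(gray_levels)),
    x = 16 + (seq_along(gray_levels) - 1) * 8.5, y = 2, w = 7, h = 10
  )
  n_col_rows <- ceiling(n_colors / 6)
  cols <- tibble(
    patch_id = paste0("color_", seq_len(n_colors)),
    x = 16 + ((seq_len(n_colors) - 1) %% 6) * 11,
    y = 16 + ((seq_len(n_colors) - 1) %/% 6) * 13,
    w = 9, h = 11
  )
  patches <- dplyr::bind_rows(grays, cols)
  refl <- c(
    setNames(lapply(gray_levels, function(g) {
      spectrum(wl, rep(g, length(wl)), "reflectance")
    }), grays$patch_id),
    setNames(synth_library(n_colors, seed = seed, grid = grid), cols$patch_id)
  )
  card_layout(dict, markers, patches, refl)
}

#' Scene specification for the synthetic renderer
#'
#' Bundles everything needed to render a dual-camera recording of the colour
#' card with known ground truth.
#'
#' @param layout A [card_layout()].
#' @param illuminant Scene illuminant (`NULL` = ideal isoluminance).
#' @param cameras As returned by [synth_camera()].
#' @param misalignment 3 x 3 homography mapping VIS pixel coords to UV pixel
#'   coords (the inverse of the alignment the pipeline must recover).
#' @param frame_offset Integer frame delay of the UV stream.
#' @param noise_sd Gaussian read noise sd in 8-bit pixel units (0-255 scale).
#' @param exposure Per-camera linear gain applied before encoding (named
#'   list `uv`, `vis`).
#' @param dim_px Image `c(height, width)` in pixels.
#' @param k [slog3_constants()] used for encoding.
#' @param seed Seed for the scene's noise generator.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(layout, illuminant = NULL, cameras = synth_camera(),
                       misalignment = diag(3), frame_offset = 0L,
                       noise_sd = 0, exposure = list(uv = 1, vis = 1),
                       dim_px = c(144, 192), k = slog3_constants(),
                       seed = 1) {
  structure(
    list(layout = layout, illuminant = illuminant, cameras = cameras,
         misalignment = misalignment, frame_offset = as.integer(frame_offset),
         noise_sd = noise_sd, exposure = exposure, dim_px = dim_px, k = k,
         seed = seed),
    class = "scene_spec"
  )
}

# Homography placing the card into the frame: card units -> VIS pixels,
# with a margin, optional rotation about the card centre, and translation.
card_pose <- function(layout, dim_px, rotation_deg = 0, translate_px = c(0, 0)) {
  card_w <- max(layout$markers$x + layout$markers$size,
                layout$patches$x + layout$patches$w)
  card_h <- max(layout$markers$y + layout$markers$size,
                layout$patches$y + layout$patches$h)
  s <- min((dim_px[2] * 0.78) / card_w, (dim_px[1] * 0.78) / card_h)
  th <- rotation_deg * pi / 180
  ctr_card <- c(card_w, card_h) / 2
  ctr_img <- c(dim_px[2], dim_px[1]) / 2 + translate_px
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  A <- s * R
  t_vec <- ctr_img - A %*% ctr_card
  affine_matrix(A[1, 1], A[1, 2], t_vec[1], A[2, 1], A[2, 2], t_vec[2])
}

# Values of the card content at card-frame points, for one channel.
# `patch_vals` is a named vector of encoded (or linear) per-patch values;
# `marker_dark`/`card_white` are background levels in the same units.
card_content_at <- function(layout, pts, patch_vals, card_white, marker_dark,
                            outside_val) {
  x <- pts[, 1]; y <- pts[, 2]
  card_w <- max(layout$markers$x + layout$markers$size,
                layout$patches$x + layout$patches$w)
  card_h <- max(layout$markers$y + layout$markers$size,
                layout$patches$y + layout$patches$h)
  v <- rep(outside_val, length(x))
  on_card <- x >= -3 & x <= card_w + 3 & y >= -3 & y <= card_h + 3
  v[on_card] <- card_white
  for (i in seq_len(nrow(layout$patches))) {
    p <- layout$patches[i, ]
    sel <- x >= p$x & x < p$x + p$w & y >= p$y & y < p$y + p$h
    v[sel] <- patch_vals[[as.character(p$patch_id)]]
  }
  dict <- layout$dictionary
  ncell <- dict$n_bits + 2
  for (i in seq_len(nrow(layout$markers))) {
    m <- layout$markers[i, ]
    cell <- m$size / ncell
    lx <- x - m$x; ly <- y - m$y
    sel <- lx >= 0 & lx < m$size & ly >= 0 & ly < m$size
    if (!any(sel)) next
    ci <- pmin(floor(lx[sel] / cell), ncell - 1)   # column, 0-based
    ri <- pmin(floor(ly[sel] / cell), ncell - 1)   # row, 0-based
    pat <- dict$patterns[[as.character(m$id)]]
    is_border <- ci == 0 | ri == 0 | ci == ncell - 1 | ri == ncell - 1
    bit_white <- !is_border &
      pat[cbind(pmin(pmax(ri, 1), dict$n_bits), pmin(pmax(ci, 1), dict$n_bits))] == 1
    v[sel] <- ifelse(is_border | !bit_white, marker_dark, card_white)
  }
  v
}

# Render one channel: supersampled backward mapping from image pixels to
# card coordinates, then box-filter downsampling.
render_channel <- function(layout, H_card_to_img, dim_px, patch_vals,
                           card_white, marker_dark, outside_val, ss = 3) {
  h <- dim_px[1]; w <- dim_px[2]
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  xs <- rep(0:(w - 1), each = ss) + rep(sub, times = w)
  ys <- rep(0:(h - 1), each = ss) + rep(sub, times = h)
  pts_img <- cbind(
    rep(xs, each = h * ss),
    rep(ys, times = w * ss)
  )
  pts_card <- apply_homography(solve(H_card_to_img), pts_img)
  v <- card_content_at(layout, pts_card, patch_vals, card_white, marker_dark,
                       outside_val)
  full <- matrix(v, h * ss, w * ss)
  # average ss x ss blocks
  m <- matrix(0, h, w)
  for (i in seq_len(ss)) for (j in seq_len(ss)) {
    m <- m + full[seq(i, h * ss, by = ss), seq(j, w * ss, by = ss)]
  }
  m / ss^2
}

# Per-patch linear camera values for one camera under the scene illuminant.
scene_patch_linear <- function(layout, cs, illuminant, exposure,
                               grid = grid_policy()) {
  ids <- as.character(layout$patches$patch_id)
  vals <- lapply(ids, function(id) {
    exposure * channel_catches(layout$reflectances[[id]], cs, illuminant, grid)
  })
  setNames(vals, ids)
}

# Linear-domain base image of one camera (no overlay, noise or encoding).
render_linear_base <- function(scene, cs, H_card_to_img, exposure,
                               grid = grid_policy()) {
  labs <- channel_labels(cs)
  lin <- scene_patch_linear(scene$layout, cs, scene$illuminant, exposure, grid)
  white <- exposure * vapply(cs$channels, function(s) {
    quantum_catch(spectrum(grid_wavelengths(grid),
                           rep(0.92, length(grid_wavelengths(grid))),
                           "reflectance"),
                  s, scene$illuminant, grid)
  }, numeric(1))
  dark <- 0.02 * white
  outside <- 0.25 * white
  linear <- array(0, c(scene$dim_px, length(labs)))
  for (ch in seq_along(labs)) {
    pv <- lapply(lin, function(v) v[[ch]])
    linear[, , ch] <- render_channel(scene$layout, H_card_to_img,
                                     scene$dim_px, pv, white[[ch]],
                                     dark[[ch]], outside[[ch]])
  }
  list(linear = linear, dark = dark, labs = labs)
}

render_camera_frame <- function(scene, cs, H_card_to_img, exposure,
                                rng = NULL, grid = grid_policy(),
                                overlay_alpha = NULL, overlay_H = diag(3)) {
  labs <- channel_labels(cs)
  lin <- scene_patch_linear(scene$layout, cs, scene$illuminant, exposure, grid)
  white <- exposure * vapply(cs$channels, function(s) {
    quantum_catch(spectrum(grid_wavelengths(grid),
                           rep(0.92, length(grid_wavelengths(grid))),
                           "reflectance"),
                  s, scene$illuminant, grid)
  }, numeric(1))
  dark <- 0.02 * white
  outside <- 0.25 * white
  alpha <- if (!is.null(overlay_alpha)) {
    h <- scene$dim_px[1]; w <- scene$dim_px[2]
    pts <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), times = w))
    ref <- apply_homography(overlay_H, pts)   # this camera -> reference coords
    matrix(overlay_alpha(ref[, 1], ref[, 2]), h, w)
  }
  out <- array(0, c(scene$dim_px, length(labs)))
  for (ch in seq_along(labs)) {
    pv <- lapply(lin, function(v) v[[ch]])
    linear <- render_channel(scene$layout, H_card_to_img, scene$dim_px, pv,
                             white[[ch]], dark[[ch]], outside[[ch]])
    if (!is.null(alpha)) {
      linear <- linear * (1 - alpha) + alpha * dark[[ch]]
    }
    enc <- linear_to_slog3(linear, scene$k)
    if (!is.null(rng) && scene$noise_sd > 0) {
      enc <- enc + rng$norm(length(enc), 0, scene$noise_sd / 255)
    }
    out[, , ch] <- matrix(pmin(pmax(enc, 0), 1), scene$dim_px[1],
                          scene$dim_px[2])
  }
  quantize_8bit(image_plane(out, "encoded", labs))
}

#' Render one dual-camera frame pair
#'
#' Forward model of the recording chain: per patch, camera catches under the
#' scene illuminant and exposure gain, painted into the frame geometry,
#' encoded to S-Log3, 8-bit quantized, with the UV frame warped by the scene
#' misalignment and seeded Gaussian read noise added. Ground truth (ideal
#' camera catches, per-patch saturation flags, the card pose and the
#' misalignment) is returned alongside.
#'
#' @param scene A [scene_spec()].
#' @param rotation_deg,translate_px Card pose in the VIS frame.
#' @return List: `uv` and `vis` encoded `image_plane`s, and `truth` (list
#'   with `H_card_to_vis`, `misalignment`, tibble `cc_ideal` of per-patch
#'   ideal camera catches for the combined fitting channels, and `saturated`
#'   flags).
#' @export
render_frames <- function(scene, rotation_deg = 0, translate_px = c(0, 0)) {
  stopifnot(inherits(scene, "scene_spec"))
  rng <- make_rng(scene$seed)
  H_card_vis <- card_pose(scene$layout, scene$dim_px, rotation_deg,
                          translate_px)
  H_card_uv <- scene$misalignment %*% H_card_vis
  vis <- render_camera_frame(scene, scene$cameras$vis, H_card_vis,
                             scene$exposure$vis, rng)
  uv <- render_camera_frame(scene, scene$cameras$uv, H_card_uv,
                            scene$exposure$uv, rng)
  ids <- as.character(scene$layout$patches$patch_id)
  cc <- purrr::map_dfr(ids, function(id) {
    v <- channel_catches(scene$layout$reflectances[[id]],
                         scene$cameras$combined, NULL)
    tibble(patch_id = id, channel = names(v), cc_ideal = unname(v))
  })
  lin_vis <- scene_patch_linear(scene$layout, scene$cameras$vis,
                                scene$illuminant, scene$exposure$vis)
  lin_uv <- scene_patch_linear(scene$layout, scene$cameras$uv,
                               scene$illuminant, scene$exposure$uv)
  enc_top <- 1 # encoded values above 1 clip
  saturated <- vapply(ids, function(id) {
    any(linear_to_slog3(c(lin_vis[[id]], lin_uv[[id]]), scene$k) > enc_top)
  }, logical(1))
  list(
    uv = uv, vis = vis,
    truth = list(
      H_card_to_vis = H_card_vis, misalignment = scene$misalignment,
      cc_ideal = cc, saturated = tibble(patch_id = ids, saturated = saturated)
    )
  )
}

#' Render a dual-camera video with motion and frame offset
#'
#' The card sits still while a dark occluder bar sweeps across the scene
#' along a seeded random direction; the UV stream is delayed by
#' `scene$frame_offset` frames. A static background plus an independently
#' moving object makes the frame offset identifiable: a wrong offset cannot
#' be compensated by any single spatial warp that also keeps the static card
#' aligned. Per-frame ground truth is returned.
#'
#' @param scene A [scene_spec()].
#' @param n_frames Number of VIS frames.
#' @param motion_px Total sweep of the occluder over the sequence, pixels.
#' @param bar_width_px Occluder width, pixels.
#' @return List: `uv`, `vis` (lists of encoded frames, equal length) and
#'   `truth` (card pose, misalignment, offset, per-frame bar positions).
#' @export
render_video <- function(scene, n_frames, motion_px = 30, bar_width_px = 9) {
  stopifnot(inherits(scene, "scene_spec"))
  off <- scene$frame_offset
  if (n_frames <= 2 * abs(off) + 2) {
    abort("`n_frames` must exceed 2*|frame_offset| + 2.")
  }
  rng <- make_rng(scene$seed)
  vertical <- rng$unif(1) < 0.5
  x0 <- rng$unif(1, 0.15, 0.35) *
    (if (vertical) scene$dim_px[2] else scene$dim_px[1])
  bar_pos <- function(t) x0 + (t - 1) / max(n_frames - 1, 1) * motion_px
  bar_alpha <- function(s) {
    function(x, y) {
      u <- if (vertical) x else y
      d <- abs(u - bar_pos(s)) - bar_width_px / 2
      pmin(pmax(1 - d, 0), 1)  # 1 inside the bar, soft 1-px edge
    }
  }
  H_vis <- card_pose(scene$layout, scene$dim_px, 0, c(0, 0))
  H_uv <- scene$misalignment %*% H_vis
  uv_to_vis <- solve(scene$misalignment)
  # the card is static: render the linear base of each camera once
  base_vis <- render_linear_base(scene, scene$cameras$vis, H_vis,
                                 scene$exposure$vis)
  base_uv <- render_linear_base(scene, scene$cameras$uv, H_uv,
                                scene$exposure$uv)
  vis_coords <- function(H) {
    h <- scene$dim_px[1]; w <- scene$dim_px[2]
    pts <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), times = w))
    apply_homography(H, pts)
  }
  pts_vis <- vis_coords(diag(3))
  pts_uv <- vis_coords(uv_to_vis)
  compose <- function(base, pts, s) {
    af <- bar_alpha(s)
    alpha <- matrix(af(pts[, 1], pts[, 2]), scene$dim_px[1], scene$dim_px[2])
    out <- array(0, dim(base$linear))
    for (ch in seq_len(dim(base$linear)[3])) {
      lin <- base$linear[, , ch] * (1 - alpha) + alpha * base$dark[[ch]]
      enc <- linear_to_slog3(lin, scene$k)
      if (scene$noise_sd > 0) {
        enc <- enc + rng$norm(length(enc), 0, scene$noise_sd / 255)
      }
      out[, , ch] <- pmin(pmax(enc, 0), 1)
    }
    quantize_8bit(image_plane(out, "encoded", base$labs))
  }
  vis <- lapply(seq_len(n_frames), function(t) compose(base_vis, pts_vis, t))
  # UV frame t shows the scene as it was `off` frames earlier
  uv <- lapply(seq_len(n_frames), function(t) {
    compose(base_uv, pts_uv, t - off)
  })
  list(uv = uv, vis = vis,
       truth = list(H_card_to_vis = H_vis, misalignment = scene$misalignment,
                    frame_offset = off,
                    bar_positions = vapply(seq_len(n_frames), bar_pos,
                                           numeric(1))))
}

#' Synthetic monochromator sweep
#'
#' Generates sweep measurements from a known sensitivity set: narrowband
#' Gaussian irradiance at each step, lit pixel values from the forward model
#' `P = gain * sum(S * I) + dark`, plus seeded noise — closing the loop for
#' the sensitivity estimator.
#'
#' @param true_sensitivity A [channel_set()] (the ground truth).
#' @param step_nm Sweep step (default 5 nm).
#' @param range_nm Sweep range (default 280-800 nm).
#' @param irradiance_fwhm_nm FWHM of each narrowband emission (default 7.3).
#' @param flux_peak Peak photon flux of each emission.
#' @param gain Pixel units per unit flux-weighted sensitivity.
#' @param dark_offset Constant dark level added to lit and dark readings.
#' @param noise_sd Gaussian noise sd on the pixel readings.
#' @param seed Seed.
#' @return List of [sweep_measurement()] objects.
#' @export
synth_sweep <- function(true_sensitivity, step_nm = 5, range_nm = c(280, 800),
                        irradiance_fwhm_nm = 7.3, flux_peak = 10, gain = 20,
                        dark_offset = 2, noise_sd = 0, seed = 1) {
  stopifnot(inherits(true_sensitivity, "channel_set"))
  rng <- make_rng(seed)
  labs <- channel_labels(true_sensitivity)
  wl_set <- seq(range_nm[1], range_nm[2], by = step_nm)
  sd_irr <- fwhm_to_sd(irradiance_fwhm_nm)
  lapply(wl_set, function(w0) {
    irr_wl <- seq(max(250, w0 - 40), w0 + 40, by = 1)
    irr <- spectrum(irr_wl, flux_peak * exp(-(irr_wl - w0)^2 / (2 * sd_irr^2)),
                    "illuminant")
    lit <- vapply(true_sensitivity$channels, function(s) {
      sv <- approx(s$wavelength, s$value, xout = irr_wl, rule = 1)$y
      sv[is.na(sv)] <- 0
      gain * sum(sv * irr$value) + dark_offset +
        if (noise_sd > 0) rng$norm(1, 0, noise_sd) else 0
    }, numeric(1))
    dark <- setNames(rep(dark_offset, length(labs)) +
                       if (noise_sd > 0) rng$norm(length(labs), 0, noise_sd)
                     else 0, labs)
    sweep_measurement(w0, irr, pmax(setNames(lit, labs), 0), pmax(dark, 0))
  })
}
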