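# Closed-loop benchmarks: every quantity is recovered by running the full
# pipeline against the synthetic simulator's known ground truth. These are
# the package's own accuracy checks, shared by the test suite and the
# reproduction script.

#' S-Log3 round-trip error
#'
#' Encodes linear values to S-Log3, quantizes to 8 bits, and decodes back.
#' The linear probe values are the decode-curve values at points between
#' adjacent 8-bit codes, i.e. the values that maximally expose quantization.
#' The theoretical floor is the maximum local slope of the decode curve per
#' half quantization step; a mean absolute error at or below ~1.5x that
#' floor means the inversion adds essentially nothing beyond the 8-bit
#' quantization itself.
#'
#' @param k [slog3_constants()].
#' @param per_code Probe points per code interval.
#' @return List: `mean_abs_error`, `max_abs_error`, `floor` (max local slope
#'   x 1/512), `ratio` (mean error / floor), `n`.
#' @export
slog3_roundtrip_error <- function(k = slog3_constants(), per_code = 4) {
  codes <- (0:255) / 255
  r_codes <- slog3_to_linear(codes, k)
  # probe linear values strictly between codes
  frac <- (seq_len(per_code) - 0.5) / per_code
  x_probe <- as.vector(outer(frac / 255, (0:254) / 255, "+"))
  r_in <- slog3_to_linear(x_probe, k)
  r_out <- slog3_to_linear(quantize_8bit(linear_to_slog3(r_in, k)), k)
  err <- abs(r_out - r_in)
  slope <- max(abs(diff(r_codes))) * 255
  floor_err <- slope / 512
  list(
    mean_abs_error = mean(err), max_abs_error = max(err),
    floor = floor_err, ratio = mean(err) / floor_err, n = length(err)
  )
}

#' Closed-loop spatio-temporal alignment recovery trials
#'
#' For each trial, draws a random rigid-plus-affine UV misalignment
#' (translation up to +/-4 px, linear terms up to +/-0.012) and an integer
#' frame offset (up to +/-3), renders a short dual-camera video with a
#' static colour card and a moving occluder, and runs [temporal_align()]
#' blind. Success means the offset is recovered exactly and the corner
#' reprojection error of the spatial model stays within `corner_tol_px`.
#'
#' @param n_trials Number of seeded trials.
#' @param seed Base seed.
#' @param dim_px Frame size (default 96 x 128; scaled-down stand-in for real
#'   frames, which are far larger and easier to register precisely).
#' @param noise_sd Read noise sd in 8-bit pixel units.
#' @param n_frames Frames per video.
#' @param offset_range Offset search range (and truth range), frames.
#' @param corner_tol_px Corner error tolerance, px.
#' @param layout Card layout (default a small demo card).
#' @return A tibble with one row per trial: `trial`, `true_offset`,
#'   `found_offset`, `corner_error_px`, `ok`.
#' @export
alignment_recovery_trials <- function(n_trials = 40, seed = 1,
                                      dim_px = c(96, 128), noise_sd = 1,
                                      n_frames = 10, offset_range = 3,
                                      corner_tol_px = 0.5, layout = NULL) {
  layout <- layout %||% demo_card_layout(n_colors = 6)
  corners <- rbind(
    c(0, 0), c(dim_px[2] - 1, 0),
    c(dim_px[2] - 1, dim_px[1] - 1), c(0, dim_px[1] - 1)
  )
  purrr::map_dfr(seq_len(n_trials), function(i) {
    rng <- make_rng(seed * 1000 + i)
    tx <- rng$unif(1, -4, 4); ty <- rng$unif(1, -4, 4)
    a <- rng$unif(4, -0.012, 0.012)
    off <- rng$int(1, -offset_range, offset_range)
    mis <- affine_matrix(1 + a[1], a[2], tx, a[3], 1 + a[4], ty)
    sc <- scene_spec(layout, misalignment = mis, frame_offset = off,
                     dim_px = dim_px, noise_sd = noise_sd,
                     seed = seed * 1000 + i)
    vid <- render_video(sc, n_frames = n_frames, motion_px = 24)
    am <- try(
      temporal_align(vid$uv, vid$vis, offset_range = offset_range,
                     motion_model = "translation", final_model = "affine",
                     search_radius_px = 4),
      silent = TRUE
    )
    if (inherits(am, "try-error")) {
      return(tibble(trial = i, true_offset = off, found_offset = NA_integer_,
                    corner_error_px = NA_real_, ok = FALSE))
    }
    # recovered map should invert the misalignment: total o mis ~ identity
    err <- apply_homography(total_homography(am),
                            apply_homography(mis, corners)) - corners
    cerr <- max(sqrt(rowSums(err^2)))
    tibble(
      trial = i, true_offset = off, found_offset = am$temporal_offset_frames,
      corner_error_px = cerr,
      ok = am$temporal_offset_frames == off & cerr <= corner_tol_px
    )
  })
}

#' End-to-end quantum-catch recovery benchmark
#'
#' Runs the whole pipeline against a rendered dual-camera frame pair with
#' known ground truth: detect the card on the VIS frame, align the UV frame
#' (jittered manual points + ECC refinement), extract grayscale and colour
#' patches, linearize and normalize on the grayscales (exact decode +
#' regression, or the one-step power law), fit the transformation matrix on
#' an independent synthetic library, predict the animal catches of the
#' colour patches, and compare them with the exact catches of the patches'
#' true reflectances.
#'
#' @param seed Seed for the scene (noise, misalignment jitter) and library.
#' @param noise_sd Read noise sd in 8-bit pixel units (0 = ideal).
#' @param viewer `"bee"` or `"bird"`.
#' @param n_colors Colour patches on the card.
#' @param dim_px Frame size.
#' @param library_n Library size for fitting T.
#' @param method `"slog3"` (decode + normalization regression) or
#'   `"power_law"` (one-step fit).
#' @return List: `eval` (a [evaluate_catches()] tibble), `transform`, the
#'   per-channel normalization diagnostics, and the predicted/reference
#'   catch matrices.
#' @export
catch_recovery_benchmark <- function(seed = 1, noise_sd = 0, viewer = "bee",
                                     n_colors = 16, dim_px = c(144, 192),
                                     library_n = 2494,
                                     method = c("slog3", "power_law")) {
  method <- match.arg(method)
  rng <- make_rng(seed + 5000)
  layout <- demo_card_layout(n_colors = n_colors, seed = seed + 77)
  tx <- rng$unif(1, -4, 4); ty <- rng$unif(1, -4, 4)
  a <- rng$unif(4, -0.01, 0.01)
  mis <- affine_matrix(1 + a[1], a[2], tx, a[3], 1 + a[4], ty)
  cams <- synth_camera()
  scene <- scene_spec(layout, illuminant = NULL, cameras = cams,
                      misalignment = mis, noise_sd = noise_sd,
                      exposure = list(uv = 1.25, vis = 0.85),
                      dim_px = dim_px, seed = seed)
  fr <- render_frames(scene)

  # --- alignment: jittered "hand-picked" points, then ECC refinement
  pts_vis <- rbind(c(20, 20), c(dim_px[2] - 20, 24),
                   c(dim_px[2] - 24, dim_px[1] - 20), c(24, dim_px[1] - 24))
  pts_uv <- apply_homography(mis, pts_vis) +
    matrix(rng$unif(8, -1, 1), 4, 2)
  coarse <- fit_coarse(pts_uv, pts_vis)
  fine <- ecc_refine(fr$vis, fr$uv, init = coarse, motion_model = "affine",
                     search_radius_px = 3)
  M <- if (isTRUE(fine$ok)) fine$correction else coarse
  uv_aligned <- warp_image(fr$uv, M)

  # --- card detection and patch extraction
  H_card <- detect_card(fr$vis, layout)
  patches_vis <- extract_patches(fr$vis, layout, H_card)
  patches_uv <- extract_patches(uv_aligned, layout, H_card)

  fit_channels <- c("uv_r", "vis_b", "vis_g", "vis_r")
  pix <- dplyr::bind_rows(
    dplyr::filter(patches_uv, .data$channel == "uv_r"),
    dplyr::filter(patches_vis, .data$channel %in% c("vis_b", "vis_g", "vis_r"))
  )
  targets <- patch_target_catches(layout, cams$combined)
  samples <- dplyr::inner_join(pix, targets, by = c("patch_id", "channel"))
  gray <- dplyr::filter(samples, grepl("^gray_", .data$patch_id),
                        !.data$outside, .data$n_pixels > 0)

  # --- linearization + normalization on the grayscale standards
  model <- if (method == "power_law") {
    fit_power_law(tibble(channel = gray$channel, pixel = gray$mean,
                         target = gray$target))
  } else {
    fit_normalization(tibble(
      channel = gray$channel,
      pixel = slog3_to_linear(gray$mean),
      target = gray$target
    ))
  }
  lin_fun <- function(channel, pixel) {
    f <- model$fits[[channel]]
    if (method == "power_law") {
      f$a1 * f$a2^pixel + f$a3
    } else {
      f$slope * slog3_to_linear(pixel) + f$intercept
    }
  }

  # --- estimated camera catches of the colour patches
  colors <- dplyr::filter(samples, grepl("^color_", .data$patch_id),
                          !.data$outside, .data$n_pixels > 0)
  colors <- dplyr::mutate(
    colors,
    cc_est = vapply(seq_len(nrow(colors)), function(r) {
      lin_fun(colors$channel[r], colors$mean[r])
    }, numeric(1))
  )
  cc_wide <- tidyr::pivot_wider(
    dplyr::select(colors, "patch_id", "channel", "cc_est"),
    names_from = "channel", values_from = "cc_est"
  )
  cc_mat <- as.matrix(cc_wide[, fit_channels])
  rownames(cc_mat) <- cc_wide$patch_id

  # --- transformation matrix from an independent library
  animal <- example_receptors(viewer)
  lib <- synth_library(library_n, seed = seed + 999)
  des <- build_design(lib, cams$combined, animal, NULL)
  tr <- fit_catch_transform(des$CC, des$AC,
                            metadata = list(library = "synthetic",
                                            n_train = library_n))
  predicted <- pmax(predict(tr, cc_mat), 0)

  # --- reference: exact catches of the true patch reflectances
  reference <- t(vapply(rownames(cc_mat), function(id) {
    channel_catches(layout$reflectances[[id]], animal, NULL)
  }, numeric(length(channel_labels(animal)))))

  list(
    eval = evaluate_catches(predicted, reference),
    transform = tr,
    normalization = glance(model),
    predicted = predicted,
    reference = reference
  )
}
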