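test_that("coarse homography fitting is exact on constructed matches", {
  pts <- cbind(c(10, 80, 80, 10, 45), c(10, 12, 60, 58, 35))
  H_id <- fit_coarse(pts, pts)
  expect_lt(max(abs(H_id - diag(3))), 1e-6)

  shifted <- pts + matrix(c(5, -3), nrow(pts), 2, byrow = TRUE)
  H_t <- fit_coarse(pts, shifted)
  reproj <- apply_homography(H_t, pts)
  expect_lt(max(abs(reproj - shifted)), 1e-6)

  expect_error(fit_coarse(pts[1:3, ], pts[1:3, ]), "4 point")
  collinear <- cbind(1:5, 2 * (1:5))
  expect_error(fit_coarse(collinear, collinear), "Degenerate")
})

test_that("ECC refinement recovers shifts and reports failures", {
  img <- textured_image(seed = 4)

  same <- ecc_refine(img, img, motion_model = "translation",
                     search_radius_px = 2)
  expect_true(same$ok)
  expect_equal(same$ecc, 1, tolerance = 1e-6)
  expect_lt(max(abs(same$correction - diag(3))), 0.01)

  pair <- shifted_pair(3.7, -2.2, seed = 4)
  got <- ecc_refine(pair$fixed, pair$moving, motion_model = "translation",
                    search_radius_px = 6)
  expect_true(got$ok)
  expect_lt(abs(got$correction[1, 3] - 3.7), 0.25)
  expect_lt(abs(got$correction[2, 3] + 2.2), 0.25)

  flat <- ecc_refine(matrix(0.5, 40, 40), matrix(0.5, 40, 40))
  expect_false(flat$ok)
  expect_match(flat$reason, "textureless")
})

test_that("candidate selection maximizes mean ECC with first-index ties", {
  pair <- shifted_pair(3, 1, seed = 9)
  H_true <- translation_matrix(3, 1)
  pairs <- list(pair)

  one <- select_alignment(list(H_true), pairs)
  expect_s3_class(one, "alignment_model")
  expect_gt(one$mean_ecc, 0.99)

  wrong <- translation_matrix(-4, 2)
  best <- select_alignment(list(wrong, H_true), pairs)
  expect_equal(total_homography(best), H_true)
  # the winner's mean ECC dominates every other candidate's (definitional)
  ecc_wrong <- select_alignment(list(wrong), pairs)$mean_ecc
  expect_gte(best$mean_ecc, ecc_wrong)

  tie <- select_alignment(list(H_true, H_true + 0), pairs)
  expect_equal(total_homography(tie), H_true)

  expect_error(select_alignment(list(), pairs), "candidate")
  expect_error(select_alignment(list(H_true), list()), "evaluation pair")
})

test_that("temporal alignment finds the frame offset jointly with space", {
  lay <- demo_card_layout(n_colors = 6)
  sc <- scene_spec(lay, misalignment = translation_matrix(2.5, -1.5),
                   frame_offset = 4L, dim_px = c(72, 96), noise_sd = 0.5,
                   seed = 8)
  vid <- render_video(sc, n_frames = 12, motion_px = 24)
  am <- temporal_align(vid$uv, vid$vis, offset_range = 4,
                       motion_model = "translation",
                       search_radius_px = 4)
  expect_equal(am$temporal_offset_frames, 4L)

  # identical sequences: offset 0
  am0 <- temporal_align(vid$vis, vid$vis, offset_range = 2,
                        search_radius_px = 2)
  expect_equal(am0$temporal_offset_frames, 0L)
  expect_gt(am0$mean_ecc, 0.999)

  # static scene: insufficient motion
  sc_still <- scene_spec(lay, dim_px = c(72, 96), seed = 8)
  fr <- render_frames(sc_still)
  static <- replicate(8, fr$vis, simplify = FALSE)
  expect_error(
    temporal_align(static, static, offset_range = 2),
    "Insufficient motion"
  )
})

test_that("ghost composite exposes misalignment as colour fringing", {
  img <- textured_image(seed = 3)
  vis3 <- image_plane(array(rep(img, 3), c(dim(img), 3)), "encoded",
                      c("vis_r", "vis_g", "vis_b"))
  aligned <- ghost_composite(vis3, img)
  a <- as.array(aligned)
  expect_equal(a[, , 1], a[, , 2])   # gray when perfectly aligned
  expect_equal(a[, , 2], a[, , 3])
  expect_identical(image_domain(aligned), "display")

  # a 5 px shift leaves a green/magenta fringe at edges
  shifted <- warp_image(array(img, c(dim(img), 1)),
                        translation_matrix(5, 0))[, , 1]
  ghost <- ghost_composite(vis3, shifted)
  fringe <- abs(as.array(ghost)[, , 2] - as.array(ghost)[, , 1])
  expect_gt(max(fringe), 0.1)

  expect_error(ghost_composite(vis3, img[1:10, 1:10]), "height and width")
  expect_error(ghost_composite(numeric(0), img), "Empty")
})

test_that("alignment models round-trip through JSON", {
  m <- alignment_model(
    coarse_H = translation_matrix(2, 3),
    fine_correction = affine_matrix(1.01, 0.002, -0.5, -0.001, 0.99, 0.7),
    temporal_offset_frames = -2L, mean_ecc = 0.987
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_alignment_json(m, path)
  m2 <- read_alignment_json(path)
  expect_equal(m2$coarse_H, m$coarse_H)
  expect_equal(m2$fine_correction, m$fine_correction)
  expect_identical(m2$temporal_offset_frames, -2L)
  expect_equal(m2$mean_ecc, 0.987)
  expect_error(alignment_model(matrix(0, 3, 3)), "invertible")
})
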