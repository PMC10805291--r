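card_corners <- function(layout) {
  w <- max(layout$markers$x + layout$markers$size)
  h <- max(layout$markers$y + layout$markers$size)
  rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
}

test_that("layout and dictionary constructors validate their inputs", {
  dict <- demo_marker_dictionary()
  expect_length(dict$patterns, 4)
  # rotation-colliding pattern rejected
  sym <- matrix(c(1, 0, 0, 1), 2, 2)  # 180-degree symmetric
  expect_error(marker_dictionary("bad", list(a = sym)), "collides")

  lay <- demo_card_layout(n_colors = 4)
  expect_s3_class(lay, "card_layout")
  expect_error(
    card_layout(dict, lay$markers[1:3, ], lay$patches, lay$reflectances),
    "4 distinct markers"
  )
  expect_error(
    card_layout(dict, lay$markers, lay$patches,
                lay$reflectances[-1]),
    "Missing reflectance"
  )
})

test_that("detection recovers the card pose at identity and rotated poses", {
  lay <- demo_card_layout(n_colors = 6)
  sc <- scene_spec(lay, dim_px = c(144, 192), seed = 1)

  fr0 <- render_frames(sc)                       # frontal pose
  H0 <- detect_card(fr0$vis, lay)
  err0 <- apply_homography(H0, card_corners(lay)) -
    apply_homography(fr0$truth$H_card_to_vis, card_corners(lay))
  expect_lt(max(sqrt(rowSums(err0^2))), 0.5)

  fr1 <- render_frames(sc, rotation_deg = 10, translate_px = c(4, -3))
  H1 <- detect_card(fr1$vis, lay)
  err1 <- apply_homography(H1, card_corners(lay)) -
    apply_homography(fr1$truth$H_card_to_vis, card_corners(lay))
  expect_lt(max(sqrt(rowSums(err1^2))), 0.5)
})

test_that("a hidden marker produces an error naming the missing id", {
  lay <- demo_card_layout(n_colors = 6)
  fr <- render_frames(scene_spec(lay, dim_px = c(144, 192), seed = 1))
  img <- as.array(fr$vis)
  # paint over marker '3' with card white
  m <- lay$markers[lay$markers$id == "3", ]
  box <- apply_homography(
    fr$truth$H_card_to_vis,
    rbind(c(m$x - 1, m$y - 1), c(m$x + m$size + 1, m$y + m$size + 1))
  )
  rows <- intersect((floor(box[1, 2]) + 1):(ceiling(box[2, 2]) + 1),
                    seq_len(dim(img)[1]))
  cols <- intersect((floor(box[1, 1]) + 1):(ceiling(box[2, 1]) + 1),
                    seq_len(dim(img)[2]))
  img[rows, cols, ] <- max(img)
  expect_error(
    detect_card(image_plane(img, "encoded"), lay),
    "missing: 3"
  )
})

test_that("patch statistics are exact on synthetic patches", {
  # build a bare image by hand: one uniform patch in card coords == px coords
  dict <- demo_marker_dictionary()
  refl <- list(p = flat_reflectance(0.5))
  lay <- card_layout(
    dict,
    tibble::tibble(id = c("0", "1", "2", "3"),
                   x = c(0, 80, 80, 0), y = c(0, 0, 60, 60), size = 10),
    tibble::tibble(patch_id = "p", x = 30, y = 20, w = 20, h = 16),
    refl
  )
  img <- array(0.9, c(90, 100, 1))
  img[21:36, 31:50, 1] <- 0.4                     # the patch (0-based rect)
  ps <- extract_patches(image_plane(img, "encoded", "ch"), lay, diag(3))
  expect_equal(ps$mean, 0.4)
  expect_equal(ps$trimmed_mean, 0.4)
  expect_equal(ps$saturation_fraction, 0)
  expect_false(ps$outside)

  # 1-px contaminated border is excluded by the default shrink
  img2 <- img
  img2[21:36, 31, 1] <- 1        # saturated left column of the patch
  ps2 <- extract_patches(image_plane(img2, "encoded", "ch"), lay, diag(3),
                         shrink = 0.25)
  expect_equal(ps2$mean, 0.4)

  # fully saturated patch
  img3 <- img
  img3[21:36, 31:50, 1] <- 1
  ps3 <- extract_patches(image_plane(img3, "encoded", "ch"), lay, diag(3))
  expect_equal(ps3$saturation_fraction, 1)

  # patch projected outside the image is flagged, not fatal
  H_off <- translation_matrix(500, 0)
  ps4 <- extract_patches(image_plane(img, "encoded", "ch"), lay, H_off)
  expect_true(ps4$outside)
  expect_error(extract_patches(image_plane(img, "encoded"), lay, diag(3),
                               shrink = 0.6), "shrink")
})

test_that("render-detect-extract round-trips patch values at random poses", {
  lay <- demo_card_layout(n_colors = 6)
  cams <- synth_camera()
  rng <- make_rng(99)
  for (i in 1:2) {
    sc <- scene_spec(lay, dim_px = c(144, 192), seed = i)
    fr <- render_frames(sc, rotation_deg = rng$unif(1, -8, 8),
                        translate_px = rng$unif(2, -6, 6))
    H <- detect_card(fr$vis, lay)
    got <- extract_patches(fr$vis, lay, H)
    # expected encoded value of each gray patch on each VIS channel
    grays <- paste0("gray_", 1:8)
    for (ch_i in 1:3) {
      lab <- channel_labels(cams$vis)[ch_i]
      for (gid in grays[c(1, 4, 8)]) {
        cc <- sc$exposure$vis *
          channel_catches(lay$reflectances[[gid]], cams$vis)[[lab]]
        enc <- quantize_8bit(linear_to_slog3(cc))
        m <- got$mean[got$patch_id == gid & got$channel == lab]
        expect_lt(abs(m - enc), 1 / 255 + 1e-9)
      }
    }
  }
})

test_that("card layouts round-trip through JSON with their spectra", {
  dir <- withr::local_tempdir()
  lay <- demo_card_layout(n_colors = 3)
  path <- file.path(dir, "layout.json")
  write_card_layout_json(lay, path)
  lay2 <- read_card_layout_json(path)
  expect_equal(lay2$markers$id, lay$markers$id)
  expect_equal(lay2$markers$x, lay$markers$x)
  expect_equal(lay2$dictionary$patterns, lay$dictionary$patterns)
  expect_equal(as.character(lay2$patches$patch_id),
               as.character(lay$patches$patch_id))
  expect_equal(lay2$reflectances$color_2$value,
               lay$reflectances$color_2$value, tolerance = 1e-12)
})
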