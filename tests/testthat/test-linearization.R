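test_that("the decode curve reproduces its defining values", {
  k <- slog3_constants()
  # x = 0 falls on the linear branch: r is the intercept
  expect_equal(slog3_to_linear(0, k, apply_scale = FALSE), k$c6)
  # x = 1, no scale: frozen value from direct evaluation of the constants
  expect_equal(slog3_to_linear(1, k, apply_scale = FALSE), 38.4208098020,
               tolerance = 1e-9)
  # each branch is strictly increasing over the 8-bit code grid; the printed
  # constants leave a small jump where the branches meet, so monotonicity is
  # asserted per branch
  codes <- (0:255) / 255
  r <- slog3_to_linear(codes, k)
  on_log <- k$s * codes >= k$c4
  expect_true(all(diff(r[on_log]) > 0))
  expect_true(all(diff(r[!on_log]) > 0))
  # the input scale compresses the domain
  expect_equal(slog3_to_linear(0.5, k, apply_scale = TRUE),
               slog3_to_linear(0.5 * k$s, k, apply_scale = FALSE))
})

test_that("encode inverts decode exactly off the branch overlap", {
  k <- slog3_constants()
  x <- seq(0, 1, length.out = 513)
  r <- slog3_to_linear(x, k)
  back <- linear_to_slog3(r, k)
  r_break <- k$c1 * k$c2^k$c4 + k$c3
  lin_top <- k$c5 * k$c4 + k$c6
  clean <- r < r_break | r > lin_top   # outside the two-branch overlap
  expect_lt(max(abs(back[clean] - x[clean])), 1e-12)
})

test_that("8-bit round trip sits at the quantization floor", {
  rt <- slog3_roundtrip_error()
  expect_lte(rt$mean_abs_error, 1.5 * rt$floor)
})

test_that("ideal target catches scale with flat reflectance", {
  cams <- synth_camera()
  chans <- channel_spectra(cams$combined)
  for (s in chans) {
    expect_equal(ideal_target_catch(flat_reflectance(0.99), s), 0.99,
                 tolerance = 1e-9)
    expect_equal(ideal_target_catch(flat_reflectance(0.02), s), 0.02,
                 tolerance = 1e-9)
  }
  got <- ideal_target_catch(gaussian_reflectance(520, 120, 0.8),
                            chans$vis_g)
  # fine-grid oracle with the channel's own (gap-cut) shape
  wl <- grid_wavelengths(grid_policy())
  oracle <- sum(gaussian_reflectance(520, 120, 0.8)$value * chans$vis_g$value)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("power-law fit recovers exact generating parameters", {
  p <- seq(0.1, 0.8, length.out = 8)
  truth <- c(a1 = 0.005, a2 = 8000, a3 = -0.01)
  cc <- truth[1] * truth[2]^p + truth[3]
  fit <- fit_power_law(tibble::tibble(channel = "g", pixel = p, target = cc))
  est <- tidy(fit)
  expect_lt(abs(est$a1 - truth[1]) / truth[1], 1e-4)
  expect_lt(abs(est$a2 - truth[2]) / truth[2], 1e-4)
  expect_lt(abs(est$a3 - truth[3]) / abs(truth[3]), 1e-3)

  # near-linear data: the power law approximates a line over a bounded range
  lin <- tibble::tibble(channel = "g", pixel = p, target = 0.3 + 0.5 * p)
  fit2 <- fit_power_law(lin)
  f <- fit2$fits$g
  resid <- f$a1 * f$a2^p + f$a3 - lin$target
  expect_lt(max(abs(resid)) / diff(range(lin$target)), 1e-3)

  expect_error(
    fit_power_law(tibble::tibble(channel = "g", pixel = p[1:3],
                                 target = cc[1:3])),
    ">= 4"
  )
  expect_error(
    fit_power_law(tibble::tibble(channel = "g", pixel = rep(0.5, 5),
                                 target = cc[1:5])),
    "distinct"
  )
})

test_that("normalization regression recovers gain and offset", {
  p <- c(0.99, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05, 0.02)
  ident <- fit_normalization(
    tibble::tibble(channel = "c", pixel = p, target = p)
  )
  expect_equal(ident$fits$c$slope, 1, tolerance = 1e-9)
  expect_equal(ident$fits$c$intercept, 0, tolerance = 1e-9)

  scaled <- fit_normalization(
    tibble::tibble(channel = "c", pixel = 2 * p + 0.1, target = p)
  )
  expect_equal(scaled$fits$c$slope, 0.5, tolerance = 1e-9)
  expect_equal(scaled$fits$c$intercept, -0.05, tolerance = 1e-9)

  expect_error(
    fit_normalization(tibble::tibble(channel = "c", pixel = rep(1, 3),
                                     target = p[1:3])),
    "grayscale levels"
  )
})

test_that("grayscale regression on synthetic encoded data is near perfect", {
  # encode ideal gray levels with gain, quantize, decode, regress
  grays <- c(0.99, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05, 0.02)
  gain <- 0.85
  enc <- quantize_8bit(linear_to_slog3(gain * grays))
  m <- fit_normalization(tibble::tibble(
    channel = "c", pixel = slog3_to_linear(enc), target = grays
  ))
  expect_gt(glance(m)$r_squared, 0.999)
  expect_equal(m$fits$c$slope, 1 / gain, tolerance = 0.01)
})

test_that("decode+regression and one-step power law agree end to end", {
  grays <- c(0.99, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05, 0.02)
  gain <- 1.2
  enc <- as.numeric(quantize_8bit(linear_to_slog3(gain * grays)))
  m1 <- fit_normalization(tibble::tibble(
    channel = "c", pixel = slog3_to_linear(enc), target = grays
  ))
  m2 <- fit_power_law(tibble::tibble(channel = "c", pixel = enc,
                                     target = grays))
  probe <- seq(min(enc), max(enc), length.out = 50)
  v1 <- m1$fits$c$slope * slog3_to_linear(probe) + m1$fits$c$intercept
  v2 <- m2$fits$c$a1 * m2$fits$c$a2^probe + m2$fits$c$a3
  expect_lt(max(abs(v1 - v2)), 0.01)   # within 1% of full scale
})

test_that("encode-quantize-decode round trip meets the quantization bound", {
  # a known linear image through the full 8-bit chain
  img <- image_plane(array(seq(0.01, 0.99, length.out = 60), c(5, 4, 3)),
                     "camera_catch")
  enc <- quantize_8bit(linear_to_slog3(img))
  dec <- slog3_to_linear(enc)
  k <- slog3_constants()
  codes <- (0:255) / 255
  floor_err <- max(abs(diff(slog3_to_linear(codes, k)))) / 2
  expect_lte(mean(abs(as.numeric(dec) - as.numeric(img))), floor_err)
  expect_identical(image_domain(dec), "camera_catch")
})

test_that("apply_linearization maps whole images per channel", {
  img <- image_plane(array(c(0.2, 0.4), c(1, 1, 2)), "encoded",
                     c("a", "b"))
  m <- fit_normalization(tibble::tibble(
    channel = c(rep("a", 4), rep("b", 4)),
    pixel = rep(c(0.1, 0.2, 0.3, 0.4), 2),
    target = c(0.2, 0.4, 0.6, 0.8, 0.1, 0.2, 0.3, 0.4)
  ))
  out <- apply_linearization(img, m)
  expect_equal(as.numeric(out), c(0.4, 0.4))
  expect_identical(image_domain(out), "camera_catch")
  expect_error(apply_linearization(img, m, channels = "a"), "channel count")
})

test_that("calibration reports round-trip through JSON", {
  p <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  m <- fit_normalization(tibble::tibble(channel = "c", pixel = p,
                                        target = 0.8 * p + 0.05))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(m, path)
  m2 <- read_calibration_json(path)
  expect_s3_class(m2, "normalization_model")
  expect_equal(m2$fits$c$slope, m$fits$c$slope)

  pw <- fit_power_law(tibble::tibble(
    channel = "c", pixel = p, target = 0.005 * 8000^p - 0.01
  ))
  write_calibration_json(pw, path)
  pw2 <- read_calibration_json(path)
  expect_s3_class(pw2, "power_law_model")
  expect_equal(pw2$fits$c$a2, pw$fits$c$a2)
})
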