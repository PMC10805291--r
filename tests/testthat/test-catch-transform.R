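test_that("design matrices match the catch integrals element-wise", {
  g <- grid_policy()
  cams <- synth_camera()
  bee <- example_receptors("bee")
  lib <- c(list(flat_reflectance(1)),
           lapply(seq(350, 650, by = 40), function(p) {
             gaussian_reflectance(p, 90, 0.8)
           }))
  des <- build_design(lib, cams$combined, bee, NULL, g)
  expect_equal(dim(des$CC), c(9, 4))
  expect_equal(dim(des$AC), c(9, 3))
  # flat white: every catch is one
  expect_equal(unname(des$CC[1, ]), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(des$AC[1, ]), rep(1, 3), tolerance = 1e-9)
  # element-wise agreement with the scalar integral
  for (i in c(2, 5)) {
    expect_equal(unname(des$CC[i, ]),
                 unname(channel_catches(lib[[i]], cams$combined, NULL, g)),
                 tolerance = 1e-9)
    expect_equal(unname(des$AC[i, ]),
                 unname(channel_catches(lib[[i]], bee, NULL, g)),
                 tolerance = 1e-9)
  }
  expect_error(build_design(list(), cams$combined, bee), "empty")
  bad <- list(ideal_illuminant())
  expect_error(build_design(bad, cams$combined, bee), "kind")
})

test_that("T is exact whenever AC is an exact linear map of CC", {
  cams <- synth_camera()
  lib <- synth_library(60, seed = 5)
  des <- build_design(lib, cams$combined, cams$combined, NULL)
  # animal identical to camera: T is the identity
  tr <- fit_catch_transform(des$CC, des$AC)
  expect_lt(max(abs(tr$T - diag(4))), 1e-8)

  # known mixing matrix K recovered exactly
  K <- matrix(c(0.6, 0.2, 0.1, 0.1,
                0, 0.9, 0.1, 0,
                0.25, 0.25, 0.25, 0.25,
                -0.1, 0.4, 0.5, 0.2), 4, 4, byrow = TRUE)
  AC <- des$CC %*% t(K)
  tr2 <- fit_catch_transform(des$CC, AC)
  expect_lt(max(abs(tr2$T - K)), 1e-8)

  expect_error(fit_catch_transform(des$CC[1:3, ], AC[1:3, ]), "as many")
  dup <- cbind(des$CC, des$CC[, 1])
  expect_error(fit_catch_transform(dup, AC), "rank deficient")
})

test_that("applying T transforms pixels and clips negatives", {
  tr <- fit_catch_transform(diag(4), diag(4))
  img <- image_plane(array(runif(2 * 3 * 4), c(2, 3, 4)), "camera_catch")
  out <- apply_catch_transform(img, tr)
  expect_equal(as.numeric(out), as.numeric(img))

  # hand-computed 3 x 4 product on a single pixel
  Tm <- matrix(c(1, 0, 0, 1,
                 0, 2, 0, 0,
                 0, 0, -1, 0), 3, 4, byrow = TRUE)
  tr2 <- structure(
    list(T = Tm, receptors = c("r1", "r2", "r3"), channels = paste0("c", 1:4),
         n_train = 4, train_r_squared = rep(1, 3), metadata = list()),
    class = "catch_transform"
  )
  px <- image_plane(array(c(0.1, 0.2, 0.3, 0.4), c(1, 1, 4)), "camera_catch")
  got <- apply_catch_transform(px, tr2)
  expect_equal(as.numeric(got), c(0.1 + 0.4, 0.4, 0))  # third clipped to 0
  expect_equal(attr(got, "n_clipped"), 1)
  expect_identical(image_domain(got), "animal_catch")
  expect_error(apply_catch_transform(px[, , 1:3, drop = FALSE] |>
                                       image_plane("camera_catch"), tr2),
               "channels")
})

test_that("evaluation metrics match their definitions", {
  set.seed(2)
  ref <- matrix(runif(40, 0.1, 1), 20, 2, dimnames = list(NULL, c("a", "b")))
  ev0 <- evaluate_catches(ref, ref)
  expect_equal(ev0$r_squared, c(1, 1))
  expect_equal(ev0$mape, c(0, 0))
  expect_equal(ev0$rmspe, c(0, 0))
  expect_equal(ev0$band_lower, c(0, 0))
  expect_equal(ev0$band_upper, c(0, 0))

  # hand error set: band by brute-force sorted percentiles
  errs <- c(-2, -1, 0, 1, 2, 3, -3, 0.5)
  pred <- cbind(a = 0.5 + errs)
  refm <- cbind(a = rep(0.5, 8))
  ev <- evaluate_catches(pred, refm)
  expect_equal(ev$mape, mean(abs(errs)))
  expect_equal(ev$rmspe, sqrt(mean(errs^2)))
  expect_equal(c(ev$band_lower, ev$band_upper),
               unname(quantile(errs, c(0.125, 0.875))))
  expect_gte(ev$rmspe, ev$mape)  # power-mean inequality
  expect_true(is.na(ev$r_squared))  # constant reference

  # RMSPE >= MAPE on random samples
  for (i in 1:5) {
    p <- matrix(runif(24), 12, 2); r <- matrix(runif(24), 12, 2)
    e <- evaluate_catches(p, r)
    expect_true(all(e$rmspe >= e$mape - 1e-12))
  }
  expect_error(evaluate_catches(pred[1:3, , drop = FALSE],
                                refm[1:3, , drop = FALSE]), "at least 4")
})

test_that("RNL distance matches independent closed forms and is a metric", {
  # frozen hand example, computed from a separate transcription of the
  # trichromat closed form
  qa <- c(0.8, 0.5, 0.3); qb <- c(0.6, 0.55, 0.45)
  p3 <- rnl_params(c(u = 0.1, s = 0.07, m = 0.05))
  expect_equal(rnl_distance(qa, qb, p3), 6.534535435341, tolerance = 1e-9)

  expect_equal(rnl_distance(qa, qa, p3), 0)
  # scaling either vector leaves the distance unchanged
  expect_equal(rnl_distance(qa * 3, qb, p3), rnl_distance(qa, qb, p3))
  expect_equal(rnl_distance(qa, qb * 0.2, p3), rnl_distance(qa, qb, p3))

  # tetrachromat closed form vs the general quadratic form, written out
  # independently here
  e4 <- c(0.1, 0.07, 0.06, 0.05)
  p4 <- rnl_params(setNames(e4, paste0("r", 1:4)))
  q1 <- c(0.9, 0.4, 0.55, 0.2); q2 <- c(0.5, 0.6, 0.35, 0.4)
  df <- log(q1 / q2)
  num <- (e4[1] * e4[2])^2 * (df[4] - df[3])^2 +
    (e4[1] * e4[3])^2 * (df[4] - df[2])^2 +
    (e4[1] * e4[4])^2 * (df[3] - df[2])^2 +
    (e4[2] * e4[3])^2 * (df[4] - df[1])^2 +
    (e4[2] * e4[4])^2 * (df[3] - df[1])^2 +
    (e4[3] * e4[4])^2 * (df[2] - df[1])^2
  den <- (e4[1] * e4[2] * e4[3])^2 + (e4[1] * e4[2] * e4[4])^2 +
    (e4[1] * e4[3] * e4[4])^2 + (e4[2] * e4[3] * e4[4])^2
  expect_equal(rnl_distance(q1, q2, p4), sqrt(num / den), tolerance = 1e-12)

  # metric properties on random triples
  rng <- make_rng(31)
  for (i in 1:10) {
    x <- rng$unif(3, 0.05, 1); y <- rng$unif(3, 0.05, 1)
    z <- rng$unif(3, 0.05, 1)
    expect_equal(rnl_distance(x, y, p3), rnl_distance(y, x, p3))
    expect_lte(rnl_distance(x, z, p3),
               rnl_distance(x, y, p3) + rnl_distance(y, z, p3) + 1e-12)
  }
  expect_error(rnl_distance(c(0, 1, 1), c(1, 1, 1), p3), "positive")
  expect_error(rnl_params(c(0.1, -1)), "positive")
})

test_that("the train/test split is seeded and mirrors the 90/10 sizes", {
  cams <- synth_camera()
  lib <- synth_library(100, seed = 2)
  s1 <- accuracy_sweep(c(450), "A1", lib, cams$combined, seed = 5)
  s2 <- accuracy_sweep(c(450), "A1", lib, cams$combined, seed = 5)
  expect_equal(s1$r_squared, s2$r_squared)
  # default split on a 2,494-member library is 2,244 / 250
  expect_equal(floor(0.9 * 2494), 2244)
  expect_equal(2494 - floor(0.9 * 2494), 250)
})

test_that("accuracy sweep has the expected shape over receptor peaks", {
  cams <- synth_camera()
  lib <- synth_library(700, seed = 11)
  peaks <- c(305, 320, 335, 370, 410, 440, 480, 560, 640, 700)
  sw <- accuracy_sweep(peaks, "A1", lib, cams$combined, seed = 3)
  r2 <- setNames(sw$r_squared, sw$peak_nm)

  # a receptor matching a camera channel is predicted almost perfectly
  expect_gt(r2[["560"]], 0.99)
  # far-UV peaks degrade below the long-wavelength plateau
  expect_lt(max(r2[c("305", "320")]), min(r2[as.character(peaks[peaks >= 440])]))
  # local dip at the inter-camera gap
  expect_lt(r2[["410"]], r2[["370"]])
  expect_lt(r2[["410"]], r2[["480"]])

  expect_equal(nrow(accuracy_sweep(numeric(0), "A1", lib, cams$combined)), 0)
})

test_that("narrowband stress shrinks toward the broadband regime", {
  cams <- synth_camera()
  lib <- synth_library(400, seed = 21)
  ns <- narrowband_stress(c(10, 220), seq(340, 660, by = 60),
                          c(360, 550), cams$combined, lib)
  expect_true(all(is.finite(ns$abs_error)))   # total on the full grid
  m <- tapply(ns$abs_error, ns$fwhm_nm, max)
  expect_lt(m[["220"]], m[["10"]])

  # a training member itself is predicted with near-zero error
  des <- build_design(lib, cams$combined, example_receptors("bee"), NULL)
  tr <- fit_catch_transform(des$CC, des$AC)
  pred <- predict(tr, des$CC[5, , drop = FALSE])
  expect_lt(max(abs(pred - des$AC[5, ])), 0.05)
})

test_that("tidy and glance expose the transform in tabular form", {
  cams <- synth_camera()
  lib <- synth_library(40, seed = 1)
  des <- build_design(lib, cams$combined, example_receptors("bee"), NULL)
  tr <- fit_catch_transform(des$CC, des$AC)
  td <- tidy(tr)
  expect_setequal(names(td), c("receptor", "channel", "estimate"))
  expect_equal(nrow(td), 12)
  gl <- glance(tr)
  expect_equal(gl$n_train, rep(40, 3))
  expect_true(all(gl$train_r_squared > 0.9))
})

test_that("transformation matrices round-trip through JSON", {
  cams <- synth_camera()
  lib <- synth_library(30, seed = 9)
  des <- build_design(lib, cams$combined, example_receptors("bee"), NULL)
  tr <- fit_catch_transform(des$CC, des$AC, metadata = list(library = "demo"))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tr, path)
  tr2 <- read_transform_json(path)
  expect_equal(tr2$T, tr$T)
  expect_equal(tr2$receptors, tr$receptors)
  expect_equal(tr2$metadata$library, "demo")
  expect_equal(predict(tr2, des$CC[1:5, ]), predict(tr, des$CC[1:5, ]))
})
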