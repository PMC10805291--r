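test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(300:310, rep(0.5, 11), "reflectance"), "qc_spectrum")
  expect_error(spectrum(c(300, 300), c(1, 1), "reflectance"), "increasing")
  expect_error(spectrum(300:301, c(1, NA), "illuminant"), "NA")
  expect_error(spectrum(300:301, c(-0.1, 0), "sensitivity"), "nonnegative")
  expect_error(spectrum(300:302, c(1, 1), "reflectance"), "length")
  # super-white reflectance warns but is kept
  expect_warning(s <- spectrum(300:301, c(1.2, 1.2), "reflectance"), "1.1")
  expect_equal(s$value, c(1.2, 1.2))
})

test_that("resample interpolates linearly and zeroes outside support", {
  g <- grid_policy()
  const <- resample(spectrum(c(300, 700), c(0.5, 0.5), "reflectance"), g)
  expect_equal(const$value, rep(0.5, 401))

  seg <- resample(spectrum(c(400, 500), c(0, 1), "reflectance"), g)
  expect_equal(seg$value[seg$wavelength == 450], 0.5)
  expect_equal(seg$value[seg$wavelength == 350], 0)  # outside support
  expect_equal(seg$value[seg$wavelength == 650], 0)
  expect_identical(spectrum_kind(seg), "reflectance")

  expect_error(
    resample(spectrum(c(800, 900), c(1, 1), "illuminant"), g),
    "800-900.*300-700"
  )
})

test_that("resampling a 5 nm Gaussian to 1 nm preserves its integral", {
  wl5 <- seq(300, 700, by = 5)
  f <- gauss_fn(530, 60)
  coarse <- spectrum(wl5, f(wl5), "reflectance")
  fine <- resample(coarse, grid_policy())
  # oracle: fine-step numerical integral of the true curve
  truth <- sum(f(seq(300, 700, by = 0.01))) * 0.01
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_lt(abs(trap(fine$wavelength, fine$value) - truth) / truth, 1e-3)
})

test_that("resample onto the same grid is idempotent", {
  g <- grid_policy()
  s1 <- resample(gaussian_reflectance(500, 80), g)
  s2 <- resample(s1, g)
  expect_equal(s2$value, s1$value)
})

test_that("relativize makes every channel sum to one and is idempotent", {
  g <- grid_policy()
  rng <- make_rng(7)
  for (i in 1:5) {
    cs <- channel_set("cam", list(
      a = gaussian_sensitivity(rng$unif(1, 340, 660), rng$unif(1, 30, 120)),
      b = gaussian_sensitivity(rng$unif(1, 340, 660), rng$unif(1, 30, 120))
    ))
    rel <- relativize(cs, g)
    sums <- vapply(channel_spectra(rel), function(s) sum(s$value), numeric(1))
    expect_equal(unname(sums), c(1, 1), tolerance = 1e-9)
    rel2 <- relativize(rel, g)
    expect_equal(channel_spectra(rel2)$a$value, channel_spectra(rel)$a$value)
  }
  expect_true(is_relativized(rel))

  two_pt <- spectrum(c(400, 500), c(0.2, 0.6), "sensitivity")
  r <- relativize(channel_set("x", list(p = two_pt)),
                  grid_policy(400, 500, 100))
  expect_equal(channel_spectra(r)$p$value, c(0.25, 0.75))

  zero <- spectrum(c(400, 500), c(0, 0), "sensitivity")
  expect_error(relativize(channel_set("x", list(z = zero))), "all zero")
})

test_that("quantum catch is normalized, linear, and matches integration", {
  g <- grid_policy()
  s <- channel_spectra(relativize(
    channel_set("c", list(x = gaussian_sensitivity(540, 80))), g
  ))$x

  expect_equal(quantum_catch(flat_reflectance(1), s), 1)
  expect_equal(quantum_catch(flat_reflectance(0), s), 0)

  # Gaussian x Gaussian against a fine-grid oracle
  got <- quantum_catch(gaussian_reflectance(550, 60), s)
  truth <- oracle_catch(gauss_fn(550, 60), gauss_fn(540, 80))
  expect_lt(abs(got - truth) / truth, 1e-4)

  # frozen value from the same oracle computed at 0.01 nm
  expect_equal(got, 0.5835936920, tolerance = 1e-4)

  # linearity in reflectance
  r1 <- gaussian_reflectance(480, 70)
  r2 <- gaussian_reflectance(600, 90, amplitude = 0.6)
  wl <- grid_wavelengths(g)
  mix <- spectrum(wl, 0.3 * r1$value + 0.6 * r2$value, "reflectance")
  expect_equal(
    quantum_catch(mix, s),
    0.3 * quantum_catch(r1, s) + 0.6 * quantum_catch(r2, s),
    tolerance = 1e-9
  )

  # kind mismatch rejected
  expect_error(quantum_catch(ideal_illuminant(), s), "kind")
  expect_error(quantum_catch(flat_reflectance(), flat_reflectance()), "kind")
})

test_that("flat-white catch is one for random relativized channels", {
  g <- grid_policy()
  rng <- make_rng(11)
  for (i in 1:8) {
    wl <- grid_wavelengths(g)
    shape <- rng$unif(length(wl), 0, 1) +
      gauss_fn(rng$unif(1, 320, 680), rng$unif(1, 40, 150))(wl)
    cs <- relativize(channel_set("r", list(
      ch = spectrum(wl, shape, "sensitivity")
    )), g)
    expect_equal(
      unname(channel_catches(flat_reflectance(1), cs)), 1, tolerance = 1e-9
    )
  }
})

test_that("receptor templates peak at one, are unimodal, and A2 is broader", {
  g <- grid_policy()
  for (pk in c(360, 450, 560)) {
    for (chrom in c("A1", "A2")) {
      t <- receptor_template(pk, chrom, g)
      expect_equal(max(t$value), 1)
      at <- function(w) t$value[t$wavelength == w]
      # the curve's maximum sits near the nominal alpha peak; the A2 fit
      # drifts by ~10 nm when extrapolated into the UV
      expect_lt(abs(t$wavelength[which.max(t$value)] - pk), 12)
      expect_lt(at(min(pk + 100, 700)), at(pk))
      if (pk - 100 >= 300 && chrom == "A1") expect_lt(at(pk - 100), at(pk))
    }
    half_width <- function(t) {
      v <- t$value / max(t$value)
      diff(range(t$wavelength[v >= 0.5]))
    }
    expect_gte(half_width(receptor_template(pk, "A2", g)),
               half_width(receptor_template(pk, "A1", g)))
  }
  expect_error(receptor_template(250, "A1"), "outside")
  expect_error(receptor_template(500, "A3"))
})

test_that("spectra round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- gaussian_reflectance(500, 80, 0.7)
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path, "reflectance")
  expect_equal(s2$value, s$value)
  expect_equal(s2$wavelength, s$wavelength)

  cs <- relativize(channel_set("cam", list(
    a = gaussian_sensitivity(400, 60), b = gaussian_sensitivity(550, 60)
  )))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_channels_csv(cs, path2)
  cs2 <- read_channels_csv(path2, "cam")
  expect_equal(channel_labels(cs2), c("a", "b"))
  expect_equal(channel_spectra(cs2)$b$value, channel_spectra(cs)$b$value)
})
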