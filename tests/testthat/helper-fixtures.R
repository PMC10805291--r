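# Shared fixtures built in code.

flat_reflectance <- function(level = 1, grid = grid_policy()) {
  wl <- grid_wavelengths(grid)
  spectrum(wl, rep(level, length(wl)), "reflectance")
}

ideal_illuminant <- function(grid = grid_policy()) {
  wl <- grid_wavelengths(grid)
  spectrum(wl, rep(1, length(wl)), "illuminant")
}

# smooth random-blob image for registration tests
textured_image <- function(h = 80, w = 100, n_blobs = 12, seed = 1) {
  rng <- make_rng(seed)
  xs <- matrix(rep(0:(w - 1), each = h), h)
  ys <- matrix(rep(0:(h - 1), times = w), h)
  img <- matrix(0, h, w)
  for (k in seq_len(n_blobs)) {
    cx <- rng$unif(1, 5, w - 5); cy <- rng$unif(1, 5, h - 5)
    s <- rng$unif(1, 3, 9); a <- rng$unif(1, 0.2, 1)
    img <- img + a * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  }
  img / max(img)
}

# independent fine-grid rectangle-rule catch integral (0.01 nm)
oracle_catch <- function(refl_fn, sens_fn, ill_fn = function(x) 1,
                         lo = 300, hi = 700, step = 0.01) {
  x <- seq(lo, hi, by = step)
  s <- sens_fn(x)
  s <- s / sum(s * step)           # relativized density
  sum(refl_fn(x) * s * ill_fn(x) * step)
}

gauss_fn <- function(peak, fwhm, amp = 1) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  function(x) amp * exp(-(x - peak)^2 / (2 * sd^2))
}

# fixed/moving pair sampled from one larger texture, so the moving image has
# no synthetic zero border: moving(y) = fixed(y + (dx, dy))
shifted_pair <- function(dx, dy, h = 80, w = 100, seed = 1) {
  big <- textured_image(h + 24, w + 24, n_blobs = 16, seed = seed)
  fixed <- big[13:(12 + h), 13:(12 + w)]
  moved <- warp_image(array(big, c(dim(big), 1)),
                      translation_matrix(-(12 + dx), -(12 + dy)))[, , 1]
  list(fixed = fixed, moving = moved[seq_len(h), seq_len(w)])
}
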