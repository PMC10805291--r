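# Camera-catch to animal-quantum-catch transformation.
#
# Natural reflectance spectra are smooth enough that a linear map from a few
# broadband camera catches to an animal's photoreceptor catches holds to high
# accuracy. The map T (rows = receptors, columns = camera channels) is fitted
# without intercept over a reflectance library and evaluated on a held-out
# split.

#' Design matrices for the transformation fit
#'
#' Computes camera catches (under ideal illumination, the domain in which the
#' normalized recordings live) and animal catches (under the chosen target
#' illuminant) for every spectrum in a reflectance library.
#'
#' @param library List of `qc_spectrum` reflectances.
#' @param camera Relativized [channel_set()] of the camera channels used for
#'   the fit. To avoid overfitting from the UV camera's highly overlapping
#'   bands, the conventional choice is its red channel plus the three VIS
#'   channels; see [synth_camera()].
#' @param animal Relativized `channel_set` of the animal's receptors.
#' @param illuminant Target illuminant for the animal catches (`NULL` =
#'   ideal isoluminance).
#' @param grid A [grid_policy()].
#' @return List with matrices `CC` (n x i) and `AC` (n x j), labelled.
#' @export
build_design <- function(library, camera, animal, illuminant = NULL,
                         grid = grid_policy()) {
  if (!length(library)) abort("Reflectance library is empty.")
  stopifnot(inherits(camera, "channel_set"), inherits(animal, "channel_set"))
  if (!camera$relativized || !animal$relativized) {
    abort("Both channel sets must be relativized.")
  }
  wl <- grid_wavelengths(grid)
  R <- t(vapply(library, function(s) {
    assert_kind(s, "reflectance", arg = "library member")
    resample(s, grid)$value
  }, numeric(length(wl))))
  Sc <- vapply(camera$channels, function(s) resample(s, grid)$value,
               numeric(length(wl)))
  Sa <- vapply(animal$channels, function(s) resample(s, grid)$value,
               numeric(length(wl)))
  I_target <- if (is.null(illuminant)) {
    rep(1, length(wl))
  } else {
    assert_kind(illuminant, "illuminant")
    resample(illuminant, grid)$value
  }
  CC <- R %*% Sc                      # camera catches, ideal illumination
  AC <- R %*% (Sa * I_target)        # animal catches, target illumination
  colnames(CC) <- channel_labels(camera)
  colnames(AC) <- channel_labels(animal)
  list(CC = CC, AC = AC)
}

#' Fit the camera-to-receptor transformation matrix
#'
#' Per-receptor ordinary least squares through the origin:
#' `AC_j ~ t_j1 CC_1 + ... + t_ji CC_i`, no intercept, no regularization.
#'
#' @param CC n x i matrix of camera catches (n >= i).
#' @param AC n x j matrix of animal catches, same rows.
#' @param metadata Optional list stored with the fit (library id, split
#'   sizes, illuminant id, ...).
#' @return A `catch_transform`: the j x i matrix `T`, channel labels, and
#'   per-receptor training diagnostics. Supports [tidy()] and [glance()].
#' @export
fit_catch_transform <- function(CC, AC, metadata = list()) {
  CC <- as.matrix(CC); AC <- as.matrix(AC)
  if (nrow(CC) != nrow(AC)) abort("CC and AC must have the same rows.")
  if (nrow(CC) < ncol(CC)) {
    abort(sprintf("Need at least as many spectra (%d) as camera channels (%d).",
                  nrow(CC), ncol(CC)))
  }
  qrCC <- qr(CC)
  if (qrCC$rank < ncol(CC)) {
    abort(sprintf(
      "Camera-catch matrix is rank deficient (rank %d < %d columns; condition number %.3g).",
      qrCC$rank, ncol(CC), kappa(CC)
    ))
  }
  Tm <- t(qr.coef(qrCC, AC))          # j x i
  rownames(Tm) <- colnames(AC) %||% paste0("r", seq_len(ncol(AC)))
  colnames(Tm) <- colnames(CC) %||% paste0("c", seq_len(ncol(CC)))
  pred <- CC %*% t(Tm)
  train_r2 <- vapply(seq_len(ncol(AC)), function(j) {
    if (sd(AC[, j]) < 1e-12 || sd(pred[, j]) < 1e-12) return(NA_real_)
    cor(AC[, j], pred[, j])^2
  }, numeric(1))
  structure(
    list(T = Tm, receptors = rownames(Tm), channels = colnames(Tm),
         n_train = nrow(CC), train_r_squared = setNames(train_r2, rownames(Tm)),
         metadata = metadata),
    class = "catch_transform"
  )
}

#' @export
print.catch_transform <- function(x, ...) {
  cat(sprintf("<catch_transform> %d receptor(s) x %d camera channel(s), n = %d\n",
              nrow(x$T), ncol(x$T), x$n_train))
  print(round(x$T, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.catch_transform <- function(x, ...) {
  as_tibble(as.data.frame.table(x$T, responseName = "estimate")) |>
    setNames(c("receptor", "channel", "estimate")) |>
    dplyr::mutate(dplyr::across(c("receptor", "channel"), as.character))
}

#' @exportS3Method generics::glance
glance.catch_transform <- function(x, ...) {
  tibble(receptor = x$receptors,
         train_r_squared = unname(x$train_r_squared),
         n_train = x$n_train)
}

#' Predict animal catches from camera catches
#'
#' @param object A `catch_transform`.
#' @param CC n x i matrix of camera catches.
#' @param ... Unused.
#' @return n x j matrix of predicted animal catches (not clipped).
#' @export
predict.catch_transform <- function(object, CC, ...) {
  CC <- as.matrix(CC)
  if (ncol(CC) != ncol(object$T)) {
    abort(sprintf("CC has %d channels but T expects %d.",
                  ncol(CC), ncol(object$T)))
  }
  out <- CC %*% t(object$T)
  colnames(out) <- object$receptors
  out
}

#' Apply the transformation to a camera-catch image
#'
#' Per-pixel matrix-vector product mapping a camera-catch image into the
#' animal-catch domain. Negative predictions are clipped to 0 and counted.
#'
#' @param image `image_plane` in the `"camera_catch"` domain, channel count
#'   matching `ncol(T)`.
#' @param transform A `catch_transform`.
#' @return `image_plane` in the `"animal_catch"` domain with attribute
#'   `"n_clipped"` (number of clipped values).
#' @export
apply_catch_transform <- function(image, transform) {
  stopifnot(inherits(image, "image_plane"), inherits(transform, "catch_transform"))
  a <- as_bare_array(image)
  d <- dim(a)
  if (d[3] != ncol(transform$T)) {
    abort(sprintf("Image has %d channels but T expects %d.",
                  d[3], ncol(transform$T)))
  }
  flat <- matrix(a, d[1] * d[2], d[3])
  ac <- flat %*% t(transform$T)
  n_clip <- sum(ac < 0)
  ac[ac < 0] <- 0
  out <- image_plane(array(ac, c(d[1], d[2], ncol(ac))), "animal_catch",
                     transform$receptors)
  attr(out, "valid") <- attr(image, "valid")
  attr(out, "n_clipped") <- n_clip
  out
}

#' Prediction-accuracy report
#'
#' Per-receptor agreement between predicted and reference animal catches:
#' squared Pearson correlation (the primary R-squared; it measures linear
#' association only), the coefficient of determination about the 1:1 line,
#' mean absolute prediction error, root mean squared prediction error, and
#' the inner-75% band of signed errors (12.5th to 87.5th percentile, linear
#' interpolation).
#'
#' @param predicted,reference n x j matrices (n >= 4), matching columns.
#' @return A tibble of class `catch_eval` with one row per receptor.
#' @export
evaluate_catches <- function(predicted, reference) {
  predicted <- as.matrix(predicted); reference <- as.matrix(reference)
  if (!all(dim(predicted) == dim(reference))) abort("Shapes must match.")
  if (nrow(predicted) < 4) abort("Need at least 4 samples to evaluate.")
  labs <- colnames(reference) %||% paste0("r", seq_len(ncol(reference)))
  out <- purrr::map_dfr(seq_len(ncol(reference)), function(j) {
    err <- predicted[, j] - reference[, j]
    zero_var <- sd(reference[, j]) < 1e-12 || sd(predicted[, j]) < 1e-12
    band <- quantile(err, c(0.125, 0.875), names = FALSE, type = 7)
    tibble(
      receptor = labs[j],
      r_squared = if (zero_var) NA_real_ else cor(predicted[, j], reference[, j])^2,
      r_squared_identity = if (sd(reference[, j]) < 1e-12) NA_real_ else {
        1 - sum(err^2) / sum((reference[, j] - mean(reference[, j]))^2)
      },
      mape = mean(abs(err)),
      rmspe = sqrt(mean(err^2)),
      band_lower = band[1],
      band_upper = band[2],
      n = nrow(reference)
    )
  })
  class(out) <- c("catch_eval", class(out))
  out
}

#' Receptor noise parameters
#'
#' Weber-fraction-like noise values of the receptor-noise-limited model, one
#' per receptor. These are viewer-specific configuration, not constants of
#' the package.
#'
#' @param noise Named positive numeric vector, one value per receptor.
#' @return An object of class `rnl_params`.
#' @export
rnl_params <- function(noise) {
  if (any(noise <= 0)) abort("Receptor noise values must be positive.")
  if (is.null(names(noise))) names(noise) <- paste0("r", seq_along(noise))
  structure(list(noise = noise, labels = names(noise)), class = "rnl_params")
}

#' Receptor-noise-limited chromatic distance
#'
#' Distance in just-noticeable-difference (JND) units between two catch
#' vectors under the receptor-noise-limited model: log-transformed catches,
#' opponent contrasts weighted by receptor noise. Dedicated closed forms are
#' used for di-, tri- and tetrachromats; any receptor count is handled by the
#' equivalent quadratic form (the noise-weighted metric on the hyperplane
#' orthogonal to the achromatic axis). The distance is invariant to scaling
#' either catch vector by a positive factor.
#'
#' @param catch_a,catch_b Positive catch vectors, one entry per receptor.
#' @param params An [rnl_params()] with matching length.
#' @return Nonnegative JND distance.
#' @export
rnl_distance <- function(catch_a, catch_b, params) {
  stopifnot(inherits(params, "rnl_params"))
  e <- unname(params$noise)
  n <- length(e)
  if (length(catch_a) != n || length(catch_b) != n) {
    abort("Catch vectors must match the receptor count of `params`.")
  }
  if (any(catch_a <= 0) || any(catch_b <= 0)) {
    abort("Catches must be positive (log-transform undefined otherwise).")
  }
  df <- log(as.numeric(catch_a) / as.numeric(catch_b))
  if (n == 2) {
    return(abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2))
  }
  if (n == 3) {
    num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
      e[3]^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    return(sqrt(num / den))
  }
  if (n == 4) {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
      (e[1] * e[3])^2 * (df[4] - df[2])^2 +
      (e[1] * e[4])^2 * (df[3] - df[2])^2 +
      (e[2] * e[3])^2 * (df[4] - df[1])^2 +
      (e[2] * e[4])^2 * (df[3] - df[1])^2 +
      (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
      (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    return(sqrt(num / den))
  }
  sqrt(drop(t(df) %*% rnl_metric(e) %*% df))
}

# Quadratic-form metric of the RNL chromatic space for any receptor count:
# inverse noise covariance projected orthogonally to the achromatic (1,..,1)
# direction. Coincides with the published closed forms for n = 2, 3, 4.
rnl_metric <- function(e) {
  Wi <- diag(1 / e^2, length(e))
  one <- rep(1, length(e))
  Wi - (Wi %*% one %*% t(one) %*% Wi) / sum(1 / e^2)
}

#' Transformation accuracy across receptor peak positions
#'
#' For each pigment-template receptor peak, fits T on a seeded train split of
#' the library and reports the held-out R-squared — the accuracy-vs-peak
#' curve that shows where the camera can and cannot stand in for a receptor
#' (degrading in the far UV and dipping at the inter-camera gap).
#'
#' @param peaks_nm Receptor peak wavelengths to test.
#' @param chromophore `"A1"` or `"A2"`.
#' @param library List of reflectance spectra.
#' @param camera Relativized camera [channel_set()].
#' @param illuminants Named list of target illuminants (`NULL` entries =
#'   ideal).
#' @param grid A [grid_policy()].
#' @param train_frac Fraction of the library used for fitting (default 0.9,
#'   i.e. a 2,244 / 250 split on a 2,494-member library).
#' @param seed Seed for the split permutation.
#' @return Tibble: `peak_nm`, `illuminant`, `r_squared`,
#'   `r_squared_identity`, `mape`.
#' @export
accuracy_sweep <- function(peaks_nm, chromophore = "A1", library, camera,
                           illuminants = list(ideal = NULL),
                           grid = grid_policy(), train_frac = 0.9, seed = 1) {
  if (!length(peaks_nm)) {
    return(tibble(peak_nm = numeric(), illuminant = character(),
                  r_squared = numeric(), r_squared_identity = numeric(),
                  mape = numeric()))
  }
  rng <- make_rng(seed)
  n <- length(library)
  perm <- rng$sample(n, n)
  n_train <- floor(train_frac * n)
  idx_train <- perm[seq_len(n_train)]
  idx_test <- perm[-seq_len(n_train)]
  if (is.null(names(illuminants))) {
    names(illuminants) <- paste0("illum", seq_along(illuminants))
  }
  # reflectance and camera matrices are shared by every peak and illuminant
  wl <- grid_wavelengths(grid)
  R <- t(vapply(library, function(s) resample(s, grid)$value,
                numeric(length(wl))))
  Sc <- vapply(camera$channels, function(s) resample(s, grid)$value,
               numeric(length(wl)))
  CC <- R %*% Sc
  purrr::map_dfr(names(illuminants), function(ill_name) {
    ill <- illuminants[[ill_name]]
    I_target <- if (is.null(ill)) rep(1, length(wl)) else {
      assert_kind(ill, "illuminant")
      resample(ill, grid)$value
    }
    purrr::map_dfr(peaks_nm, function(pk) {
      tmpl <- receptor_template(pk, chromophore, grid)
      sa <- tmpl$value / sum(tmpl$value)
      AC <- R %*% (sa * I_target)
      tr <- fit_catch_transform(CC[idx_train, , drop = FALSE],
                                AC[idx_train, , drop = FALSE])
      ev <- evaluate_catches(
        cbind(r1 = drop(CC[idx_test, , drop = FALSE] %*% t(tr$T))),
        AC[idx_test, , drop = FALSE]
      )
      tibble(peak_nm = pk, illuminant = ill_name,
             r_squared = ev$r_squared,
             r_squared_identity = ev$r_squared_identity,
             mape = ev$mape)
    })
  })
}

#' Transformation error for narrowband reflectances
#'
#' Stress test with Gaussian reflectance spectra: for each combination of
#' reflectance peak, receptor peak and reflectance FWHM, T (fitted on the
#' supplied broadband library) predicts the animal catch of the narrowband
#' stimulus and the absolute error against the exact catch is reported.
#' Broadband regimes (large FWHM) approach the library statistics and shrink
#' the error.
#'
#' @param fwhm_nm Reflectance FWHM values to test (nm).
#' @param reflectance_peaks_nm Reflectance peak wavelengths.
#' @param receptor_peaks_nm Receptor template peak wavelengths.
#' @param camera Relativized camera [channel_set()].
#' @param library Broadband reflectance library used to fit T.
#' @param chromophore Template chromophore for the receptors.
#' @param amplitude Peak reflectance of the Gaussian stimuli.
#' @param grid A [grid_policy()].
#' @return Tibble: `fwhm_nm`, `reflectance_peak_nm`, `receptor_peak_nm`,
#'   `abs_error`, `true_ac`, `predicted_ac`.
#' @export
narrowband_stress <- function(fwhm_nm, reflectance_peaks_nm,
                              receptor_peaks_nm, camera, library,
                              chromophore = "A1", amplitude = 0.8,
                              grid = grid_policy()) {
  purrr::map_dfr(receptor_peaks_nm, function(rpk) {
    animal <- template_receptor_set(setNames(rpk, "receptor"), chromophore,
                                    grid = grid)
    des <- build_design(library, camera, animal, NULL, grid)
    tr <- fit_catch_transform(des$CC, des$AC)
    purrr::map_dfr(fwhm_nm, function(fw) {
      purrr::map_dfr(reflectance_peaks_nm, function(spk) {
        refl <- gaussian_reflectance(spk, fw, amplitude, grid)
        cc <- matrix(channel_catches(refl, camera, NULL, grid), 1)
        truth <- channel_catches(refl, animal, NULL, grid)
        pred <- max(predict(tr, cc)[1, 1], 0)
        tibble(fwhm_nm = fw, reflectance_peak_nm = spk, receptor_peak_nm = rpk,
               abs_error = abs(pred - truth[[1]]),
               true_ac = truth[[1]], predicted_ac = pred)
      })
    })
  })
}

#' Save / load a transformation matrix as JSON
#'
#' @param transform A `catch_transform`.
#' @param path File path.
#' @return `read_transform_json()` returns a `catch_transform`.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "catch_transform"))
  jsonlite::write_json(
    list(
      T = transform$T, receptors = transform$receptors,
      channels = transform$channels, n_train = transform$n_train,
      train_r_squared = transform$train_r_squared,
      metadata = transform$metadata
    ),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  Tm <- if (is.matrix(j$T)) j$T else do.call(rbind, j$T)
  rownames(Tm) <- j$receptors
  colnames(Tm) <- j$channels
  structure(
    list(T = Tm, receptors = j$receptors, channels = j$channels,
         n_train = j$n_train,
         train_r_squared = setNames(as.numeric(j$train_r_squared),
                                    j$receptors),
         metadata = as.list(j$metadata)),
    class = "catch_transform"
  )
}
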