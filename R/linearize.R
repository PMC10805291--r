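#' Ideal target catch of a reflectance for one channel
#'
#' The camera catch a stimulus would produce under ideal isoluminant
#' illumination (photon flux 1 everywhere): the normalization target for the
#' grayscale regression. With relativized channels a flat 99% standard reads
#' 0.99 on every channel.
#'
#' @param reflectance `qc_spectrum` of kind `"reflectance"`.
#' @param channel `qc_spectrum` of kind `"sensitivity"` (relativized).
#' @param grid A [grid_policy()].
#' @return A nonnegative number.
#' @export
ideal_target_catch <- function(reflectance, channel, grid = grid_policy()) {
  quantum_catch(reflectance, channel, illuminant = NULL, grid = grid)
}

#' One-step power-law linearization and normalization
#'
#' Fits `CC = a1 * a2^p + a3` per channel by bounded nonlinear least squares
#' (Levenberg-Marquardt with box constraints, `a1 > 0`, `a2` in (1, 1e6]),
#' from pixel-value/target-catch pairs of the grayscale standards. Three
#' deterministic starts are tried and the best residual kept. This single fit
#' replaces the exact log-curve inversion plus linear regression when the
#' camera's encoding curve is unknown.
#'
#' @param samples A data frame with columns `channel`, `pixel` (encoded value
#'   in \[0, 1\]) and `target` (ideal catch), or a named list of such
#'   two-column data frames keyed by channel.
#'
#' @return A `power_law_model`: per-channel `a1`, `a2`, `a3` with residual
#'   diagnostics. Supports [tidy()] and [glance()].
#' @export
fit_power_law <- function(samples) {
  samples <- normalize_samples(samples)
  fits <- lapply(split(samples, samples$channel), fit_power_law_one)
  structure(list(fits = fits), class = "power_law_model")
}

normalize_samples <- function(samples) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("channel", "pixel", "target") %in% names(samples)))
    return(samples)
  }
  purrr::imap_dfr(samples, function(df, lab) {
    tibble(channel = lab, pixel = df$pixel, target = df$target)
  })
}

fit_power_law_one <- function(df) {
  p <- df$pixel; cc <- df$target
  if (length(p) < 4) {
    abort(sprintf("Need >= 4 samples per channel, got %d.", length(p)))
  }
  if (length(unique(round(p, 10))) < 3) {
    abort("Need >= 3 distinct pixel values to fit the power law.")
  }
  resid_fn <- function(par) par[1] * par[2]^p + par[3] - cc
  lower <- c(1e-12, 1 + 1e-9, -Inf)
  upper <- c(Inf, 1e6, Inf)
  # deterministic multi-start: from near-linear (a2 ~ 1) to log-like
  slope0 <- diff(range(cc)) / max(diff(range(p)), 1e-6)
  starts <- list(
    c(max(diff(range(cc)), 1e-3) / 1e3, 1e3, min(cc)),
    c(0.005, 8000, -0.01),
    c(max(diff(range(cc)), 1e-3) / 50, 50, min(cc)),
    c(abs(slope0) / log(1.05), 1.05, min(cc) - abs(slope0) / log(1.05)),
    c(abs(slope0) / log(1.001), 1.001, min(cc) - abs(slope0) / log(1.001))
  )
  best <- NULL
  for (st in starts) {
    fit <- try(
      minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) abort("Power-law fit failed to converge from any start.")
  par <- best$fit$par
  list(a1 = par[1], a2 = par[2], a3 = par[3],
       residual_norm = best$rn, n = length(p))
}

#' @export
print.power_law_model <- function(x, ...) {
  cat("<power_law_model> CC = a1 * a2^p + a3\n")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.power_law_model <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, lab) {
    tibble(channel = lab, a1 = f$a1, a2 = f$a2, a3 = f$a3)
  })
}

#' @exportS3Method generics::glance
glance.power_law_model <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, lab) {
    tibble(channel = lab, residual_norm = f$residual_norm, n = f$n)
  })
}

#' Grayscale normalization of linearized values
#'
#' Ordinary least-squares regression, per channel, of ideal target catches on
#' linearized grayscale pixel values. Applying the model maps linearized
#' images into the camera-catch domain, where a 100%-reflective surface reads
#' 1.0 on every channel.
#'
#' @param samples As in [fit_power_law()], but `pixel` holds *linearized*
#'   values.
#' @return A `normalization_model` with per-channel slope, intercept and R^2.
#'   Supports [tidy()] and [glance()].
#' @export
fit_normalization <- function(samples) {
  samples <- normalize_samples(samples)
  fits <- lapply(split(samples, samples$channel), function(df) {
    if (length(unique(round(df$pixel, 12))) < 2) {
      abort("Need >= 2 distinct grayscale levels to normalize.")
    }
    m <- lm(target ~ pixel, data = df)
    slope <- unname(coef(m)[2])
    if (slope <= 0) {
      abort("Non-positive normalization slope; check grayscale samples.")
    }
    ss_tot <- sum((df$target - mean(df$target))^2)
    r2 <- if (ss_tot > 0) 1 - sum(residuals(m)^2) / ss_tot else NA_real_
    list(slope = slope, intercept = unname(coef(m)[1]), r_squared = r2,
         n = nrow(df))
  })
  structure(list(fits = fits), class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("<normalization_model> catch = slope * linearized + intercept\n")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.normalization_model <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, lab) {
    tibble(channel = lab, slope = f$slope, intercept = f$intercept)
  })
}

#' @exportS3Method generics::glance
glance.normalization_model <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, lab) {
    tibble(channel = lab, r_squared = f$r_squared, n = f$n)
  })
}

#' Apply a linearization/normalization model to an image
#'
#' Maps an encoded (or, for a `normalization_model`, already linearized)
#' image into the camera-catch domain, channel by channel.
#'
#' @param image An `image_plane`; channel count must match the model.
#' @param model A `power_law_model` or `normalization_model`.
#' @param channels Optional channel labels ordering the model onto the image
#'   planes; defaults to the image's channel labels, else the model's order.
#' @return An `image_plane` in the `"camera_catch"` domain.
#' @export
apply_linearization <- function(image, model, channels = NULL) {
  stopifnot(inherits(image, "image_plane"))
  labs <- channels %||% image_channels(image) %||% names(model$fits)
  if (length(labs) != dim(image)[3]) {
    abort("Channel labels must match the image's channel count.")
  }
  if (!all(labs %in% names(model$fits))) {
    abort(sprintf(
      "Model has no fit for channel(s): %s.",
      paste(setdiff(labs, names(model$fits)), collapse = ", ")
    ))
  }
  a <- as_bare_array(image)
  out <- array(0, dim(a))
  for (i in seq_along(labs)) {
    f <- model$fits[[labs[i]]]
    out[, , i] <- if (inherits(model, "power_law_model")) {
      f$a1 * f$a2^a[, , i] + f$a3
    } else {
      f$slope * a[, , i] + f$intercept
    }
  }
  res <- image_plane(out, "camera_catch", labs)
  attr(res, "valid") <- attr(image, "valid")
  res
}

#' Save / load a calibration report as JSON
#'
#' Records the per-channel linearization/normalization model fitted for a
#' recording session.
#'
#' @param model A `power_law_model` or `normalization_model`.
#' @param path File path.
#' @return `read_calibration_json()` returns the model.
#' @export
write_calibration_json <- function(model, path) {
  type <- if (inherits(model, "power_law_model")) "power_law" else "normalization"
  jsonlite::write_json(
    list(type = type, fits = model$fits),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path)
  fits <- lapply(j$fits, function(f) lapply(f, function(v) {
    if (is.numeric(v) || is.character(v)) v else unlist(v)
  }))
  structure(
    list(fits = fits),
    class = if (j$type == "power_law") "power_law_model" else "normalization_model"
  )
}
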