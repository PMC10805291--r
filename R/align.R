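# Spatial and temporal alignment of the UV recording onto the VIS recording.
#
# Stage 1 is a coarse homography from manually matched points (reusable
# across sessions because the cameras stay rigidly mounted). Stage 2 is a
# fine correction found by maximizing the enhanced correlation coefficient
# (ECC) between intensity projections; several candidate corrections can be
# fitted on different image pairs and the one with the best mean ECC across
# an evaluation batch is kept. For video, the integer frame offset is chosen
# jointly with the spatial correction by the same mean-ECC score.

#' Spatio-temporal alignment model
#'
#' @param coarse_H 3 x 3 coarse homography (UV pixel coords to VIS pixel
#'   coords).
#' @param fine_correction 3 x 3 correction applied after `coarse_H`.
#' @param temporal_offset_frames Integer frame offset: VIS frame `t`
#'   corresponds to UV frame `t + offset`.
#' @param mean_ecc Mean ECC of the model on its evaluation pairs.
#' @return An object of class `alignment_model`.
#' @export
alignment_model <- function(coarse_H, fine_correction = diag(3),
                            temporal_offset_frames = 0L, mean_ecc = NA_real_) {
  if (abs(det(coarse_H)) < 1e-12 || abs(det(fine_correction)) < 1e-12) {
    abort("Alignment matrices must be invertible.")
  }
  structure(
    list(coarse_H = coarse_H, fine_correction = fine_correction,
         temporal_offset_frames = as.integer(temporal_offset_frames),
         mean_ecc = mean_ecc),
    class = "alignment_model"
  )
}

#' @rdname alignment_model
#' @param model An `alignment_model`.
#' @export
total_homography <- function(model) {
  model$fine_correction %*% model$coarse_H
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf(
    "<alignment_model> offset %+d frame(s), mean ECC %s\n",
    x$temporal_offset_frames,
    if (is.na(x$mean_ecc)) "unset" else sprintf("%.4f", x$mean_ecc)
  ))
  invisible(x)
}

#' Coarse homography from matched points
#'
#' Least-squares homography from user-selected matching points in the UV and
#' VIS frames. Thin wrapper over [fit_homography()] with the argument order
#' of the alignment stage.
#'
#' @param points_uv,points_vis n x 2 matrices of matching points (n >= 4).
#' @return 3 x 3 homography mapping UV pixel coords to VIS pixel coords.
#' @export
fit_coarse <- function(points_uv, points_vis) {
  fit_homography(points_uv, points_vis)
}

# 2x box-filter downsampling (trailing odd row/column dropped)
downsample2 <- function(m) {
  h <- 2 * (nrow(m) %/% 2); w <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(h), seq_len(w)]
  (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
     m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
}

# Enhanced correlation coefficient between two matrices over a mask.
ecc_value <- function(f, g, mask = NULL) {
  if (!is.null(mask)) { f <- f[mask]; g <- g[mask] }
  f <- f - mean(f); g <- g - mean(g)
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  if (nf < 1e-12 || ng < 1e-12) return(NA_real_)
  sum(f * g) / (nf * ng)
}

ecc_of_warp <- function(fixed, moving, M, min_overlap = 0.25) {
  w <- warp_image(moving, M)
  mask <- attr(w, "valid")
  if (mean(mask) < min_overlap) return(NA_real_)
  ecc_value(fixed, matrix(w, nrow(fixed), ncol(fixed)), mask)
}

params_to_matrix <- function(par, motion_model, init) {
  D <- switch(motion_model,
    translation = translation_matrix(par[1], par[2]),
    affine = affine_matrix(1 + par[1], par[2], par[3],
                           par[4], 1 + par[5], par[6]),
    homography = {
      m <- matrix(c(1 + par[1], par[2], par[3],
                    par[4], 1 + par[5], par[6],
                    par[7], par[8], 1), 3, 3, byrow = TRUE)
      m
    }
  )
  D %*% init
}

#' Fine alignment by ECC maximization
#'
#' Finds the parametric correction (applied on top of `init`) that maximizes
#' the enhanced correlation coefficient between the fixed image and the
#' warped moving image. The optimizer is an integer-translation grid search
#' followed by quasi-Newton refinement of the motion parameters. Poor
#' conditions (textureless images, vanishing overlap, no improvement over a
#' degenerate score) give a failure result rather than an error.
#'
#' @param fixed,moving Single-channel matrices or `image_plane`s (multi-
#'   channel planes are reduced: UV by its red channel, others by the mean).
#' @param init 3 x 3 initial homography mapping moving to fixed coords.
#' @param motion_model `"translation"`, `"affine"` or `"homography"`.
#' @param search_radius_px Radius of the initial integer translation search.
#' @param maxit Iteration cap for the refinement.
#' @return A list of class `ecc_result`: `ok`, `correction` (3 x 3, the full
#'   moving-to-fixed map), `ecc`, `motion_model`, and `reason` when failed.
#' @export
ecc_refine <- function(fixed, moving, init = diag(3),
                       motion_model = c("translation", "affine", "homography"),
                       search_radius_px = 8, maxit = 200) {
  motion_model <- match.arg(motion_model)
  f <- ecc_intensity(fixed)
  g <- ecc_intensity(moving)
  fail <- function(reason) {
    structure(list(ok = FALSE, correction = NULL, ecc = NA_real_,
                   motion_model = motion_model, reason = reason),
              class = "ecc_result")
  }
  if (sd(f) < 1e-9 || sd(g) < 1e-9) return(fail("textureless image"))

  # integer translation pre-search around init, run at half resolution when
  # the images are large enough (the fine stages restore full precision)
  use_pyramid <- min(dim(f), dim(g)) >= 64 && search_radius_px >= 2
  if (use_pyramid) {
    fs <- downsample2(f); gs <- downsample2(g)
    S <- diag(c(0.5, 0.5, 1))
    init_s <- S %*% init %*% solve(S)
    offs <- -ceiling(search_radius_px / 2):ceiling(search_radius_px / 2)
    best <- list(par = NULL, ecc = -Inf)
    for (dx in offs) for (dy in offs) {
      e <- ecc_of_warp(fs, gs, translation_matrix(dx, dy) %*% init_s)
      if (!is.na(e) && e > best$ecc) best <- list(par = c(dx, dy), ecc = e)
    }
    if (!is.finite(best$ecc)) return(fail("no valid overlap"))
    best$par <- 2 * best$par
  } else {
    best <- list(par = NULL, ecc = -Inf)
    offs <- -search_radius_px:search_radius_px
    for (dx in offs) for (dy in offs) {
      e <- ecc_of_warp(f, g, translation_matrix(dx, dy) %*% init)
      if (!is.na(e) && e > best$ecc) best <- list(par = c(dx, dy), ecc = e)
    }
    if (!is.finite(best$ecc)) return(fail("no valid overlap"))
  }
  init2 <- translation_matrix(best$par[1], best$par[2]) %*% init

  npar <- switch(motion_model, translation = 2, affine = 6, homography = 8)
  par0 <- rep(0, npar)
  pscale <- switch(motion_model,
    translation = c(1, 1),
    affine = c(0.01, 0.01, 1, 0.01, 0.01, 1),
    homography = c(0.01, 0.01, 1, 0.01, 0.01, 1, 1e-4, 1e-4)
  )
  obj <- function(par) {
    e <- ecc_of_warp(f, g, params_to_matrix(par, motion_model, init2))
    if (is.na(e)) 1 else -e
  }
  ctrl <- list(maxit = maxit, parscale = pscale, reltol = 1e-9)
  opt <- try(
    optim(par0, obj, method = "Nelder-Mead", control = ctrl),
    silent = TRUE
  )
  if (inherits(opt, "try-error")) return(fail("optimizer error"))
  # one restart from the first solution guards against simplex collapse
  opt2 <- try(
    optim(opt$par, obj, method = "Nelder-Mead", control = ctrl),
    silent = TRUE
  )
  if (!inherits(opt2, "try-error") && opt2$value < opt$value) opt <- opt2
  M <- params_to_matrix(opt$par, motion_model, init2)
  e <- ecc_of_warp(f, g, M)
  if (is.na(e)) return(fail("no valid overlap after refinement"))
  structure(
    list(ok = TRUE, correction = M, ecc = e, motion_model = motion_model,
         reason = NULL),
    class = "ecc_result"
  )
}

# Intensity projection for ECC: UV planes use their first (red) channel,
# which carries the UV camera's signal; anything else uses the channel mean.
ecc_intensity <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(inherits(x, "image_plane") || is.array(x))
  a <- as_bare_array(x)
  labs <- if (inherits(x, "image_plane")) image_channels(x) else NULL
  if (!is.null(labs) && grepl("^uv", labs[1])) a[, , 1] else to_intensity(x)
}

#' Select the best alignment among candidates
#'
#' Applies each candidate correction to every evaluation pair, scores it by
#' the mean ECC, and returns the candidate with the highest mean (ties broken
#' by first index).
#'
#' @param candidates List of 3 x 3 matrices or [ecc_refine()] results.
#' @param eval_pairs List of `list(fixed = , moving = )` image pairs.
#' @param coarse_H Coarse homography recorded in the returned model; the
#'   candidates are full moving-to-fixed maps.
#' @return An [alignment_model()] carrying the winning correction and its
#'   mean ECC.
#' @export
select_alignment <- function(candidates, eval_pairs, coarse_H = diag(3)) {
  if (!length(candidates)) abort("Need at least one candidate.")
  if (!length(eval_pairs)) abort("Need at least one evaluation pair.")
  mats <- lapply(candidates, function(cand) {
    if (inherits(cand, "ecc_result")) {
      if (!isTRUE(cand$ok)) NULL else cand$correction
    } else cand
  })
  scores <- vapply(mats, function(M) {
    if (is.null(M)) return(NA_real_)
    e <- vapply(eval_pairs, function(p) {
      ecc_of_warp(ecc_intensity(p$fixed), ecc_intensity(p$moving), M)
    }, numeric(1))
    mean(e, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(scores))) abort("All candidates failed on all pairs.")
  i <- which.max(ifelse(is.na(scores), -Inf, scores))
  alignment_model(
    coarse_H = coarse_H,
    fine_correction = mats[[i]] %*% solve(coarse_H),
    mean_ecc = scores[i]
  )
}

frame_motion_scores <- function(frames) {
  n <- length(frames)
  if (n < 2) return(numeric(0))
  vapply(2:n, function(t) {
    mean(abs(ecc_intensity(frames[[t]]) - ecc_intensity(frames[[t - 1]])))
  }, numeric(1))
}

#' Joint spatial and temporal video alignment
#'
#' Scores motion as the mean absolute inter-frame difference, picks the batch
#' of frames with the most motion, and for every candidate integer offset
#' fits a spatial ECC correction and evaluates its mean ECC across the batch;
#' the offset and spatial model with the best mean ECC win jointly. Sub-frame
#' misalignment is irreducible (the cameras run free), so the offset search
#' is integer-only.
#'
#' @param uv_frames,vis_frames Lists of frames (`image_plane` or matrix).
#' @param coarse_H Coarse homography (UV to VIS pixels).
#' @param offset_range Max |offset| searched, frames (default 15).
#' @param motion_threshold Minimum mean absolute inter-frame difference for a
#'   batch to count as having adequate motion.
#' @param batch_len Frames per evaluation batch.
#' @param motion_model Motion model of the per-offset candidate fits
#'   (translation is fast and suffices to rank offsets).
#' @param final_model Motion model of the one refinement run at the winning
#'   offset; defaults to `motion_model`.
#' @param search_radius_px Integer translation search radius of each ECC fit.
#' @return An [alignment_model()] with `temporal_offset_frames` set.
#' @export
temporal_align <- function(uv_frames, vis_frames, coarse_H = diag(3),
                           offset_range = 15, motion_threshold = 0.005,
                           batch_len = 4,
                           motion_model = c("translation", "affine",
                                            "homography"),
                           final_model = NULL, search_radius_px = 8) {
  motion_model <- match.arg(motion_model)
  final_model <- final_model %||% motion_model
  n_vis <- length(vis_frames); n_uv <- length(uv_frames)
  scores <- frame_motion_scores(vis_frames)
  if (!length(scores)) abort("Need at least 2 VIS frames.")
  win <- batch_len - 1
  if (length(scores) < win) abort("Sequence shorter than the batch length.")
  win_mean <- vapply(seq_len(length(scores) - win + 1), function(s) {
    mean(scores[s:(s + win - 1)])
  }, numeric(1))
  if (max(win_mean) < motion_threshold) {
    abort("Insufficient motion for temporal alignment.")
  }
  # prefer batches for which the whole offset range stays inside the UV
  # sequence, so no candidate offset is silently excluded
  starts <- seq_along(win_mean)
  full_range <- starts >= 1 + offset_range &
    starts + batch_len - 1 <= n_uv - offset_range
  eligible <- full_range & win_mean >= motion_threshold
  t0 <- if (any(eligible)) {
    starts[eligible][which.max(win_mean[eligible])]
  } else {
    which.max(win_mean)
  }
  batch <- t0:(t0 + batch_len - 1)
  offsets <- -offset_range:offset_range
  offsets <- offsets[batch[1] + offsets >= 1 &
                       batch[length(batch)] + offsets <= n_uv]
  if (!length(offsets)) abort("No feasible offsets within the sequences.")
  best <- NULL
  mid <- batch[ceiling(length(batch) / 2)]
  batch_ecc <- function(off, M) {
    e <- vapply(batch, function(t) {
      ecc_of_warp(ecc_intensity(vis_frames[[t]]),
                  ecc_intensity(uv_frames[[t + off]]), M)
    }, numeric(1))
    mean(e, na.rm = TRUE)
  }
  for (off in offsets) {
    # candidates only need to rank offsets; the winning offset is refined
    # once more below, so cap the per-offset iteration budget
    cand <- ecc_refine(vis_frames[[mid]], uv_frames[[mid + off]],
                       init = coarse_H, motion_model = motion_model,
                       search_radius_px = search_radius_px, maxit = 60)
    if (!isTRUE(cand$ok)) next
    me <- batch_ecc(off, cand$correction)
    if (is.null(best) || me > best$mean_ecc) {
      best <- list(offset = off, M = cand$correction, mean_ecc = me)
    }
  }
  if (is.null(best)) abort("Spatial alignment failed for every offset.")
  if (final_model != motion_model) {
    fin <- ecc_refine(vis_frames[[mid]], uv_frames[[mid + best$offset]],
                      init = best$M, motion_model = final_model,
                      search_radius_px = 1, maxit = 400)
    if (isTRUE(fin$ok)) {
      me <- batch_ecc(best$offset, fin$correction)
      if (me >= best$mean_ecc) {
        best$M <- fin$correction
        best$mean_ecc <- me
      }
    }
  }
  alignment_model(
    coarse_H = coarse_H,
    fine_correction = best$M %*% solve(coarse_H),
    temporal_offset_frames = best$offset,
    mean_ecc = best$mean_ecc
  )
}

#' Ghosting-check composite
#'
#' Builds a 3-band image whose red and blue bands come from the VIS frame and
#' whose green band is the aligned UV frame, for visual inspection: residual
#' misalignment shows as green/magenta fringing.
#'
#' @param vis VIS frame (`image_plane`, 3 channels, or matrix).
#' @param uv_aligned Aligned UV frame, same height and width.
#' @return An `image_plane` in the `"display"` domain.
#' @export
ghost_composite <- function(vis, uv_aligned) {
  if (!length(vis) || !length(uv_aligned)) abort("Empty image.")
  v <- as_bare_array(if (is.matrix(vis)) array(vis, c(dim(vis), 1)) else vis)
  g <- ecc_intensity(uv_aligned)
  if (!all(dim(g) == dim(v)[1:2])) {
    abort("VIS and aligned UV frames must share height and width.")
  }
  r <- if (dim(v)[3] >= 3) v[, , 1] else v[, , 1]
  b <- if (dim(v)[3] >= 3) v[, , 3] else v[, , 1]
  out <- array(0, c(dim(g), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  image_plane(pmin(pmax(out, 0), 1), "display", c("R", "G", "B"))
}

#' Save / load an alignment model as JSON
#'
#' @param model An [alignment_model()].
#' @param path File path.
#' @return `read_alignment_json()` returns an `alignment_model`.
#' @export
write_alignment_json <- function(model, path) {
  stopifnot(inherits(model, "alignment_model"))
  jsonlite::write_json(
    list(
      coarse_H = model$coarse_H, fine_correction = model$fine_correction,
      temporal_offset_frames = model$temporal_offset_frames,
      mean_ecc = model$mean_ecc
    ),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_alignment_json
#' @export
read_alignment_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat3 <- function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), 3, 3, byrow = TRUE)
  }
  alignment_model(
    coarse_H = as_mat3(j$coarse_H),
    fine_correction = as_mat3(j$fine_correction),
    temporal_offset_frames = j$temporal_offset_frames,
    mean_ecc = j$mean_ecc %||% NA_real_
  )
}
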