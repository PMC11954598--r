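#' Metric configuration
#'
#' @param Q1,Q2 small positive stabilizing constants of the structural
#'   similarity index (both default 0.01). They are applied exactly as
#'   stated, i.e. *not* rescaled by the squared dynamic range; set
#'   `classic_scaling = TRUE` for the conventional `(K L)^2` form.
#' @param window side of the square sliding SSIM window in pixels.
#' @param dynamic_range intensity dynamic range used by PSNR/SSIM when
#'   `classic_scaling` is on.
#' @param classic_scaling logical; rescale `Q1`, `Q2` by
#'   `dynamic_range^2`.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(Q1 = 0.01, Q2 = 0.01, window = 11L,
                          dynamic_range = 1, classic_scaling = FALSE) {
  if (Q1 <= 0 || Q2 <= 0) stop("metric_config: Q1 and Q2 must be > 0")
  structure(list(Q1 = Q1, Q2 = Q2, window = as.integer(window),
                 dynamic_range = dynamic_range,
                 classic_scaling = isTRUE(classic_scaling)),
            class = "metric_config")
}

#' Signal-to-background ratio
#'
#' `SBR = mu_signal / mu_background`: the mean intensity over annotated
#' signal voxels divided by the mean over background voxels.
#'
#' @param image an [image_stack] or numeric array.
#' @param signal_mask,background_mask disjoint non-empty [mask_volume]s
#'   (or logical arrays) co-registered with `image`.
#' @return non-negative number; `Inf` (with a warning) if the background
#'   mean is zero.
#' @export
sbr <- function(image, signal_mask, background_mask) {
  img <- as_voxels(image)
  sm <- as_voxels(signal_mask); bm <- as_voxels(background_mask)
  check_coregistered(img, sm, "image and signal mask")
  check_coregistered(img, bm, "image and background mask")
  if (!any(sm) || !any(bm)) stop("sbr: signal and background masks must be non-empty")
  if (any(sm & bm)) stop("sbr: signal and background masks must be disjoint")
  mu_s <- mean(img[sm]); mu_b <- mean(img[bm])
  if (mu_b == 0) {
    warning("sbr: background mean is zero; returning Inf")
    return(Inf)
  }
  mu_s / mu_b
}

# 6-connected binary dilation by one voxel, repeated `iter` times
dilate_mask <- function(m, iter = 1L) {
  d <- dim(m)
  for (i in seq_len(iter)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  m
}

#' Signal/background masks from a vessel truth mask
#'
#' Signal voxels are the vessel truth; background voxels are those at
#' least `margin` voxels away from any vessel (computed by morphological
#' dilation), mirroring manual annotation that avoids the vessel rim.
#'
#' @param truth vessel-truth [mask_volume] (or logical array).
#' @param margin exclusion margin in voxels.
#' @return list with `signal` and `background` [mask_volume]s.
#' @export
sbr_masks_from_truth <- function(truth, margin = 3L) {
  tv <- as_voxels(truth)
  dil <- dilate_mask(tv, iter = as.integer(margin))
  list(signal = mask_volume(tv, role = "signal"),
       background = mask_volume(!dil, role = "background"))
}

#' Depth-binned SBR profile
#'
#' Pools signal and background voxels over bins of consecutive frames
#' and reports one SBR per bin at the bin's central depth.
#'
#' @param stack an [image_stack].
#' @param signal_mask,background_mask masks co-registered with `stack`.
#' @param bin bin width in frames.
#' @return data.frame with columns `depth_um`, `sbr`, `frames`.
#' @export
sbr_depth_profile <- function(stack, signal_mask, background_mask, bin = 1L) {
  img <- stack$voxels
  sm <- as_voxels(signal_mask); bm <- as_voxels(background_mask)
  check_coregistered(img, sm); check_coregistered(img, bm)
  nz <- dim(img)[1]
  depths <- frame_depths(stack)
  starts <- seq(1L, nz, by = as.integer(bin))
  res <- lapply(starts, function(s) {
    ks <- s:min(s + bin - 1L, nz)
    svals <- img[ks, , ][sm[ks, , ]]
    bvals <- img[ks, , ][bm[ks, , ]]
    val <- if (length(svals) == 0 || length(bvals) == 0) NA_real_
           else if (mean(bvals) == 0) Inf
           else mean(svals) / mean(bvals)
    data.frame(depth_um = mean(depths[ks]), sbr = val, frames = length(ks))
  })
  do.call(rbind, res)
}

#' Mean squared error
#'
#' Average squared difference between a test image and a reference,
#' `MSE = ||I - L||^2 / N` with `N` the pixel count.
#'
#' @param test,reference arrays of identical shape.
#' @return non-negative number.
#' @export
mse <- function(test, reference) {
  a <- as_voxels(test); b <- as_voxels(reference)
  check_coregistered(a, b, "test and reference")
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `PSNR = 10 log10(max(I)^2 / MSE)` with `max(I)` the maximum of the
#' reference. Identical inputs give `Inf`.
#'
#' @param test,reference arrays of identical shape; `reference` is the
#'   ground truth whose maximum defines the peak.
#' @param max_val optional explicit peak value; defaults to
#'   `max(reference)`.
#' @return PSNR in decibels (`Inf` when MSE is zero).
#' @export
psnr <- function(test, reference, max_val = NULL) {
  m <- mse(test, reference)
  peak <- if (is.null(max_val)) max(as_voxels(reference)) else max_val
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

# sum over all w x w windows at valid positions, via a summed-area table
box_sums <- function(m, w) {
  S <- apply(apply(m, 2, cumsum), 1, cumsum)  # S[j, i] after second apply
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  nr <- nrow(m) - w + 1L; nc <- ncol(m) - w + 1L
  i <- seq_len(nr); j <- seq_len(nc)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

ssim_frame <- function(u, v, cfg) {
  w <- cfg$window
  if (w > min(dim(u))) stop("ssim: window larger than image")
  Q1 <- cfg$Q1; Q2 <- cfg$Q2
  if (cfg$classic_scaling) {
    Q1 <- Q1 * cfg$dynamic_range^2
    Q2 <- Q2 * cfg$dynamic_range^2
  }
  n <- w * w
  mu_u <- box_sums(u, w) / n
  mu_v <- box_sums(v, w) / n
  var_u <- box_sums(u * u, w) / n - mu_u^2
  var_v <- box_sums(v * v, w) / n - mu_v^2
  cov_uv <- box_sums(u * v, w) / n - mu_u * mu_v
  num <- (2 * mu_u * mu_v + Q1) * (2 * cov_uv + Q2)
  den <- (mu_u^2 + mu_v^2 + Q1) * (var_u + var_v + Q2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Windowed SSIM: each square window is scored as
#' `(2 mu_u mu_v + Q1)(2 cov_uv + Q2) /
#'  ((mu_u^2 + mu_v^2 + Q1)(var_u + var_v + Q2))`
#' (population moments, uniform weights) and scores are averaged over all
#' fully contained window positions. For a multi-frame stack the
#' per-frame values are averaged.
#'
#' @param test,reference images or stacks of identical shape, intensities
#'   on the configured dynamic range.
#' @param cfg a [metric_config()].
#' @return value in `(-1, 1]`; exactly 1 for identical inputs.
#' @export
ssim <- function(test, reference, cfg = metric_config()) {
  a <- as_voxels(test); b <- as_voxels(reference)
  check_coregistered(a, b, "test and reference")
  if (is.matrix(a)) return(ssim_frame(a, b, cfg))
  d <- dim(a)
  if (length(d) == 2L) return(ssim_frame(matrix(a, d[1], d[2]), matrix(b, d[1], d[2]), cfg))
  vals <- vapply(seq_len(d[1]), function(k) {
    ssim_frame(matrix(a[k, , ], d[2], d[3]), matrix(b[k, , ], d[2], d[3]), cfg)
  }, numeric(1))
  mean(vals)
}

#' Voxel-wise confusion counts
#'
#' @param pred,truth co-registered binary masks.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN` summing to the evaluated voxel count.
#' @export
confusion <- function(pred, truth) {
  p <- as_voxels(pred); t <- as_voxels(truth)
  check_coregistered(p, t, "prediction and truth")
  p <- as.logical(p); t <- as.logical(t)
  structure(list(
    TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t)
  ), class = "confusion_counts")
}

#' F1 score from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of sensitivity and
#' precision. The degenerate empty-vs-empty case (TP = FP = FN = 0) is
#' defined as 1 with a warning.
#'
#' @param counts a `confusion_counts` object, or a prediction mask if
#'   `truth` is also given.
#' @param truth optional truth mask (computes the confusion internally).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(counts, truth = NULL) {
  if (!inherits(counts, "confusion_counts")) counts <- confusion(counts, truth)
  denom <- 2 * counts$TP + counts$FP + counts$FN
  if (denom == 0) {
    warning("f1_score: no positives in prediction or truth; returning 1 (empty-empty agreement)")
    return(1)
  }
  2 * counts$TP / denom
}
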