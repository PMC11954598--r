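#' Extract training patches from the shallow side of a stack
#'
#' Self-supervision contract: the frames nearest the objective (the
#' "shallow side", where image quality is best) serve as clean ground
#' truth. Patches are drawn only from the first
#' `ceil(shallow_fraction * n_frames)` frames, at seeded random
#' positions, after per-stack min-max normalization to `[0, 1]`.
#'
#' @param stack an [image_stack] with at least 2 frames.
#' @param cfg a [diffusion_config()].
#' @param n_patches number of patches to draw.
#' @param seed integer RNG seed.
#' @return list of `patch_size x patch_size` matrices; attribute
#'   `frames_used` records which frames were sampled.
#' @export
extract_shallow_subvolumes <- function(stack, cfg, n_patches = 64L, seed = 1L) {
  d <- dim(stack$voxels)
  if (d[1] < 2L) stop("extract_shallow_subvolumes: stack must have >= 2 frames")
  ps <- cfg$patch_size
  if (ps > d[2] || ps > d[3]) {
    stop("extract_shallow_subvolumes: patch size larger than frame")
  }
  n_shallow <- max(1L, ceiling(cfg$shallow_fraction * d[1]))
  norm <- normalize_stack(stack)
  vox <- norm$stack$voxels
  set.seed(as.integer(seed))
  frames <- sample.int(n_shallow, n_patches, replace = TRUE)
  ys <- if (d[2] == ps) rep(1L, n_patches) else sample.int(d[2] - ps + 1L, n_patches, replace = TRUE)
  xs <- if (d[3] == ps) rep(1L, n_patches) else sample.int(d[3] - ps + 1L, n_patches, replace = TRUE)
  patches <- lapply(seq_len(n_patches), function(i) {
    matrix(vox[frames[i], ys[i] + seq_len(ps) - 1L, xs[i] + seq_len(ps) - 1L], ps, ps)
  })
  attr(patches, "frames_used") <- sort(unique(frames))
  patches
}

rot90m <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Augment training patches
#'
#' Expands the patch set with seeded geometric transforms: horizontal and
#' vertical flips and 90-degree rotations. With both flags on, each patch
#' yields its 8 dihedral variants (originals included); with all flags
#' off the input is returned unchanged.
#'
#' @param patches list of square matrices.
#' @param flip,rotate logical flags.
#' @param seed integer seed controlling the (deterministic) output order.
#' @return augmented list of matrices.
#' @export
augment_patches <- function(patches, flip = TRUE, rotate = TRUE, seed = 1L) {
  if (length(patches) == 0L) stop("augment_patches: empty patch list")
  if (!flip && !rotate) return(patches)
  flipud <- function(m) m[nrow(m):1, , drop = FALSE]
  fliplr <- function(m) m[, ncol(m):1, drop = FALSE]
  out <- list()
  for (p in patches) {
    vars <- list(p)
    if (rotate) {
      r <- p
      for (i in 1:3) { r <- rot90m(r); vars[[length(vars) + 1L]] <- r }
    }
    if (flip) {
      # rotations x vertical flip span the full dihedral group of 8
      vars <- c(vars, lapply(vars, flipud))
      if (!rotate) vars <- c(vars, list(fliplr(p), fliplr(flipud(p))))
    }
    out <- c(out, vars)
  }
  set.seed(as.integer(seed))
  out[sample.int(length(out))]
}

#' Closed-form forward diffusion marginal
#'
#' `x_t = sqrt(alpha_bar_t) x0 + sqrt(1 - alpha_bar_t) eps`: the
#' Gaussian forward process that mimics progressive image degradation.
#'
#' @param x0 clean patch (matrix).
#' @param t step index in `1..T`.
#' @param cfg a [diffusion_config()].
#' @param eps standard-normal noise draw of the same shape as `x0`
#'   (drawn internally when `NULL`).
#' @return noised patch `x_t`.
#' @export
forward_diffuse <- function(x0, t, cfg, eps = NULL) {
  t <- as.integer(t)
  if (t < 1L || t > cfg$T) stop("forward_diffuse: t out of range 1..T")
  if (is.null(eps)) eps <- matrix(stats::rnorm(length(x0)), nrow(x0), ncol(x0))
  ab <- cfg$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Train the diffusion denoiser
#'
#' Standard DDPM training: for each minibatch patch a step `t` is drawn
#' uniformly from `1..T`, noise `eps` is injected through the closed-form
#' marginal, and the U-Net is trained with Adam to predict `eps` under a
#' mean-squared-error loss. Patches (expected in `[0, 1]`) are mapped to
#' `[-1, 1]` internally. All randomness is seeded; equal seeds give
#' identical loss histories.
#'
#' @param patches list of square matrices in `[0, 1]`, sides divisible
#'   by 8.
#' @param cfg a [diffusion_config()].
#' @param spec a [unet_spec()] (defaults to one built from `cfg`).
#' @param seed integer RNG seed.
#' @return An object of class `denoiser_model`: fields `params`, `spec`,
#'   `cfg`, `loss_history` (one mean loss per epoch), `version`.
#' @export
train_diffusion <- function(patches, cfg, spec = NULL, seed = 1L) {
  if (length(patches) < 1L) stop("train_diffusion: need at least one patch")
  if (is.null(spec)) spec <- unet_spec(base_width = cfg$base_width)
  params <- unet_init(spec, seed = derive_seed(seed, 101L))
  state <- adam_init(params)
  n <- length(patches)
  loss_hist <- numeric(cfg$epochs)
  set.seed(derive_seed(seed, 202L))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_losses <- numeric(0)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      gacc <- NULL
      bloss <- 0
      for (i in idx) {
        x0 <- patches[[i]] * 2 - 1
        t <- sample.int(cfg$T, 1L)
        eps <- matrix(stats::rnorm(length(x0)), nrow(x0), ncol(x0))
        xt <- forward_diffuse(x0, t, cfg, eps)
        fw <- unet_forward(xt, t, params, spec, want_cache = TRUE)
        resid <- fw$y - eps
        bloss <- bloss + mean(resid^2)
        dy <- 2 * resid / length(resid)
        g <- unet_backward(dy, params, spec, fw$cache)
        gacc <- if (is.null(gacc)) g else nn_map2(gacc, g, `+`)
      }
      gacc <- rapply(gacc, function(x) x / length(idx), how = "replace")
      upd <- adam_step(params, gacc, state, lr = cfg$learning_rate)
      params <- upd$params; state <- upd$state
      ep_losses <- c(ep_losses, bloss / length(idx))
    }
    loss_hist[ep] <- mean(ep_losses)
    if (!is.finite(loss_hist[ep])) {
      stop(sprintf("train_diffusion: loss diverged (non-finite) at epoch %d", ep))
    }
    dv_log("train", sprintf("epoch %d/%d loss %.5f", ep, cfg$epochs, loss_hist[ep]))
  }
  structure(
    list(params = params, spec = spec, cfg = cfg,
         loss_history = loss_hist, version = "deepvasc-ckpt-1"),
    class = "denoiser_model"
  )
}

#' @export
print.denoiser_model <- function(x, ...) {
  cat(sprintf("<denoiser_model> T=%d, base width %d, %d epoch(s), final loss %.5f\n",
              x$cfg$T, x$spec$base_width, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Save / load a trained denoiser checkpoint
#'
#' The checkpoint is versioned and round-trips exactly: predictions from
#' a reloaded model are bit-identical.
#'
#' @param model a `denoiser_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the model (load).
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "denoiser_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "denoiser_model") || !identical(model$version, "deepvasc-ckpt-1")) {
    stop("load_denoiser: not a recognized checkpoint")
  }
  model
}

#' Estimate the matching diffusion step of a noisy frame
#'
#' Estimates the additive noise level of a frame (Immerkaer's fast
#' Laplacian-difference estimator, robust to image structure), maps it to
#' the `[-1, 1]` training scale, and returns the smallest `t` whose
#' forward-marginal noise amplitude `sqrt(1 - alpha_bar_t)` is at least
#' the estimate. A frame at that step is consistent with the model's
#' `x_t` assumption.
#'
#' @param frame matrix in `[0, 1]`.
#' @param cfg a [diffusion_config()].
#' @param max_t optional cap on the returned step.
#' @return integer step in `1..T`.
#' @export
estimate_t_start <- function(frame, cfg, max_t = cfg$T) {
  H <- nrow(frame); W <- ncol(frame)
  if (H < 3L || W < 3L) return(1L)
  L <- frame[1:(H - 2), 2:(W - 1)] + frame[3:H, 2:(W - 1)] +
       frame[2:(H - 1), 1:(W - 2)] + frame[2:(H - 1), 3:W] -
       4 * frame[2:(H - 1), 2:(W - 1)]
  # second difference of white noise has variance 20 sigma^2; use a
  # median-based scale for robustness to structure edges
  sigma <- stats::median(abs(L)) / (0.6745 * sqrt(20))
  sigma_train <- 2 * sigma  # [0,1] -> [-1,1] doubles amplitudes
  amp <- sqrt(1 - cfg$alpha_bar)
  t <- which(amp >= sigma_train)[1]
  if (is.na(t)) t <- cfg$T
  min(max(t, 1L), as.integer(max_t))
}

#' Reverse diffusion denoising of a single frame
#'
#' Standard DDPM ancestral sampling initialized at the input frame
#' treated as `x_{t_start}`: for `t = t_start..1`,
#' `x_{t-1} = (x_t - beta_t / sqrt(1 - alpha_bar_t) eps_hat) /
#' sqrt(1 - beta_t) + sqrt(beta_t) z` (no noise injected at the final
#' step). Input is expected in `[0, 1]` and is mapped to the `[-1, 1]`
#' model scale and back.
#'
#' @param frame matrix in `[0, 1]`, sides divisible by 8.
#' @param model a trained `denoiser_model`.
#' @param t_start starting step in `1..T`; `NULL` selects it per frame
#'   with [estimate_t_start()].
#' @param seed integer RNG seed for the ancestral noise.
#' @return denoised matrix, same shape, finite.
#' @export
reverse_denoise <- function(frame, model, t_start = NULL, seed = 1L) {
  cfg <- model$cfg
  if (is.null(t_start)) t_start <- estimate_t_start(frame, cfg)
  t_start <- as.integer(t_start)
  if (t_start < 1L || t_start > cfg$T) stop("reverse_denoise: t_start out of range 1..T")
  set.seed(as.integer(seed))
  x <- frame * 2 - 1
  for (t in seq(t_start, 1L)) {
    eps_hat <- unet_forward(x, t, model$params, model$spec)$y
    beta_t <- cfg$beta[t]
    ab_t <- cfg$alpha_bar[t]
    mean_t <- (x - beta_t / sqrt(1 - ab_t) * eps_hat) / sqrt(1 - beta_t)
    if (t > 1L) {
      z <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
      x <- mean_t + sqrt(beta_t) * z
    } else {
      x <- mean_t
    }
  }
  (x + 1) / 2
}

#' Train a denoiser on the shallow side of a stack
#'
#' The self-supervised training entry point: the stack is stripe-filtered
#' and neighbor-depth averaged (the same preprocessing applied at
#' inference), patches are extracted from its shallow side — the frames
#' nearest the objective, where image quality is best — optionally
#' augmented, and the diffusion model is trained on them. No external
#' clean data is consumed.
#'
#' @param stack the (noisy) [image_stack] to be enhanced.
#' @param cfg a [pipeline_config()].
#' @param n_patches patches to draw before augmentation.
#' @param seed integer RNG seed.
#' @return a trained `denoiser_model`.
#' @export
train_for_stack <- function(stack, cfg = pipeline_config(), n_patches = 24L, seed = 1L) {
  lr <- lr_denoise_stack(stack, threshold = cfg$lr_ratio_threshold)
  avg <- neighbor_depth_average(lr$stack, cfg$neighbor_avg_radius)
  patches <- extract_shallow_subvolumes(avg, cfg$diffusion, n_patches = n_patches,
                                        seed = derive_seed(seed, 11L))
  if (cfg$diffusion$augment) {
    patches <- augment_patches(patches, flip = TRUE, rotate = FALSE,
                               seed = derive_seed(seed, 12L))
  }
  train_diffusion(patches, cfg$diffusion, seed = derive_seed(seed, 13L))
}

#' Uniform neighbor-depth averaging
#'
#' Replaces each frame by the uniform mean of the frames within
#' `radius` planes of it (window truncated at the stack ends). Adjacent
#' planes image nearly the same structures, so averaging reinforces
#' signal against uncorrelated photon noise.
#'
#' @param stack an [image_stack].
#' @param radius window half-width in frames (`0` is the identity).
#' @return averaged [image_stack].
#' @export
neighbor_depth_average <- function(stack, radius = 1L) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("neighbor_depth_average: radius must be >= 0")
  if (radius == 0L) return(stack)
  vox <- stack$voxels
  nz <- dim(vox)[1]
  out <- vox
  for (k in seq_len(nz)) {
    ks <- max(1L, k - radius):min(nz, k + radius)
    out[k, , ] <- apply(vox[ks, , , drop = FALSE], c(2, 3), mean)
  }
  image_stack(out, z_step = stack$z_step, z0_depth = stack$z0_depth,
              bit_depth = stack$bit_depth)
}

#' Full restoration pipeline: stripe removal, depth averaging, diffusion
#'
#' Applies, in order: frame-wise low-rank stripe removal
#' ([lr_denoise_stack()]), uniform neighbor-depth averaging
#' ([neighbor_depth_average()]), and per-frame reverse diffusion
#' ([reverse_denoise()]) with a noise-adaptive (or fixed) starting step.
#' Each frame is min-max normalized for the network (deep frames are dim
#' relative to the stack maximum, while the model is trained on
#' full-range shallow patches) and mapped back afterwards.
#'
#' @param stack the raw [image_stack].
#' @param model a trained `denoiser_model` (trained on the shallow side
#'   of this stack or on a compatible corpus).
#' @param cfg a [pipeline_config()].
#' @param seed integer RNG seed.
#' @param t_start optional fixed starting step overriding the per-frame
#'   noise-adaptive choice.
#' @param keep_stages record per-stage intermediates in the
#'   `stages` attribute.
#' @return enhanced [image_stack].
#' @export
lrdm_enhance <- function(stack, model, cfg = pipeline_config(), seed = 1L,
                         t_start = NULL, keep_stages = FALSE) {
  stopifnot(inherits(stack, "image_stack"), inherits(model, "denoiser_model"))
  lr <- lr_denoise_stack(stack, threshold = cfg$lr_ratio_threshold)
  avg <- neighbor_depth_average(lr$stack, cfg$neighbor_avg_radius)
  vox <- avg$voxels
  d <- dim(vox)
  out <- vox
  for (k in seq_len(d[1])) {
    fr <- matrix(vox[k, , ], d[2], d[3])
    # per-frame normalization: deep frames are dim relative to the stack
    # maximum, while the model is trained on full-range shallow patches
    lo <- min(fr); hi <- max(fr)
    if (hi > lo) {
      fr01 <- (fr - lo) / (hi - lo)
      ts <- if (is.null(t_start)) {
        estimate_t_start(fr01, model$cfg, max_t = cfg$t_start_max)
      } else {
        t_start
      }
      den <- reverse_denoise(fr01, model, t_start = ts,
                             seed = derive_seed(seed, 500L + k))
      out[k, , ] <- den * (hi - lo) + lo
    }
  }
  out <- pmax(out, 0)
  enhanced <- image_stack(out, z_step = stack$z_step, z0_depth = stack$z0_depth,
                          bit_depth = stack$bit_depth)
  if (keep_stages) {
    attr(enhanced, "stages") <- list(lr = lr$stack, averaged = avg,
                                     reports = lr$reports)
  }
  enhanced
}
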