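#' Diffusion model configuration
#'
#' Holds the forward-process schedule and training hyperparameters of the
#' denoising diffusion model. The noise schedule is a monotone sequence of
#' variances `beta_1..beta_T` in (0, 1); the derived signal-retention
#' products `alpha_bar_t = prod(1 - beta_s)` are strictly decreasing.
#'
#' @param T number of diffusion steps (default 200).
#' @param beta_min,beta_max endpoints of the linear beta schedule
#'   (standard defaults 1e-4 and 2e-2).
#' @param epochs training epochs (default 300).
#' @param learning_rate Adam learning rate.
#' @param patch_size square training patch side in pixels (default 256;
#'   the network is resolution-relative and runs identically at 32-64 px).
#' @param base_width base channel width of the U-Net.
#' @param shallow_fraction fraction of the stack depth (nearest the
#'   objective) treated as the clean "shallow side" used for training.
#' @param augment logical: apply flip/rotation augmentation.
#' @param batch_size minibatch size.
#' @return An object of class `diffusion_config`.
#' @export
diffusion_config <- function(T = 200L, beta_min = 1e-4, beta_max = 2e-2,
                             epochs = 300L, learning_rate = 1e-3,
                             patch_size = 256L, base_width = 8L,
                             shallow_fraction = 0.2, augment = TRUE,
                             batch_size = 8L) {
  T <- as.integer(T)
  epochs <- as.integer(epochs)
  if (T < 1L) stop("diffusion_config: T must be >= 1")
  if (epochs < 1L) stop("diffusion_config: epochs must be >= 1")
  if (!(beta_min > 0 && beta_max < 1 && beta_min <= beta_max)) {
    stop("diffusion_config: need 0 < beta_min <= beta_max < 1")
  }
  if (shallow_fraction <= 0 || shallow_fraction > 1) {
    stop("diffusion_config: shallow_fraction must be in (0, 1]")
  }
  beta <- if (T == 1L) beta_min else seq(beta_min, beta_max, length.out = T)
  alpha_bar <- cumprod(1 - beta)
  structure(
    list(T = T, beta = beta, alpha_bar = alpha_bar,
         epochs = epochs, learning_rate = learning_rate,
         patch_size = as.integer(patch_size), base_width = as.integer(base_width),
         shallow_fraction = shallow_fraction, augment = isTRUE(augment),
         batch_size = as.integer(batch_size)),
    class = "diffusion_config"
  )
}

#' Pipeline configuration
#'
#' Bundles the knobs of the full restoration pipeline. Defaults follow the
#' method's published operating point: singular-value ratio gate at 3,
#' diffusion length T = 200, neighbor-depth averaging over +/- 1 frame.
#'
#' @param lr_ratio_threshold gate on sigma1/sigma2 for the stripe
#'   denoiser; frames at or above it are filtered (`> 1`).
#' @param neighbor_avg_radius half-width (frames) of the uniform
#'   neighbor-depth averaging window (`>= 0`).
#' @param t_start_max cap on the noise-adaptive reverse-process entry
#'   step: after stripe removal and depth averaging the residual noise
#'   is modest, and entering the generative process too deep risks
#'   hallucinated structure (and costs compute linearly in the step).
#' @param diffusion a [diffusion_config()].
#' @param segmentation segmentation method tag, see [otsu_segment()].
#' @param morph_window,morph_stride cubic window side and stride (voxels)
#'   for the morphometry maps.
#' @param rng_seed integer seed propagated to all stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(lr_ratio_threshold = 3,
                            neighbor_avg_radius = 1L,
                            t_start_max = 15L,
                            diffusion = diffusion_config(),
                            segmentation = "global_otsu",
                            morph_window = 32L, morph_stride = 16L,
                            rng_seed = 1L) {
  if (!is.numeric(lr_ratio_threshold) || lr_ratio_threshold <= 1) {
    stop("pipeline_config: lr_ratio_threshold must be > 1")
  }
  neighbor_avg_radius <- as.integer(neighbor_avg_radius)
  if (neighbor_avg_radius < 0) stop("pipeline_config: neighbor_avg_radius must be >= 0")
  morph_window <- as.integer(morph_window); morph_stride <- as.integer(morph_stride)
  if (morph_window < 1L || morph_stride < 1L) {
    stop("pipeline_config: morphometry window and stride must be positive integers")
  }
  stopifnot(inherits(diffusion, "diffusion_config"))
  structure(
    list(lr_ratio_threshold = lr_ratio_threshold,
         neighbor_avg_radius = neighbor_avg_radius,
         t_start_max = as.integer(t_start_max),
         diffusion = diffusion,
         segmentation = segmentation,
         morph_window = morph_window, morph_stride = morph_stride,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Missing keys take the documented defaults; invalid values are reported
#' with their key path. An empty document yields the full default
#' configuration (ratio gate 3, T = 200).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` document.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_config: cannot read '%s'", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("load_config: document root must be a mapping")
  known_top <- c("lr_ratio_threshold", "neighbor_avg_radius", "t_start_max",
                 "segmentation", "morph_window", "morph_stride", "rng_seed",
                 "diffusion")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop(sprintf("load_config: unknown key(s): %s", paste(bad, collapse = ", ")))
  diff_args <- raw$diffusion %||% list()
  known_diff <- names(formals(diffusion_config))
  badd <- setdiff(names(diff_args), known_diff)
  if (length(badd)) stop(sprintf("load_config: unknown key(s): %s", paste0("diffusion.", badd, collapse = ", ")))
  diffusion <- tryCatch(
    do.call(diffusion_config, diff_args),
    error = function(e) stop(sprintf("load_config: diffusion: %s", conditionMessage(e)))
  )
  args <- raw[setdiff(names(raw), "diffusion")]
  args$diffusion <- diffusion
  tryCatch(
    do.call(pipeline_config, args),
    error = function(e) stop(sprintf("load_config: %s", conditionMessage(e)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed deterministically
#'
#' All stochastic operations take an explicit seed; nested stages derive
#' per-item seeds from the parent seed so that whole-pipeline runs are
#' bit-reproducible. Kept below 2^31 so the result is a valid R integer.
#'
#' @param seed parent integer seed.
#' @param ... integer offsets identifying the child stream.
#' @return integer child seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483647
  as.integer(h)
}

dv_log <- function(stage, ...) {
  msg <- paste0(...)
  if (isTRUE(getOption("deepvasc.verbose", FALSE))) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  invisible(NULL)
}
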