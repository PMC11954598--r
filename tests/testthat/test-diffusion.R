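test_that("shallow-side extraction draws only from the shallow fraction", {
  set.seed(1)
  vox <- array(runif(20 * 32 * 32), c(20, 32, 32))
  s <- image_stack(vox)
  cfg <- diffusion_config(T = 10, epochs = 1, patch_size = 16, shallow_fraction = 0.2)
  p <- extract_shallow_subvolumes(s, cfg, n_patches = 30, seed = 2)
  expect_true(all(attr(p, "frames_used") <= 4L))  # 20% of 20 frames
  expect_true(all(vapply(p, function(m) all(m >= 0 & m <= 1), logical(1))))
  # whole stack eligible at fraction 1
  cfg1 <- diffusion_config(T = 10, epochs = 1, patch_size = 16, shallow_fraction = 1)
  p1 <- extract_shallow_subvolumes(s, cfg1, n_patches = 200, seed = 3)
  expect_gt(max(attr(p1, "frames_used")), 4L)
  # determinism
  expect_identical(p, extract_shallow_subvolumes(s, cfg, n_patches = 30, seed = 2))
  # patch larger than frame is a config error
  cfgbig <- diffusion_config(T = 10, epochs = 1, patch_size = 64)
  expect_error(extract_shallow_subvolumes(s, cfgbig, seed = 1), "patch size")
})

test_that("augmentation yields the dihedral variants and respects flags", {
  set.seed(4)
  p <- list(matrix(runif(36), 6, 6))
  off <- augment_patches(p, flip = FALSE, rotate = FALSE, seed = 1)
  expect_identical(off, p)
  both <- augment_patches(p, flip = TRUE, rotate = TRUE, seed = 1)
  expect_length(both, 8L)
  # the 8 variants are distinct for a generic patch
  keys <- vapply(both, function(m) paste(round(m, 10), collapse = ","), character(1))
  expect_length(unique(keys), 8L)
  expect_identical(augment_patches(p, seed = 9), augment_patches(p, seed = 9))
})

test_that("the forward marginal matches its closed form", {
  cfg <- diffusion_config(T = 50, epochs = 1, patch_size = 8)
  x0 <- matrix(0.5, 8, 8)
  # identity limit: alpha_bar ~ 1 at t = 1
  set.seed(5)
  xt <- forward_diffuse(x0, 1, cfg)
  expect_lt(mean(abs(xt - x0)), 0.05)
  # zero signal: pure scaled noise
  eps <- matrix(rnorm(64), 8, 8)
  expect_equal(forward_diffuse(x0 * 0, 25, cfg, eps),
               sqrt(1 - cfg$alpha_bar[25]) * eps)
  expect_error(forward_diffuse(x0, 0, cfg), "range")
  expect_error(forward_diffuse(x0, 51, cfg), "range")
  # Monte-Carlo moments at t in {1, T/2, T}
  set.seed(6)
  for (t in c(1L, 25L, 50L)) {
    ab <- cfg$alpha_bar[t]
    n_draws <- 200                       # x 64 pixels = 12800 samples
    draws <- replicate(n_draws, forward_diffuse(x0, t, cfg))
    dev <- draws - sqrt(ab) * 0.5
    n_tot <- length(dev)
    se_mean <- sqrt(1 - ab) / sqrt(n_tot)
    expect_lt(abs(mean(dev)), 3 * se_mean)
    v <- mean(dev^2)
    se_var <- (1 - ab) * sqrt(2 / n_tot)  # var of chi^2-based estimator
    expect_lt(abs(v - (1 - ab)), 3 * se_var)
  }
})

test_that("a tiny training run reduces the loss deterministically", {
  set.seed(8)
  base <- matrix(0.2, 16, 16)
  base[6:10, ] <- 0.9
  patches <- lapply(1:6, function(i) pmin(pmax(base + 0.02 * matrix(rnorm(256), 16, 16), 0), 1))
  cfg <- diffusion_config(T = 10, epochs = 3, patch_size = 16, base_width = 2,
                          learning_rate = 5e-3, batch_size = 3)
  m1 <- train_diffusion(patches, cfg, seed = 11)
  expect_length(m1$loss_history, 3L)
  expect_lt(m1$loss_history[3], m1$loss_history[1])
  # identical seeds and configs give identical loss histories
  m2 <- train_diffusion(patches, cfg, seed = 11)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_error(train_diffusion(list(), cfg), "at least one")
})

test_that("checkpoints round-trip with bit-identical predictions", {
  cfg <- diffusion_config(T = 10, epochs = 1, patch_size = 16, base_width = 2)
  m <- train_diffusion(list(matrix(runif(256), 16, 16)), cfg, seed = 12)
  p <- withr::local_tempfile(fileext = ".rds")
  save_denoiser(m, p)
  m2 <- load_denoiser(p)
  x <- matrix(runif(256), 16, 16)
  expect_identical(unet_forward(x, 5L, m$params, m$spec)$y,
                   unet_forward(x, 5L, m2$params, m2$spec)$y)
  expect_error(load_denoiser(withr::local_tempfile(fileext = ".rds")))
})

test_that("reverse denoising is near-identity from a low entry step", {
  cfg <- diffusion_config(T = 50, epochs = 1, patch_size = 16, base_width = 2)
  # untrained model: zero-initialized output layer predicts zero noise,
  # so one step at t = 1 only rescales by 1/sqrt(1 - beta_1)
  m <- structure(list(params = unet_init(unet_spec(2L), seed = 1),
                      spec = unet_spec(2L), cfg = cfg,
                      loss_history = NA_real_, version = "deepvasc-ckpt-1"),
                 class = "denoiser_model")
  x <- matrix(runif(256, 0.2, 0.8), 16, 16)
  y <- reverse_denoise(x, m, t_start = 1, seed = 3)
  expect_lt(max(abs(y - x)) / max(x), 0.05)
  expect_error(reverse_denoise(x, m, t_start = 0, seed = 1), "range")
  # seeded twice: identical outputs
  y2 <- reverse_denoise(x, m, t_start = 5, seed = 4)
  y3 <- reverse_denoise(x, m, t_start = 5, seed = 4)
  expect_identical(y2, y3)
})

test_that("neighbor-depth averaging uses truncated uniform windows", {
  vox <- array(0, c(3, 4, 4))
  vox[1, , ] <- 1; vox[2, , ] <- 4; vox[3, , ] <- 7
  s <- image_stack(vox)
  a <- neighbor_depth_average(s, radius = 1)
  expect_equal(unique(as.numeric(a$voxels[1, , ])), 2.5)  # (1+4)/2 at the edge
  expect_equal(unique(as.numeric(a$voxels[2, , ])), 4)    # (1+4+7)/3
  expect_identical(neighbor_depth_average(s, 0)$voxels, vox)
})

test_that("the enhancement pipeline is seed-reproducible end to end", {
  ph <- generate_vessels(small_phantom_cfg(), seed = 21)
  noised <- degrade(ph$clean, ph$truth, degradation_config(), seed = 22)
  dcfg <- diffusion_config(T = 20, epochs = 2, patch_size = 32, base_width = 2,
                           shallow_fraction = 0.25, augment = FALSE)
  cfg <- pipeline_config(diffusion = dcfg, t_start_max = 4L)
  model <- train_for_stack(noised, cfg, n_patches = 6, seed = 23)
  e1 <- lrdm_enhance(noised, model, cfg, seed = 24)
  e2 <- lrdm_enhance(noised, model, cfg, seed = 24)
  expect_identical(e1$voxels, e2$voxels)
  expect_true(all(is.finite(e1$voxels)) && all(e1$voxels >= 0))
  # stage intermediates are recorded on request
  e3 <- lrdm_enhance(noised, model, cfg, seed = 24, keep_stages = TRUE)
  st <- attr(e3, "stages")
  expect_named(st, c("lr", "averaged", "reports"))
  expect_length(st$reports, dim(noised)[1])
})
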