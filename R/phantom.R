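#' Vessel phantom configuration
#'
#' Describes a synthetic tubular vessel network inside a 3D volume. The
#' phantom stands in for *in vivo* vasculature: smooth random centerlines
#' swept with a circular cross-section, optional branching, bright tubes
#' on a dim uniform background.
#'
#' @param shape integer vector `(z, y, x)`; every dimension `>= 16`.
#' @param n_vessels number of root vessels (0 gives an empty phantom).
#' @param radius_range min/max tube radius in voxels (`>= 1`).
#' @param tortuosity curvature scale of the centerlines: standard
#'   deviation of the random direction perturbation per voxel travelled
#'   (0 gives straight tubes).
#' @param branching_prob probability of spawning a branch per voxel of
#'   centerline travelled.
#' @param vessel_intensity intensity of vessel voxels (relative units).
#' @param background_level intensity elsewhere; must be below
#'   `vessel_intensity`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(32L, 64L, 64L), n_vessels = 4L,
                           radius_range = c(2, 4), tortuosity = 0.15,
                           branching_prob = 0.02,
                           vessel_intensity = 1, background_level = 0.02) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (any(shape < 16L)) stop("phantom_config: every dimension must be >= 16")
  if (min(radius_range) < 1) stop("phantom_config: radii must be >= 1 voxel")
  if (!(vessel_intensity > background_level && background_level >= 0)) {
    stop("phantom_config: need vessel_intensity > background_level >= 0")
  }
  structure(
    list(shape = shape, n_vessels = as.integer(n_vessels),
         radius_range = sort(as.numeric(radius_range)),
         tortuosity = tortuosity, branching_prob = branching_prob,
         vessel_intensity = vessel_intensity, background_level = background_level),
    class = "phantom_config"
  )
}

#' Rasterize a capsule (tube segment) into a logical volume
#'
#' Marks every voxel whose center lies within `radius` of the segment
#' `p0`-`p1` (a capsule: cylinder with hemispherical caps). Coordinates
#' are in voxel units, `(z, y, x)`, voxel centers at integers starting
#' at 1. Exact by construction: each candidate voxel's distance to the
#' segment is evaluated directly.
#'
#' @param vol logical 3D array to update (modified copy returned).
#' @param p0,p1 numeric length-3 segment endpoints `(z, y, x)`.
#' @param radius capsule radius in voxels.
#' @return The updated logical array.
#' @export
rasterize_capsule <- function(vol, p0, p1, radius) {
  d <- dim(vol)
  lo <- pmax(floor(pmin(p0, p1) - radius), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + radius), d)
  if (any(lo > hi)) return(vol)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  seg <- p1 - p0
  len2 <- sum(seg^2)
  # voxel center coordinates of the bounding box, one row per voxel
  g <- as.matrix(expand.grid(z = zs, y = ys, x = xs))
  rel <- sweep(g, 2, p0)
  t <- if (len2 > 0) pmin(pmax(rel %*% seg / len2, 0), 1) else matrix(0, nrow(g), 1)
  dist2 <- rowSums((rel - t %*% t(seg))^2)
  inside <- dist2 <= radius^2
  if (any(inside)) {
    idx <- g[inside, , drop = FALSE]
    vol[idx[, c("z", "y", "x"), drop = FALSE]] <- TRUE
  }
  vol
}

# one random smooth centerline; returns list of (points matrix, radius) plus
# branch seeds (position, direction, radius) emitted along the way
trace_centerline <- function(shape, start, direction, radius, tortuosity,
                             branching_prob, step = 1.0) {
  max_steps <- ceiling(3 * sqrt(sum(shape^2)) / step)
  pts <- matrix(NA_real_, max_steps + 1L, 3L)
  pts[1L, ] <- start
  dirn <- direction / sqrt(sum(direction^2))
  branches <- list()
  n <- 1L
  for (i in seq_len(max_steps)) {
    dirn <- dirn + tortuosity * sqrt(step) * stats::rnorm(3)
    dirn <- dirn / sqrt(sum(dirn^2))
    p <- pts[n, ] + step * dirn
    if (any(p < 1 - radius) || any(p > shape + radius)) break
    n <- n + 1L
    pts[n, ] <- p
    if (stats::runif(1) < branching_prob * step && radius > 1.5) {
      perp <- stats::rnorm(3)
      perp <- perp - sum(perp * dirn) * dirn
      perp <- perp / sqrt(sum(perp^2))
      bd <- 0.6 * dirn + 0.8 * perp
      branches[[length(branches) + 1L]] <-
        list(start = p, direction = bd / sqrt(sum(bd^2)), radius = max(1, 0.75 * radius))
    }
  }
  list(points = pts[seq_len(n), , drop = FALSE], radius = radius, branches = branches)
}

#' Generate a synthetic vessel phantom
#'
#' Sweeps tubes of random radius along smooth random centerlines (with
#' optional branches) through the volume. The truth mask is the exact
#' union of capsules around consecutive centerline samples; the clean
#' stack carries `vessel_intensity` on truth voxels and
#' `background_level` elsewhere.
#'
#' @param cfg a [phantom_config()].
#' @param seed integer RNG seed; equal seeds give identical phantoms.
#' @param z_step depth increment in micrometres for the returned stack.
#' @return list with `clean` (an [image_stack]) and `truth`
#'   (a [mask_volume] of role `vessel_truth`).
#' @export
generate_vessels <- function(cfg, seed = 1L, z_step = 2) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(as.integer(seed))
  shape <- cfg$shape
  truth <- array(FALSE, dim = shape)
  if (cfg$n_vessels == 0L) {
    warning("generate_vessels: zero vessels requested; returning empty phantom")
  } else {
    queue <- list()
    for (v in seq_len(cfg$n_vessels)) {
      # enter through a random face, heading inward
      face <- sample.int(6L, 1L)
      ax <- ((face - 1L) %/% 2L) + 1L
      at_min <- face %% 2L == 1L
      start <- stats::runif(3, 1, shape)
      start[ax] <- if (at_min) 1 else shape[ax]
      dirn <- stats::rnorm(3)
      dirn[ax] <- abs(dirn[ax]) * (if (at_min) 1 else -1) + (if (at_min) 1 else -1)
      radius <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
      queue[[length(queue) + 1L]] <- list(start = start, direction = dirn, radius = radius)
    }
    max_segments <- 4L * cfg$n_vessels  # cap total branches
    drawn <- 0L
    while (length(queue) > 0L && drawn < max_segments) {
      job <- queue[[1L]]; queue[[1L]] <- NULL
      drawn <- drawn + 1L
      cl <- trace_centerline(shape, job$start, job$direction, job$radius,
                             cfg$tortuosity, cfg$branching_prob)
      pts <- cl$points
      if (nrow(pts) >= 2L) {
        for (i in seq_len(nrow(pts) - 1L)) {
          truth <- rasterize_capsule(truth, pts[i, ], pts[i + 1L, ], cl$radius)
        }
      } else if (nrow(pts) == 1L) {
        truth <- rasterize_capsule(truth, pts[1L, ], pts[1L, ], cl$radius)
      }
      queue <- c(queue, cl$branches)
    }
  }
  clean <- array(cfg$background_level, dim = shape)
  clean[truth] <- cfg$vessel_intensity
  list(
    clean = image_stack(clean, z_step = z_step),
    truth = mask_volume(truth, role = "vessel_truth")
  )
}

#' Degradation configuration
#'
#' The depth-imaging degradation model applied to clean phantoms: signal
#' attenuation with depth, a diffuse scattering glow, line-wise periodic
#' stripe (ripple) noise, photon shot noise and Gaussian readout noise —
#' a mixture of structured and random noise.
#'
#' @param attenuation_length exponential decay length of the signal with
#'   depth, in micrometres (`Inf` disables attenuation).
#' @param psf_sigma Gaussian blur of the signal itself, in voxels.
#' @param scatter_sigma blur radius (voxels) of the diffuse scattering
#'   glow around bright structures.
#' @param scatter_fraction strength of the glow relative to the
#'   (attenuated) signal.
#' @param stripe_amplitude amplitude of the line-wise stripe field
#'   (relative units); the field is constant along x within each line y.
#' @param stripe_period stripe period in lines.
#' @param stripe_jitter phase jitter in `[0, 1]`: 0 locks the phase
#'   across frames, 1 draws a fresh uniform phase per frame.
#' @param stripe_waveform `"sine"` (default) or `"square"`.
#' @param photon_scale expected detected photons per unit intensity for
#'   the shot-noise stage (0 disables shot noise). The stage is
#'   mean-preserving: `E[out] = in`.
#' @param readout_sigma standard deviation of additive Gaussian readout
#'   noise (relative units).
#' @param target_sbr optional: if set, a single global multiplier on the
#'   noise amplitudes (stripes and readout noise) is solved by bisection
#'   so the measured SBR of the output is within 5% of this value.
#' @return An object of class `degradation_config`.
#' @export
degradation_config <- function(attenuation_length = 50,
                               psf_sigma = 0.5,
                               scatter_sigma = 4, scatter_fraction = 0.5,
                               stripe_amplitude = 0.5, stripe_period = 8,
                               stripe_jitter = 1, stripe_waveform = c("sine", "square"),
                               photon_scale = 30, readout_sigma = 0.05,
                               target_sbr = NULL) {
  stripe_waveform <- match.arg(stripe_waveform)
  vals <- c(psf_sigma, scatter_sigma, scatter_fraction, stripe_amplitude,
            stripe_period, photon_scale, readout_sigma)
  if (any(vals < 0)) stop("degradation_config: scales and amplitudes must be >= 0")
  if (!(attenuation_length > 0)) stop("degradation_config: attenuation_length must be > 0")
  if (stripe_jitter < 0 || stripe_jitter > 1) stop("degradation_config: stripe_jitter in [0,1]")
  if (!is.null(target_sbr) && target_sbr <= 0) stop("degradation_config: target_sbr must be > 0")
  structure(
    list(attenuation_length = attenuation_length, psf_sigma = psf_sigma,
         scatter_sigma = scatter_sigma, scatter_fraction = scatter_fraction,
         stripe_amplitude = stripe_amplitude, stripe_period = stripe_period,
         stripe_jitter = stripe_jitter, stripe_waveform = stripe_waveform,
         photon_scale = photon_scale, readout_sigma = readout_sigma,
         target_sbr = target_sbr),
    class = "degradation_config"
  )
}

# core degradation pass; `mult` scales the additive noise amplitudes
# (stripes and readout noise; the scattering glow is part of the optical
# degradation, not of the detector noise)
degrade_once <- function(clean, cfg, seed, mult = 1) {
  set.seed(as.integer(seed))
  vox <- clean$voxels
  d <- dim(vox)
  depths <- frame_depths(clean)
  out <- array(0, dim = d)
  for (k in seq_len(d[1])) {
    fr <- matrix(vox[k, , ], d[2], d[3])
    att <- if (is.finite(cfg$attenuation_length)) exp(-depths[k] / cfg$attenuation_length) else 1
    fr <- fr * att
    if (cfg$psf_sigma > 0) fr <- ebimage_blur(fr, cfg$psf_sigma)
    if (cfg$scatter_fraction > 0 && cfg$scatter_sigma > 0) {
      glow <- ebimage_blur(fr, cfg$scatter_sigma)
      fr <- fr + cfg$scatter_fraction * glow
    }
    if (cfg$stripe_amplitude > 0) {
      phase <- 2 * pi * cfg$stripe_jitter * stats::runif(1)
      arg <- 2 * pi * seq_len(d[2]) / cfg$stripe_period + phase
      s <- if (cfg$stripe_waveform == "sine") sin(arg) else sign(sin(arg))
      fr <- fr + mult * cfg$stripe_amplitude * s  # constant across x per line y
    }
    if (cfg$photon_scale > 0) {
      lam <- pmax(fr, 0) * cfg$photon_scale
      fr <- matrix(stats::rpois(length(lam), lam), d[2], d[3]) / cfg$photon_scale
    }
    if (cfg$readout_sigma > 0) {
      fr <- fr + mult * cfg$readout_sigma * stats::rnorm(length(fr))
    }
    out[k, , ] <- pmax(fr, 0)
  }
  image_stack(out, z_step = clean$z_step, z0_depth = clean$z0_depth)
}

ebimage_blur <- function(frame, sigma) {
  # EBImage images are (x, y); transpose in and out
  as.matrix(t(EBImage::gblur(t(frame), sigma = sigma, boundary = "replicate")))
}

#' Degrade a clean phantom with structured plus random noise
#'
#' Applies, per frame at depth z: exponential attenuation
#' `exp(-z / attenuation_length)`, signal blur, a diffuse scattering glow
#' (`scatter_fraction` times a widely blurred copy of the signal), a
#' line-wise periodic stripe field added identically across x within each
#' line y, photon shot noise (Poisson with mean `photon_scale *`
#' intensity, rescaled so the stage is mean-preserving), Gaussian readout
#' noise, and clipping at zero. If `cfg$target_sbr` is set, the additive
#' noise components are jointly scaled by bisection until the measured
#' SBR of the output is within 5% of the target.
#'
#' @param clean clean [image_stack].
#' @param truth co-registered vessel-truth [mask_volume] (used for SBR
#'   targeting and available for evaluation).
#' @param cfg a [degradation_config()].
#' @param seed integer RNG seed.
#' @return The degraded [image_stack]. When SBR targeting is active, the
#'   achieved SBR and the multiplier are attached as attributes
#'   `achieved_sbr` and `noise_multiplier`.
#' @export
degrade <- function(clean, truth, cfg, seed = 1L) {
  stopifnot(inherits(clean, "image_stack"), inherits(cfg, "degradation_config"))
  check_coregistered(clean, truth, "clean stack and truth mask")
  if (is.null(cfg$target_sbr)) {
    return(degrade_once(clean, cfg, seed))
  }
  masks <- sbr_masks_from_truth(truth)
  eval_sbr <- function(m) {
    s <- degrade_once(clean, cfg, seed, mult = m)
    sbr(s, masks$signal, masks$background)
  }
  target <- cfg$target_sbr
  base <- eval_sbr(0)
  if (base < target) {
    stop(sprintf("degrade: target_sbr %.3g unreachable (noise-free SBR is %.3g)", target, base))
  }
  lo <- 0; hi <- 1
  repeat {
    v <- eval_sbr(hi)
    # SBR approaches an asymptote slightly above 1 as the noise dominates
    # both masks; accept once the target is bracketed or nearly reached
    if (v <= target || abs(v - target) / target < 0.04) break
    lo <- hi; hi <- hi * 2
    if (hi > 1e6) stop("degrade: SBR targeting failed to bracket the target")
  }
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    v <- eval_sbr(mid)
    if (v > target) lo <- mid else hi <- mid
    if (abs(v - target) / target < 0.01) { lo <- hi <- mid; break }
  }
  m <- (lo + hi) / 2
  out <- degrade_once(clean, cfg, seed, mult = m)
  attr(out, "achieved_sbr") <- sbr(out, masks$signal, masks$background)
  attr(out, "noise_multiplier") <- m
  out
}

#' Generate a paired clean/degraded phantom dataset
#'
#' Produces `n_volumes` independent phantom volumes, each generated and
#' degraded under a per-volume seed derived deterministically from the
#' top-level seed, and (optionally) writes them to disk alongside a JSON
#' manifest recording configurations and seeds. Re-running with the same
#' seed reproduces the dataset bit-identically.
#'
#' @param phantom_cfg a [phantom_config()].
#' @param degrade_cfg a [degradation_config()].
#' @param n_volumes number of volumes (`>= 1`).
#' @param seed top-level integer seed.
#' @param out_dir optional output directory; when `NULL` the dataset is
#'   returned in memory only.
#' @return list of triples, each with `clean`, `noised`, `truth`, `seed`;
#'   attribute `manifest` holds the manifest (also written to
#'   `manifest.json` when `out_dir` is given).
#' @export
make_paired_dataset <- function(phantom_cfg, degrade_cfg, n_volumes, seed = 1L,
                                out_dir = NULL) {
  stopifnot(n_volumes >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  triples <- vector("list", n_volumes)
  entries <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    s_gen <- derive_seed(seed, i, 1L)
    s_deg <- derive_seed(seed, i, 2L)
    ph <- generate_vessels(phantom_cfg, seed = s_gen)
    noised <- degrade(ph$clean, ph$truth, degrade_cfg, seed = s_deg)
    triples[[i]] <- list(clean = ph$clean, noised = noised, truth = ph$truth,
                         seed = c(generate = s_gen, degrade = s_deg))
    entry <- list(index = i, seed_generate = s_gen, seed_degrade = s_deg)
    if (!is.null(out_dir)) {
      fc <- file.path(out_dir, sprintf("clean_%03d.tif", i))
      fn <- file.path(out_dir, sprintf("noised_%03d.tif", i))
      ft <- file.path(out_dir, sprintf("truth_%03d.tif", i))
      write_stack(ph$clean, fc)
      write_stack(noised, fn)
      write_mask(ph$truth, ft)
      entry <- c(entry, list(clean = basename(fc), noised = basename(fn), truth = basename(ft)))
    }
    entries[[i]] <- entry
  }
  manifest <- list(
    n_volumes = n_volumes, seed = seed,
    phantom_config = unclass(phantom_cfg),
    degradation_config = unclass(degrade_cfg)[!vapply(unclass(degrade_cfg), is.null, logical(1))],
    volumes = entries
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(triples, "manifest") <- manifest
  triples
}
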