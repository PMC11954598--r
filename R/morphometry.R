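#' Segment vessels by Otsu-type thresholding
#'
#' Thresholds every frame of a stack independently. Three methods:
#' \describe{
#'   \item{`global_otsu`}{classic Otsu threshold (maximum between-class
#'     variance on the frame histogram).}
#'   \item{`proportion_adjusted`}{Otsu threshold, then adjusted so the
#'     foreground fraction falls inside a plausible vessel-fraction band
#'     (default 1-20%): if the Otsu mask is larger/smaller than the band
#'     the threshold moves to the corresponding intensity quantile.}
#'   \item{`weighted_optimal`}{exhaustive threshold sweep maximizing
#'     normalized between-class variance plus a Gaussian prior on the
#'     foreground fraction (weight `w_prior`, prior `prior_frac` with
#'     spread `prior_sd`).}
#' }
#' The two adjusted variants are parameterized reconstructions of
#' common practice for sparse tubular foregrounds; all knobs are
#' exposed.
#'
#' @param x an [image_stack] or a single frame matrix.
#' @param method segmentation method tag.
#' @param band foreground-fraction band for `proportion_adjusted`.
#' @param prior_frac,prior_sd,w_prior prior on the vessel fraction for
#'   `weighted_optimal`.
#' @param n_levels candidate thresholds for the sweep.
#' @return A [mask_volume] of role `vessel_truth`; per-frame thresholds
#'   in attribute `thresholds`. A constant frame gives an empty mask
#'   with a warning.
#' @export
otsu_segment <- function(x, method = c("global_otsu", "proportion_adjusted", "weighted_optimal"),
                         band = c(0.01, 0.20), prior_frac = 0.08, prior_sd = 0.06,
                         w_prior = 0.5, n_levels = 256L) {
  method <- match.arg(method)
  vox <- as_voxels(x)
  if (is.matrix(vox)) vox <- array(vox, c(1L, dim(vox)))
  if (!all(is.finite(vox))) stop("otsu_segment: non-finite intensities")
  d <- dim(vox)
  hi <- max(vox); lo <- min(vox)
  rng <- if (hi > lo) hi - lo else 1
  out <- array(FALSE, d)
  thresholds <- numeric(d[1])
  for (k in seq_len(d[1])) {
    fr <- matrix(vox[k, , ], d[2], d[3])
    if (max(fr) == min(fr)) {
      warning(sprintf("otsu_segment: frame %d is constant; empty mask", k))
      thresholds[k] <- NA_real_
      next
    }
    fr01 <- (fr - lo) / rng
    thr <- switch(method,
      global_otsu = EBImage::otsu(t(fr01), range = c(0, 1), levels = n_levels),
      proportion_adjusted = {
        t0 <- EBImage::otsu(t(fr01), range = c(0, 1), levels = n_levels)
        frac <- mean(fr01 > t0)
        if (frac > band[2]) stats::quantile(fr01, 1 - band[2], names = FALSE)
        else if (frac < band[1]) stats::quantile(fr01, 1 - band[1], names = FALSE)
        else t0
      },
      weighted_optimal = {
        cands <- seq(min(fr01), max(fr01), length.out = n_levels + 2L)
        cands <- cands[-c(1L, length(cands))]
        tot_var <- stats::var(as.numeric(fr01)) * (length(fr01) - 1) / length(fr01)
        best <- cands[1]; best_score <- -Inf
        mu <- mean(fr01)
        for (tc in cands) {
          w1 <- mean(fr01 > tc)
          if (w1 == 0 || w1 == 1) next
          mu1 <- mean(fr01[fr01 > tc]); mu0 <- mean(fr01[fr01 <= tc])
          sb2 <- w1 * (1 - w1) * (mu1 - mu0)^2
          score <- sb2 / tot_var + w_prior * exp(-(w1 - prior_frac)^2 / (2 * prior_sd^2))
          if (score > best_score) { best_score <- score; best <- tc }
        }
        best
      }
    )
    out[k, , ] <- fr01 > thr
    thresholds[k] <- thr * rng + lo
  }
  m <- mask_volume(out, role = "vessel_truth")
  attr(m, "thresholds") <- thresholds
  attr(m, "method") <- method
  m
}

#' 3D medial-axis skeletonization
#'
#' Topology-preserving iterative thinning (sequential deletion of simple
#' border points from the six cardinal directions; curve end points are
#' kept), reducing a binary vessel volume to a 1-voxel-wide curve
#' skeleton. The skeleton is a subset of the input and each connected
#' component stays connected.
#'
#' @param A binary vessel volume ([mask_volume] or logical array).
#' @return logical array of the same shape (the skeleton `S`).
#' @export
skeletonize <- function(A) {
  v <- as_voxels(A)
  storage.mode(v) <- "logical"
  d <- dim(v)
  .thin3d_cpp(as.vector(v), as.integer(d))
}

#' Extract the vessel surface voxels
#'
#' A surface voxel is a vessel voxel with at least one 6-connected
#' face-neighbor outside the vessel volume; the volume border counts as
#' outside.
#'
#' @param A binary vessel volume.
#' @return logical array `P` of the same shape, `P` a subset of `A`.
#' @export
surface_extract <- function(A) {
  v <- as_voxels(A)
  storage.mode(v) <- "logical"
  d <- dim(v)
  # interior = all six face neighbors inside A (borders padded FALSE)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- v
  i <- 2:(d[1] + 1L); j <- 2:(d[2] + 1L); k <- 2:(d[3] + 1L)
  interior <- pad[i - 1L, j, k] & pad[i + 1L, j, k] &
              pad[i, j - 1L, k] & pad[i, j + 1L, k] &
              pad[i, j, k - 1L] & pad[i, j, k + 1L]
  v & !interior
}

#' Bundle vessel volume, skeleton and surface
#'
#' @param A binary vessel volume.
#' @param S optional skeleton (computed with [skeletonize()] if `NULL`).
#' @param P optional surface (computed with [surface_extract()] if
#'   `NULL`).
#' @return An object of class `label_volumes` with logical arrays `A`,
#'   `S`, `P`; invariants (`S` and `P` subsets of `A`, every surface
#'   voxel face-adjacent to outside) are asserted.
#' @export
label_volumes <- function(A, S = NULL, P = NULL) {
  Av <- as_voxels(A); storage.mode(Av) <- "logical"
  Sv <- if (is.null(S)) skeletonize(Av) else as_voxels(S)
  Pv <- if (is.null(P)) surface_extract(Av) else as_voxels(P)
  storage.mode(Sv) <- "logical"; storage.mode(Pv) <- "logical"
  check_coregistered(Av, Sv); check_coregistered(Av, Pv)
  if (any(Sv & !Av)) stop("label_volumes: skeleton is not a subset of the vessel volume")
  if (any(Pv & !Av)) stop("label_volumes: surface is not a subset of the vessel volume")
  structure(list(A = Av, S = Sv, P = Pv), class = "label_volumes")
}

# zero-padded 3D summed-volume table; window sums in O(1)
svt <- function(m) {
  m <- apply(m, c(2, 3), cumsum)
  m <- aperm(apply(m, c(1, 3), cumsum), c(2, 1, 3))
  m <- aperm(apply(m, c(1, 2), cumsum), c(2, 3, 1))
  d <- dim(m)
  out <- array(0, d + 1L)
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  out
}

svt_window_sum <- function(S, z0, y0, x0, n) {
  # sum over [z0..z0+n-1] x [y0..y0+n-1] x [x0..x0+n-1] (1-based starts)
  z1 <- z0 + n; y1 <- y0 + n; x1 <- x0 + n
  S[z1, y1, x1] - S[z0, y1, x1] - S[z1, y0, x1] - S[z1, y1, x0] +
    S[z0, y0, x1] + S[z0, y1, x0] + S[z1, y0, x0] - S[z0, y0, x0]
}

#' Voxel-wise 3D vascular morphometry maps
#'
#' Evaluates the five metrics in sliding cubic windows of side `n` on a
#' stride grid. Per window, with `sum_A`, `sum_S`, `sum_P` the vessel,
#' skeleton and surface voxel counts:
#' \describe{
#'   \item{VVD}{`sum_A / n^3` — vessel volume density.}
#'   \item{VTI}{`sum_A / sum_S` — vessel thickness index (diameter
#'     proxy; undefined when the window holds no skeleton).}
#'   \item{VSD}{`sum_S / n^3` — skeleton density (network density).}
#'   \item{VCI}{`(sum_P)^2 / (4 pi sum_A)` — complexity index
#'     (irregularity; undefined when the window holds no vessel).}
#'   \item{VSI}{`sum_P / n^3` — surface-area index (exchange
#'     efficiency).}
#' }
#' Undefined windows are `NA` (flagged, never zero-imputed).
#'
#' @param labels a [label_volumes()].
#' @param n cubic window side in voxels (`<=` the smallest dimension).
#' @param stride grid stride in voxels (default `n / 2`).
#' @param z_step,z0_depth physical depth calibration of the underlying
#'   stack, used to report window-center depths.
#' @return An object of class `metric_maps`: arrays `VVD`, `VTI`,
#'   `VSD`, `VCI`, `VSI` on the window grid, plus `window`, `stride`,
#'   `starts` (per-axis window start indices) and `depths` (window
#'   center depth per grid layer, micrometres).
#' @export
window_metrics <- function(labels, n = 32L, stride = max(1L, n %/% 2L),
                           z_step = 1, z0_depth = 0) {
  stopifnot(inherits(labels, "label_volumes"))
  n <- as.integer(n); stride <- as.integer(stride)
  d <- dim(labels$A)
  if (n < 1L || stride < 1L) stop("window_metrics: window and stride must be positive")
  if (n > min(d)) stop("window_metrics: window exceeds the smallest volume dimension")
  SA <- svt(labels$A * 1); SS <- svt(labels$S * 1); SP <- svt(labels$P * 1)
  starts <- lapply(d, function(dd) seq(1L, dd - n + 1L, by = stride))
  g <- lengths(starts)
  mk <- function() array(NA_real_, g)
  VVD <- mk(); VTI <- mk(); VSD <- mk(); VCI <- mk(); VSI <- mk()
  n3 <- as.numeric(n)^3
  for (iz in seq_len(g[1])) for (iy in seq_len(g[2])) for (ix in seq_len(g[3])) {
    z0 <- starts[[1]][iz]; y0 <- starts[[2]][iy]; x0 <- starts[[3]][ix]
    sA <- svt_window_sum(SA, z0, y0, x0, n)
    sS <- svt_window_sum(SS, z0, y0, x0, n)
    sP <- svt_window_sum(SP, z0, y0, x0, n)
    VVD[iz, iy, ix] <- sA / n3
    VSD[iz, iy, ix] <- sS / n3
    VSI[iz, iy, ix] <- sP / n3
    if (sS > 0) VTI[iz, iy, ix] <- sA / sS
    if (sA > 0) VCI[iz, iy, ix] <- sP^2 / (4 * pi * sA)
  }
  depths <- z0_depth + (starts[[1]] - 1 + (n - 1) / 2) * z_step
  structure(
    list(VVD = VVD, VTI = VTI, VSD = VSD, VCI = VCI, VSI = VSI,
         window = n, stride = stride, starts = starts, depths = depths),
    class = "metric_maps"
  )
}

metric_names <- function() c("VVD", "VTI", "VSD", "VCI", "VSI")

#' @export
print.metric_maps <- function(x, ...) {
  g <- dim(x$VVD)
  cat(sprintf("<metric_maps> %d x %d x %d windows (side %d, stride %d)\n",
              g[1], g[2], g[3], x$window, x$stride))
  for (m in metric_names()) {
    v <- x[[m]]
    cat(sprintf("  %s: mean %.4g over %d defined window(s)\n",
                m, mean(v, na.rm = TRUE), sum(!is.na(v))))
  }
  invisible(x)
}

#' Depth profiles and distribution histograms of metric maps
#'
#' Per grid depth layer, the mean of each metric over its defined
#' windows (layers with no defined window appear as `NA` gaps, not
#' zeros), plus a distribution histogram per metric over all defined
#' windows.
#'
#' @param maps a [window_metrics()] result.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list with `profiles` (data.frame `metric`, `depth_um`,
#'   `mean`, `n_defined`) and `histograms` (named list of histogram
#'   objects).
#' @export
depth_profiles <- function(maps, breaks = 20) {
  stopifnot(inherits(maps, "metric_maps"))
  g <- dim(maps$VVD)
  prof <- do.call(rbind, lapply(metric_names(), function(m) {
    vals <- maps[[m]]
    data.frame(
      metric = m,
      depth_um = maps$depths,
      mean = vapply(seq_len(g[1]), function(iz) {
        v <- vals[iz, , ]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1)),
      n_defined = vapply(seq_len(g[1]), function(iz) sum(!is.na(vals[iz, , ])), numeric(1))
    )
  }))
  hists <- lapply(stats::setNames(metric_names(), metric_names()), function(m) {
    v <- maps[[m]][!is.na(maps[[m]])]
    if (length(v) == 0) NULL else graphics::hist(v, breaks = breaks, plot = FALSE)
  })
  list(profiles = prof, histograms = hists)
}

#' Dispersion statistics: CV, MCV and DMCV
#'
#' The coefficient of variation (CV = sd/mean) of each metric over the
#' defined windows of each grid depth layer quantifies vascular
#' heterogeneity; the mean CV over a region's layers (MCV) summarizes a
#' region, and the absolute MCV difference between adjacent regions
#' (DMCV) localizes architectural transitions.
#'
#' @param maps a [window_metrics()] result.
#' @param region_labels region label per grid depth layer (character or
#'   factor vector, length `dim(maps$VVD)[1]`).
#' @return An object of class `dispersion_stats`: `cv` (per metric and
#'   layer; `NA` where undefined or zero-mean), `mcv` (per metric and
#'   region), `dmcv` (per metric and adjacent region pair).
#' @export
dispersion <- function(maps, region_labels) {
  stopifnot(inherits(maps, "metric_maps"))
  g <- dim(maps$VVD)
  region_labels <- as.character(region_labels)
  if (length(region_labels) != g[1]) {
    stop("dispersion: need one region label per grid depth layer")
  }
  cv <- do.call(rbind, lapply(metric_names(), function(m) {
    vals <- maps[[m]]
    data.frame(
      metric = m, depth_um = maps$depths, region = region_labels,
      cv = vapply(seq_len(g[1]), function(iz) {
        v <- vals[iz, , ]; v <- v[!is.na(v)]
        if (length(v) < 2L) return(NA_real_)
        mu <- mean(v)
        if (mu == 0) return(NA_real_)
        stats::sd(v) / mu
      }, numeric(1))
    )
  }))
  regions <- unique(region_labels)
  mcv <- do.call(rbind, lapply(metric_names(), function(m) {
    do.call(rbind, lapply(regions, function(r) {
      v <- cv$cv[cv$metric == m & cv$region == r]
      data.frame(metric = m, region = r, mcv = mean(v, na.rm = TRUE))
    }))
  }))
  pairs <- if (length(regions) >= 2L) {
    do.call(rbind, lapply(seq_len(length(regions) - 1L), function(i) {
      data.frame(region_a = regions[i], region_b = regions[i + 1L])
    }))
  } else {
    data.frame(region_a = character(0), region_b = character(0))
  }
  dmcv <- do.call(rbind, lapply(metric_names(), function(m) {
    if (nrow(pairs) == 0L) return(NULL)
    cbind(metric = m, pairs,
          dmcv = vapply(seq_len(nrow(pairs)), function(i) {
            a <- mcv$mcv[mcv$metric == m & mcv$region == pairs$region_a[i]]
            b <- mcv$mcv[mcv$metric == m & mcv$region == pairs$region_b[i]]
            abs(a - b)
          }, numeric(1)))
  }))
  structure(list(cv = cv, mcv = mcv, dmcv = dmcv), class = "dispersion_stats")
}

#' Inter-metric correlation screen
#'
#' Pearson correlation of the five metrics over windows where all five
#' are defined. Metric pairs with `|r| >= 0.7` are flagged as
#' non-independent (they carry largely redundant information).
#'
#' @param maps a [window_metrics()] result.
#' @param r_threshold independence threshold on `|r|`.
#' @return list with `r` (5 x 5 correlation matrix), `dependent`
#'   (logical matrix flagging `|r| >= r_threshold`), `n` (windows used).
#' @export
metric_correlation <- function(maps, r_threshold = 0.7) {
  stopifnot(inherits(maps, "metric_maps"))
  M <- sapply(metric_names(), function(m) as.numeric(maps[[m]]))
  keep <- stats::complete.cases(M)
  if (sum(keep) < 3L) stop("metric_correlation: fewer than 3 fully defined windows")
  r <- stats::cor(M[keep, , drop = FALSE])
  list(r = r, dependent = abs(r) >= r_threshold, n = sum(keep))
}

#' Per-region metric summaries and group comparisons
#'
#' Summarizes each metric per region (mean, sd, min-max normalized mean
#' for radar display) and tests for between-region differences: one-way
#' ANOVA with post-hoc Tukey HSD for 3+ regions, Welch t-test for 2.
#' Degenerate groups (fewer than 2 values, or zero variance everywhere)
#' skip the test with a warning.
#'
#' @param maps a [window_metrics()] result.
#' @param region_labels region label per grid depth layer.
#' @return list with `summary` (data.frame `metric`, `region`, `mean`,
#'   `sd`, `n`, `norm_mean`), `tests` (per metric: ANOVA F and p, Tukey
#'   pairwise p-values or t-test p).
#' @export
region_stats <- function(maps, region_labels) {
  stopifnot(inherits(maps, "metric_maps"))
  g <- dim(maps$VVD)
  region_labels <- as.character(region_labels)
  if (length(region_labels) != g[1]) stop("region_stats: need one region label per grid depth layer")
  long <- do.call(rbind, lapply(metric_names(), function(m) {
    vals <- maps[[m]]
    do.call(rbind, lapply(seq_len(g[1]), function(iz) {
      v <- vals[iz, , ]; v <- v[!is.na(v)]
      if (length(v) == 0L) return(NULL)
      data.frame(metric = m, region = region_labels[iz], value = v)
    }))
  }))
  summ <- do.call(rbind, lapply(split(long, long[c("metric", "region")]), function(gr) {
    if (nrow(gr) == 0L) return(NULL)
    data.frame(metric = gr$metric[1], region = gr$region[1],
               mean = mean(gr$value), sd = stats::sd(gr$value), n = nrow(gr))
  }))
  rownames(summ) <- NULL
  summ$norm_mean <- NA_real_
  for (m in unique(summ$metric)) {
    idx <- summ$metric == m
    v <- summ$mean[idx]
    summ$norm_mean[idx] <- if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else 0.5
  }
  tests <- lapply(stats::setNames(metric_names(), metric_names()), function(m) {
    gr <- long[long$metric == m, ]
    counts <- table(gr$region)
    if (length(counts) < 2L || any(counts < 2L)) {
      warning(sprintf("region_stats: %s has degenerate groups; test skipped", m))
      return(NULL)
    }
    if (length(counts) == 2L) {
      tt <- stats::t.test(value ~ region, data = gr)
      list(type = "t_test", statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      if (stats::var(gr$value) == 0) {
        return(list(type = "anova", F = 0, p = 1, tukey = NULL))
      }
      fit <- stats::aov(value ~ region, data = gr)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$region
      list(type = "anova", F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
           tukey = tk[, "p adj", drop = FALSE])
    }
  })
  list(summary = summ, tests = tests)
}
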