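test_that("surface extraction matches voxel enumeration", {
  # solid 10^3 block inside a larger volume: 10^3 - 8^3 = 488 surface voxels
  b <- array(FALSE, c(14, 14, 14)); b[3:12, 3:12, 3:12] <- TRUE
  P <- surface_extract(b)
  expect_equal(sum(P), 488)
  # oracle: direct per-voxel check of the six face neighbors
  oracle <- array(FALSE, dim(b))
  at <- function(z, y, x) {
    if (z < 1 || y < 1 || x < 1 || z > 14 || y > 14 || x > 14) FALSE else b[z, y, x]
  }
  for (z in 1:14) for (y in 1:14) for (x in 1:14) {
    if (b[z, y, x]) {
      nb <- c(at(z - 1, y, x), at(z + 1, y, x), at(z, y - 1, x),
              at(z, y + 1, x), at(z, y, x - 1), at(z, y, x + 1))
      oracle[z, y, x] <- any(!nb)
    }
  }
  expect_identical(P, oracle)
  # 3x3x3 block: everything but the center; single voxel: itself;
  # the volume border counts as outside
  s3 <- array(TRUE, c(3, 3, 3))
  expect_equal(sum(surface_extract(s3)), 26)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_identical(surface_extract(one), one)
  full <- array(TRUE, c(4, 4, 4))
  expect_equal(sum(surface_extract(full)), 4^3 - 2^3)
})

test_that("skeletonization thins a tube to its medial axis", {
  v <- make_tube(c(24L, 17L, 17L), radius = 3, center = c(9, 9))
  S <- skeletonize(v)
  expect_true(all(S[v == FALSE] == FALSE))  # S subset of A
  # a straight axial tube reduces to a single-voxel-wide axial path
  expect_lte(sum(S), 24)
  expect_gte(sum(S), 20)
  per_slice <- apply(S, 1, sum)
  expect_true(all(per_slice <= 1))
  # degenerate cases: single voxel and empty mask are fixed points
  one <- array(FALSE, c(4, 4, 4)); one[2, 2, 2] <- TRUE
  expect_identical(skeletonize(one), one)
  empty <- array(FALSE, c(4, 4, 4))
  expect_identical(skeletonize(empty), empty)
})

test_that("skeletonization preserves connectivity", {
  # an L-shaped thick tube stays one connected skeleton component
  v <- array(FALSE, c(20, 20, 20))
  v <- rasterize_capsule(v, c(3, 10, 10), c(17, 10, 10), 2.5)
  v <- rasterize_capsule(v, c(17, 10, 10), c(17, 10, 18), 2.5)
  S <- skeletonize(v)
  expect_true(all(S[!v] == FALSE))
  # flood fill over 26-connectivity: one component
  count_components <- function(m) {
    d <- dim(m); seen <- array(FALSE, d); n <- 0
    idx <- which(m, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      if (seen[p[1], p[2], p[3]]) next
      n <- n + 1
      queue <- list(p)
      seen[p[1], p[2], p[3]] <- TRUE
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
          z <- q[1] + dz; y <- q[2] + dy; x <- q[3] + dx
          if (z >= 1 && y >= 1 && x >= 1 && z <= d[1] && y <= d[2] && x <= d[3] &&
              m[z, y, x] && !seen[z, y, x]) {
            seen[z, y, x] <- TRUE
            queue <- c(queue, list(c(z, y, x)))
          }
        }
      }
    }
    n
  }
  expect_equal(count_components(S), 1L)
})

test_that("label volumes enforce the subset and adjacency invariants", {
  v <- make_tube(c(16L, 17L, 17L), radius = 2.5, center = c(9, 9))
  lv <- label_volumes(v)
  expect_true(all(lv$S[!lv$A] == FALSE))
  expect_true(all(lv$P[!lv$A] == FALSE))
  # every surface voxel has a face neighbor outside A
  pad <- array(FALSE, dim(v) + 2L)
  pad[2:(dim(v)[1] + 1), 2:(dim(v)[2] + 1), 2:(dim(v)[3] + 1)] <- lv$A
  idx <- which(lv$P, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    z <- idx[r, 1] + 1L; y <- idx[r, 2] + 1L; x <- idx[r, 3] + 1L
    expect_true(!all(pad[z - 1, y, x], pad[z + 1, y, x], pad[z, y - 1, x],
                     pad[z, y + 1, x], pad[z, y, x - 1], pad[z, y, x + 1]))
  }
  bad_S <- array(TRUE, dim(v))
  expect_error(label_volumes(v, S = bad_S), "subset")
})

test_that("windowed metrics match naive triple-loop oracles exactly", {
  set.seed(31)
  A <- array(runif(12^3) > 0.7, c(12, 12, 12))
  lv <- label_volumes(A)
  n <- 8L; stride <- 4L
  maps <- window_metrics(lv, n = n, stride = stride)
  starts <- seq(1L, 12L - n + 1L, by = stride)
  for (iz in seq_along(starts)) for (iy in seq_along(starts)) for (ix in seq_along(starts)) {
    zs <- starts[iz] + 0:(n - 1); ys <- starts[iy] + 0:(n - 1); xs <- starts[ix] + 0:(n - 1)
    sA <- 0; sS <- 0; sP <- 0
    for (z in zs) for (y in ys) for (x in xs) {
      sA <- sA + lv$A[z, y, x]; sS <- sS + lv$S[z, y, x]; sP <- sP + lv$P[z, y, x]
    }
    expect_identical(maps$VVD[iz, iy, ix], sA / n^3)
    expect_identical(maps$VSD[iz, iy, ix], sS / n^3)
    expect_identical(maps$VSI[iz, iy, ix], sP / n^3)
    expect_identical(maps$VTI[iz, iy, ix], if (sS > 0) sA / sS else NA_real_)
    expect_identical(maps$VCI[iz, iy, ix], if (sA > 0) sP^2 / (4 * pi * sA) else NA_real_)
  }
})

test_that("hand-computable windows give the defining values", {
  # fully vessel-filled window: VVD = 1
  full <- array(TRUE, c(8, 8, 8))
  skel <- array(FALSE, c(8, 8, 8)); skel[, 4, 4] <- TRUE
  lv <- label_volumes(full, S = skel)
  m <- window_metrics(lv, n = 8)
  expect_equal(m$VVD[1, 1, 1], 1)
  # sum_A = 512, sum_S = 8 -> VTI = 64; sum_A/sum_S arithmetic
  expect_equal(m$VTI[1, 1, 1], 512 / 8)
  # 10^3 solid block in a 10^3 window: VCI = 488^2 / (4 pi 1000)
  b <- array(TRUE, c(10, 10, 10))
  sk <- array(FALSE, c(10, 10, 10)); sk[, 5, 5] <- TRUE
  mb <- window_metrics(label_volumes(b, S = sk), n = 10)
  expect_equal(mb$VCI[1, 1, 1], 488^2 / (4 * pi * 1000))
  expect_equal(mb$VSI[1, 1, 1], 488 / 1000)
  # empty window: densities zero, VTI and VCI undefined (NA, not 0)
  e <- label_volumes(array(FALSE, c(8, 8, 8)))
  me <- window_metrics(e, n = 8)
  expect_equal(me$VVD[1, 1, 1], 0)
  expect_true(is.na(me$VTI[1, 1, 1]))
  expect_true(is.na(me$VCI[1, 1, 1]))
  expect_error(window_metrics(e, n = 16), "window")
})

test_that("metric ranges hold and VTI grows with tube radius", {
  vti_for_radius <- function(r) {
    v <- make_tube(c(24L, 21L, 21L), radius = r, center = c(11, 11))
    lv <- label_volumes(v)
    maps <- window_metrics(lv, n = 16, stride = 8)
    mean(maps$VTI, na.rm = TRUE)
  }
  vtis <- vapply(c(2, 3, 4, 5), vti_for_radius, numeric(1))
  expect_true(all(diff(vtis) > 0))
  # range invariants on a random volume
  set.seed(32)
  A <- array(runif(16^3) > 0.6, c(16, 16, 16))
  maps <- window_metrics(label_volumes(A), n = 8, stride = 4)
  for (m in c("VVD", "VSD", "VSI")) {
    v <- maps[[m]][!is.na(maps[[m]])]
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_true(all(maps$VTI[!is.na(maps$VTI)] >= 1))
  expect_true(all(maps$VCI[!is.na(maps$VCI)] >= 0))
  ok <- !is.na(maps$VSI)
  expect_true(all(maps$VSI[ok] <= maps$VVD[ok]))
})

test_that("Otsu segmentation separates a two-level image exactly", {
  set.seed(33)
  fr <- array(10, c(1, 20, 20))
  bright <- sample(400, 40)
  fr[1, , ][bright] <- 200
  for (method in c("global_otsu", "proportion_adjusted", "weighted_optimal")) {
    m <- otsu_segment(image_stack(fr), method = method)
    got <- which(m$voxels[1, , ])
    expect_setequal(got, bright)
    thr <- attr(m, "thresholds")
    expect_true(thr > 10 && thr < 200)
  }
  expect_warning(mc <- otsu_segment(image_stack(array(5, c(1, 16, 16)))), "constant")
  expect_false(any(mc$voxels))
})

test_that("proportion-adjusted Otsu pulls the foreground into the band", {
  # heavy-tailed frame where plain Otsu over-segments
  set.seed(34)
  fr <- matrix(rexp(64 * 64, 10), 64, 64)
  fr[1:4, 1:16] <- fr[1:4, 1:16] + 2
  m <- otsu_segment(image_stack(array(fr, c(1, 64, 64))), method = "proportion_adjusted",
                    band = c(0.01, 0.05))
  frac <- mean(m$voxels)
  expect_gte(frac, 0.009)
  expect_lte(frac, 0.051)
})

test_that("depth profiles report means over defined windows with NA gaps", {
  A <- array(FALSE, c(24, 12, 12))
  A[1:12, 5:8, 5:8] <- TRUE          # vessels only in the shallow half
  lv <- label_volumes(A)
  maps <- window_metrics(lv, n = 8, stride = 4, z_step = 2)
  dp <- depth_profiles(maps)
  expect_true(all(c("metric", "depth_um", "mean", "n_defined") %in% names(dp$profiles)))
  vvd <- dp$profiles[dp$profiles$metric == "VVD", ]
  expect_true(all(diff(vvd$mean) <= 0))   # step down towards empty depths
  vti <- dp$profiles[dp$profiles$metric == "VTI", ]
  expect_true(any(is.na(vti$mean)))       # gap, not zero, where undefined
  expect_false(any(vti$mean[!is.na(vti$mean)] == 0))
})

test_that("dispersion statistics reproduce hand arithmetic", {
  # constant field: CV 0 everywhere, MCV 0, DMCV 0
  g0 <- c(4, 3, 3)
  maps <- structure(
    list(VVD = array(0.4, g0), VTI = array(4, g0), VSD = array(0.1, g0),
         VCI = array(2, g0), VSI = array(0.2, g0), window = 8L, stride = 4L,
         starts = list(1:4, 1:3, 1:3), depths = seq(0, 6, by = 2)),
    class = "metric_maps")
  ds <- dispersion(maps, region_labels = rep(c("a", "b"), each = 2))
  expect_true(all(ds$cv$cv[!is.na(ds$cv$cv)] == 0))
  expect_true(all(ds$mcv$mcv == 0))
  expect_true(all(ds$dmcv$dmcv == 0))
  # synthetic CV series: regions with CV 0.2 and 0.5 give DMCV 0.3
  fake <- maps
  set.seed(35)
  gz <- dim(maps$VVD)[1]
  for (iz in seq_len(gz)) {
    cv_t <- if (iz <= gz / 2) 0.2 else 0.5
    x <- stats::rnorm(length(fake$VVD[iz, , ]), 1, 1)
    x <- 1 + (x - mean(x)) * cv_t / stats::sd(x)  # mean 1, sd = cv_t exactly
    fake$VVD[iz, , ] <- x
  }
  labs <- rep(c("shallow", "deep"), each = gz / 2)
  ds2 <- dispersion(fake, labs)
  d_vvd <- ds2$dmcv[ds2$dmcv$metric == "VVD", ]
  expect_equal(d_vvd$dmcv, 0.3, tolerance = 1e-10)
})

test_that("the correlation screen flags dependent metric pairs", {
  set.seed(36)
  # independent random maps: |r| < 0.7 with high probability
  g <- c(4, 5, 5)
  maps <- structure(
    list(VVD = array(runif(100), g), VTI = array(1 + runif(100), g),
         VSD = array(runif(100), g), VCI = array(runif(100), g),
         VSI = array(runif(100), g),
         window = 8L, stride = 4L, starts = list(1:4, 1:5, 1:5),
         depths = seq(0, 6, by = 2)),
    class = "metric_maps")
  mc <- metric_correlation(maps)
  expect_equal(diag(mc$r), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(diag(mc$dependent)))       # a metric with itself
  off <- abs(mc$r[upper.tri(mc$r)])
  expect_true(all(off < 0.7))
  expect_false(any(mc$dependent[upper.tri(mc$dependent)]))
  # constructed dependence: VSI proportional to VVD is flagged
  maps$VSI <- maps$VVD * 0.5 + array(rnorm(100, 0, 0.01), g)
  mc2 <- metric_correlation(maps)
  expect_true(mc2$dependent["VVD", "VSI"])
  # too few defined windows errors
  maps$VVD[] <- NA
  expect_error(metric_correlation(maps), "fewer than 3")
})

test_that("on a single-radius phantom VVD and VSI are strongly correlated", {
  ph <- generate_vessels(phantom_config(shape = c(24, 48, 48), n_vessels = 5,
                                        radius_range = c(3, 3)), seed = 37)
  lv <- label_volumes(ph$truth$voxels)
  maps <- window_metrics(lv, n = 12, stride = 6)
  mc <- metric_correlation(maps)
  expect_gt(mc$r["VVD", "VSI"], 0.7)
  expect_true(mc$dependent["VVD", "VSI"])
})

test_that("region statistics normalize and test group differences", {
  set.seed(38)
  g <- c(8, 4, 4)
  base <- function(mu) array(rnorm(prod(g), mu, 1), g)
  maps <- structure(
    list(VVD = base(0), VTI = base(5), VSD = base(0), VCI = base(0), VSI = base(0),
         window = 8L, stride = 4L, starts = list(1:8, 1:4, 1:4),
         depths = seq(0, 14, by = 2)),
    class = "metric_maps")
  # two groups, VTI means differ by 10 sd -> ANOVA-style test rejects
  maps$VTI[5:8, , ] <- maps$VTI[5:8, , ] + 10
  labs <- rep(c("r1", "r2"), each = 4)
  rs <- region_stats(maps, labs)
  expect_lt(rs$tests$VTI$p, 0.05)
  # normalized means span [0, 1] per metric
  for (m in unique(rs$summary$metric)) {
    nm <- rs$summary$norm_mean[rs$summary$metric == m]
    expect_equal(min(nm), 0)
    expect_equal(max(nm), 1)
  }
  # identical groups: every depth layer holds the same values, so the
  # three regions have zero between-group variance -> F ~ 0, p ~ 1
  mapsI <- maps
  layer <- matrix(rnorm(16, 5, 1), 4, 4)
  for (iz in 1:8) for (m in c("VVD", "VTI", "VSD", "VCI", "VSI")) {
    mapsI[[m]][iz, , ] <- layer
  }
  rsI <- region_stats(mapsI, rep(c("a", "b", "c"), c(3, 3, 2)))
  expect_lt(rsI$tests$VTI$F, 1e-10)
  expect_gt(rsI$tests$VTI$p, 0.999)
})
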