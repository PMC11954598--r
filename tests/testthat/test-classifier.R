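# synthetic feature tables with region-specific metric distributions
make_region_features <- function(n_per_class, means, sd = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(means), function(cl) {
    mu <- means[[cl]]
    f <- as.data.frame(sapply(seq_along(mu), function(j) rnorm(n_per_class, mu[j], sd)))
    names(f) <- metric_names()
    f$label <- cl
    f
  }))
}

three_region_means <- list(
  neocortex   = c(0.30, 3.0, 0.040, 8,  0.20),
  white_matter = c(0.10, 2.0, 0.015, 3,  0.08),
  hippocampus = c(0.22, 5.0, 0.025, 12, 0.15)
)

test_that("linearly separable clusters are fit with training accuracy 1", {
  f <- make_region_features(50, list(c(-5, -5, -5, -5, -5), c(5, 5, 5, 5, 5)),
                            sd = 0.5, seed = 2)
  m <- train_region_svm(f)
  expect_equal(m$training_accuracy, 1)
  # margin oracle: every point sits on the correct side of its own
  # one-vs-rest hyperplane
  X <- scale(as.matrix(f[metric_names()]), m$centers, m$scales)
  for (i in seq_along(m$classes)) {
    d <- X %*% m$k[i, ] + m$b[i]
    expect_true(all((d > 0) == (f$label == m$classes[i])))
  }
})

test_that("three-class recovery generalizes to held-out samples", {
  train <- make_region_features(60, three_region_means, sd = 0.4, seed = 3)
  test <- make_region_features(60, three_region_means, sd = 0.4, seed = 4)
  m <- train_region_svm(train)
  acc <- mean(predict_svm(m, test) == test$label)
  expect_gt(acc, 0.9)
  # pairwise-voting scheme agrees closely
  m2 <- train_region_svm(train, scheme = "ovo")
  acc2 <- mean(predict_svm(m2, test) == test$label)
  expect_gt(acc2, 0.9)
})

test_that("degenerate training inputs are rejected or flagged", {
  f1 <- make_region_features(20, list(c(0, 0, 0, 0, 0)), seed = 5)
  expect_error(train_region_svm(f1), "2 classes")
  # identical duplicated points in both classes: inseparable
  set.seed(6)
  base <- make_region_features(20, list(c(0, 0, 0, 0, 0)), sd = 1, seed = 6)[metric_names()]
  dup <- rbind(cbind(base, label = 1), cbind(base, label = 2))
  expect_warning(m <- train_region_svm(dup), "inseparable|accuracy")
  expect_lte(m$training_accuracy, 0.5)
  # constant feature is dropped with a warning
  f <- make_region_features(30, list(c(-3, 0, 0, 0, 0), c(3, 0, 0, 0, 0)), seed = 7)
  f$VSI <- 1
  expect_warning(mc <- train_region_svm(f), "constant")
  expect_identical(mc$dropped, "VSI")
  expect_equal(unname(mc$k[, "VSI"]), rep(0, 2))
})

test_that("labels are invariant under feature rescaling absorbed by normalization", {
  train <- make_region_features(40, three_region_means, sd = 0.4, seed = 8)
  test <- make_region_features(40, three_region_means, sd = 0.4, seed = 9)
  m1 <- train_region_svm(train)
  train2 <- train; test2 <- test
  for (cn in metric_names()) { train2[[cn]] <- train2[[cn]] * 2; test2[[cn]] <- test2[[cn]] * 2 }
  m2 <- train_region_svm(train2)
  expect_identical(predict_svm(m1, test), predict_svm(m2, test2))
})

test_that("JSON serialization preserves decision values to 1e-12", {
  train <- make_region_features(40, three_region_means, sd = 0.4, seed = 10)
  m <- train_region_svm(train)
  p <- withr::local_tempfile(fileext = ".json")
  write_svm_json(m, p)
  m2 <- read_svm_json(p)
  X <- make_region_features(30, three_region_means, sd = 0.4, seed = 11)
  d1 <- deepvasc:::svm_decision_values(m, X)
  d2 <- deepvasc:::svm_decision_values(m2, X)
  expect_lt(max(abs(d1 - d2)), 1e-12)
  expect_identical(predict_svm(m, X), predict_svm(m2, X))
})

test_that("voxel classification labels defined windows and flags the rest", {
  train <- make_region_features(60, three_region_means, sd = 0.3, seed = 12)
  m <- train_region_svm(train)
  # constant-decision model: k = 0, intercepts favor class 1 everywhere
  mconst <- m
  mconst$k[] <- 0
  mconst$b <- c(class1 = 1, class2 = 0, class3 = 0)
  g <- c(6, 3, 3)
  set.seed(13)
  maps <- structure(
    list(VVD = array(runif(54), g), VTI = array(1 + runif(54), g),
         VSD = array(runif(54), g), VCI = array(runif(54), g),
         VSI = array(runif(54), g), window = 8L, stride = 4L,
         starts = list(1:6, 1:3, 1:3), depths = seq(0, 10, by = 2)),
    class = "metric_maps")
  maps$VTI[2, 1, 1] <- NA  # one undefined window
  lm <- classify_voxels(maps, mconst)
  expect_equal(lm$labels[2, 1, 1], 0L)
  expect_true(all(lm$labels %in% 0:3))
  def <- lm$labels != 0L
  expect_true(all(lm$labels[def] == 1L))
  # applying a model to its own training field reproduces training accuracy
  pred_train <- predict_svm(m, train)
  expect_equal(mean(pred_train == train$label), m$training_accuracy)
})

test_that("crossover depths are located by count interpolation", {
  # constructed counts: neocortex 10,10,2,0 vs white matter 0,2,10,10
  labels <- array(0L, c(4, 1, 12))
  counts <- list(c(10, 10, 2, 0), c(0, 2, 10, 10))
  for (iz in 1:4) {
    v <- c(rep(1L, counts[[1]][iz]), rep(2L, counts[[2]][iz]))
    labels[iz, 1, seq_along(v)] <- v
  }
  depths <- c(0, 10, 20, 30)
  cr <- crossover_depths(labels, depths)
  wm <- cr$crossovers[cr$crossovers$pair == "white_matter_over_neocortex", ]
  expect_equal(nrow(wm), 1L)
  expect_gt(wm$depth_um, 10)
  expect_lt(wm$depth_um, 20)
  # diff goes -8 -> +8 between bins 2 and 3: crossing at the midpoint
  expect_equal(wm$depth_um, 15)
  # single-class volume: no crossovers
  single <- array(1L, c(4, 2, 2))
  cr1 <- crossover_depths(single, depths)
  expect_equal(nrow(cr1$crossovers), 0L)
})

test_that("three-layer synthetic volumes recover bands and boundaries", {
  # depth-banded metric maps drawn from the per-region distributions
  g <- c(12, 6, 6)
  set.seed(14)
  region_of_layer <- rep(1:3, each = 4)
  maps <- structure(
    list(VVD = array(0, g), VTI = array(0, g), VSD = array(0, g),
         VCI = array(0, g), VSI = array(0, g), window = 8L, stride = 4L,
         starts = list(1:12, 1:6, 1:6), depths = seq(0, by = 8, length.out = 12)),
    class = "metric_maps")
  for (iz in seq_len(g[1])) {
    mu <- three_region_means[[region_of_layer[iz]]]
    for (j in seq_along(metric_names())) {
      maps[[metric_names()[j]]][iz, , ] <- rnorm(g[2] * g[3], mu[j], 0.3)
    }
  }
  train <- make_region_features(80, three_region_means, sd = 0.3, seed = 15)
  m <- train_region_svm(train)
  lm <- classify_voxels(maps, m)
  acc <- mean(lm$labels == array(rep(region_of_layer, g[2] * g[3]), g))
  expect_gte(acc, 0.9)
  cr <- crossover_depths(lm)
  # boundaries constructed between layers 4/5 (depth 28) and 8/9 (60)
  stride_um <- 8
  wm <- cr$crossovers$depth_um[cr$crossovers$pair == "white_matter_over_neocortex"]
  hc <- cr$crossovers$depth_um[cr$crossovers$pair == "hippocampus_over_white_matter"]
  expect_lte(abs(wm - 28), stride_um)
  expect_lte(abs(hc - 60), stride_um)
})
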