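#' Region codes
#'
#' Label convention of the classifier: 1 = neocortex, 2 = white matter,
#' 3 = hippocampus; 0 marks unclassified (undefined) windows.
#'
#' @return named integer vector.
#' @export
region_codes <- function() {
  c(neocortex = 1L, white_matter = 2L, hippocampus = 3L)
}

#' Build a feature table from metric maps
#'
#' One row per window where all five metrics are defined, with the
#' window grid position, its center depth, and the feature vector
#' `(VVD, VTI, VSD, VCI, VSI)`.
#'
#' @param maps a [window_metrics()] result.
#' @param region_labels optional region label (1/2/3) per grid depth
#'   layer, attached as a `label` column.
#' @return data.frame with columns `iz`, `iy`, `ix`, `depth_um`,
#'   the five metrics, and optionally `label`.
#' @export
features_from_maps <- function(maps, region_labels = NULL) {
  stopifnot(inherits(maps, "metric_maps"))
  g <- dim(maps$VVD)
  grid <- expand.grid(iz = seq_len(g[1]), iy = seq_len(g[2]), ix = seq_len(g[3]))
  M <- sapply(metric_names(), function(m) as.numeric(maps[[m]]))
  keep <- stats::complete.cases(M)
  out <- cbind(grid[keep, , drop = FALSE],
               depth_um = maps$depths[grid$iz[keep]],
               as.data.frame(M[keep, , drop = FALSE]))
  if (!is.null(region_labels)) out$label <- as.integer(region_labels[out$iz])
  rownames(out) <- NULL
  out
}

#' Train a linear SVM on morphometric feature vectors
#'
#' Features are z-scored with training statistics; constant features are
#' dropped with a warning. The multi-class decision surface is built
#' one-vs-rest by default: one linear hyperplane (normal vector `k`,
#' intercept `b`) per class, classification by argmax of the decision
#' values `k . v + b`; `scheme = "ovo"` delegates pairwise voting to the
#' underlying solver instead.
#'
#' @param features data.frame with the five metric columns and an
#'   integer `label` column (values in 1..3, see [region_codes()]);
#'   at least 2 classes with >= 5 samples each.
#' @param cost soft-margin regularization constant C.
#' @param scheme `"ovr"` (one-vs-rest hyperplanes) or `"ovo"`.
#' @return An object of class `linear_svm_model`: hyperplane matrix `k`
#'   (class x feature), intercepts `b`, normalization `centers`/
#'   `scales`, `classes`, `feature_names`, `training_accuracy`.
#' @export
train_region_svm <- function(features, cost = 1, scheme = c("ovr", "ovo")) {
  scheme <- match.arg(scheme)
  fn <- metric_names()
  missing_cols <- setdiff(c(fn, "label"), names(features))
  if (length(missing_cols)) {
    stop(sprintf("train_region_svm: missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  y <- as.integer(features$label)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("train_region_svm: need at least 2 classes")
  if (any(table(y) < 5L)) stop("train_region_svm: need >= 5 samples per class")
  X <- as.matrix(features[fn])
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  dropped <- scales == 0
  if (any(dropped)) {
    warning(sprintf("train_region_svm: dropping constant feature(s): %s",
                    paste(fn[dropped], collapse = ", ")))
    scales[dropped] <- 1
  }
  Xs <- scale(X, center = centers, scale = scales)
  Xs[, dropped] <- 0
  used <- !dropped
  k <- matrix(0, length(classes), length(fn),
              dimnames = list(paste0("class", classes), fn))
  b <- stats::setNames(numeric(length(classes)), paste0("class", classes))
  ovo_fit <- NULL
  if (scheme == "ovr") {
    for (i in seq_along(classes)) {
      yi <- factor(y == classes[i], levels = c(TRUE, FALSE))
      fit <- e1071::svm(Xs[, used, drop = FALSE], yi, kernel = "linear",
                        cost = cost, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      bi <- -fit$rho
      # the solver's decision-value sign convention depends on sample
      # order; orient each hyperplane so its own class scores positive
      d <- Xs[, used, drop = FALSE] %*% w + bi
      if (mean(d[y == classes[i]]) < mean(d[y != classes[i]])) {
        w <- -w
        bi <- -bi
      }
      k[i, used] <- w
      b[i] <- bi
    }
  } else {
    ovo_fit <- e1071::svm(Xs[, used, drop = FALSE], factor(y), kernel = "linear",
                          cost = cost, scale = FALSE)
  }
  model <- structure(
    list(k = k, b = b, centers = centers, scales = scales,
         dropped = fn[dropped], classes = classes, feature_names = fn,
         scheme = scheme, cost = cost, ovo_fit = ovo_fit,
         training_accuracy = NA_real_),
    class = "linear_svm_model"
  )
  pred <- predict_svm(model, X)
  model$training_accuracy <- mean(pred == y)
  if (model$training_accuracy <= 0.5) {
    warning(sprintf("train_region_svm: training accuracy %.2f <= 0.5; classes may be inseparable",
                    model$training_accuracy))
  }
  model
}

#' @export
print.linear_svm_model <- function(x, ...) {
  cat(sprintf("<linear_svm_model> %s, %d classes, training accuracy %.3f\n",
              x$scheme, length(x$classes), x$training_accuracy))
  invisible(x)
}

# decision values (n x classes) in raw feature units
svm_decision_values <- function(model, X) {
  Xs <- scale(as.matrix(X[, model$feature_names, drop = FALSE]),
              center = model$centers, scale = model$scales)
  Xs[, model$feature_names %in% model$dropped] <- 0
  Xs %*% t(model$k) + matrix(model$b, nrow(Xs), length(model$b), byrow = TRUE)
}

#' Predict region labels for feature vectors
#'
#' Evaluates the per-class decision values `k . v + b` and assigns the
#' argmax class (one-vs-rest), or delegates to pairwise voting for an
#' `"ovo"` model.
#'
#' @param model a `linear_svm_model`.
#' @param X data.frame or matrix containing the five metric columns.
#' @return integer label vector.
#' @export
predict_svm <- function(model, X) {
  if (is.matrix(X)) X <- as.data.frame(X)
  if (model$scheme == "ovo") {
    Xs <- scale(as.matrix(X[, model$feature_names, drop = FALSE]),
                center = model$centers, scale = model$scales)
    used <- !(model$feature_names %in% model$dropped)
    return(as.integer(as.character(predict(model$ovo_fit, Xs[, used, drop = FALSE]))))
  }
  D <- svm_decision_values(model, X)
  model$classes[max.col(D, ties.method = "first")]
}

#' Classify every window of a metric map volume
#'
#' Windows where any metric is undefined receive label 0
#' (unclassified); defined windows get the argmax region label and the
#' per-class decision scores.
#'
#' @param maps a [window_metrics()] result (feature order must match the
#'   model's `feature_names`).
#' @param model a `linear_svm_model`.
#' @return An object of class `label_maps`: `labels` (integer array on
#'   the window grid), `scores` (list of per-class decision arrays),
#'   `depths`.
#' @export
classify_voxels <- function(maps, model) {
  stopifnot(inherits(maps, "metric_maps"), inherits(model, "linear_svm_model"))
  if (!identical(model$feature_names, metric_names())) {
    stop("classify_voxels: model feature order does not match metric maps")
  }
  g <- dim(maps$VVD)
  M <- sapply(metric_names(), function(m) as.numeric(maps[[m]]))
  keep <- stats::complete.cases(M)
  labels <- array(0L, g)
  scores <- lapply(stats::setNames(model$classes, paste0("class", model$classes)),
                   function(cl) array(NA_real_, g))
  if (any(keep)) {
    Xdef <- as.data.frame(M[keep, , drop = FALSE])
    if (model$scheme == "ovo") {
      labels[keep] <- predict_svm(model, Xdef)
    } else {
      D <- svm_decision_values(model, Xdef)
      labels[keep] <- model$classes[max.col(D, ties.method = "first")]
      for (i in seq_along(model$classes)) scores[[i]][keep] <- D[, i]
    }
  }
  structure(list(labels = labels, scores = scores, depths = maps$depths),
            class = "label_maps")
}

#' Depth-wise class counts and crossover depths
#'
#' Counts predicted labels per grid depth layer and locates the
#' crossover depths where the white-matter count first overtakes the
#' neocortex count, and where the hippocampus count first overtakes the
#' white-matter count — the depth-delimitation of the white matter. The
#' crossing is located by linear interpolation of the count difference
#' between adjacent layers.
#'
#' @param label_maps a [classify_voxels()] result (or an integer label
#'   array plus `depths`).
#' @param depths optional depth vector when `label_maps` is a bare
#'   array.
#' @return list with `counts` (data.frame `depth_um` and one column per
#'   class) and `crossovers` (data.frame `pair`, `depth_um`; empty when
#'   no crossover exists).
#' @export
crossover_depths <- function(label_maps, depths = NULL) {
  if (inherits(label_maps, "label_maps")) {
    labels <- label_maps$labels
    depths <- label_maps$depths
  } else {
    labels <- label_maps
    if (is.null(depths)) depths <- seq_len(dim(labels)[1])
  }
  g <- dim(labels)
  classes <- 1:3
  counts <- sapply(classes, function(cl) {
    vapply(seq_len(g[1]), function(iz) sum(labels[iz, , ] == cl), numeric(1))
  })
  colnames(counts) <- c("neocortex", "white_matter", "hippocampus")
  find_cross <- function(a, b, from_depth = -Inf) {
    # first depth (at or past from_depth) where count b overtakes count a
    diffv <- b - a
    for (i in seq_along(diffv)) {
      if (depths[i] < from_depth) next
      if (diffv[i] > 0) {
        if (i == 1L) return(depths[1])
        d0 <- diffv[i - 1L]; d1 <- diffv[i]
        frac <- if (d1 == d0) 0.5 else (0 - d0) / (d1 - d0)
        return(depths[i - 1L] + frac * (depths[i] - depths[i - 1L]))
      }
    }
    NA_real_
  }
  wm_cross <- find_cross(counts[, 1], counts[, 2])
  # the regions are depth-ordered: the hippocampus can only overtake the
  # white matter once the white matter has itself begun
  hc_cross <- find_cross(counts[, 2], counts[, 3],
                         from_depth = if (is.na(wm_cross)) -Inf else wm_cross)
  cr <- data.frame(
    pair = c("white_matter_over_neocortex", "hippocampus_over_white_matter"),
    depth_um = c(wm_cross, hc_cross)
  )
  cr <- cr[!is.na(cr$depth_um), , drop = FALSE]
  rownames(cr) <- NULL
  list(counts = data.frame(depth_um = depths, counts), crossovers = cr)
}

#' Serialize / restore a one-vs-rest linear SVM model as JSON
#'
#' The hyperplanes, intercepts and normalization are written at full
#' precision; a reloaded model reproduces decision values to 1e-12.
#' (Pairwise-voting models carry a solver object and use
#' [saveRDS()] instead.)
#'
#' @param model a `linear_svm_model` trained with `scheme = "ovr"`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_svm_json <- function(model, path) {
  stopifnot(inherits(model, "linear_svm_model"))
  if (model$scheme != "ovr") stop("write_svm_json: only one-vs-rest models are JSON-serializable")
  obj <- list(format = "deepvasc-svm-1",
              k = model$k, b = model$b, centers = model$centers,
              scales = model$scales, dropped = model$dropped,
              classes = model$classes, feature_names = model$feature_names,
              cost = model$cost, training_accuracy = model$training_accuracy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_svm_json
#' @export
read_svm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "deepvasc-svm-1")) stop("read_svm_json: unrecognized format")
  k <- matrix(obj$k, nrow = length(obj$classes), byrow = FALSE,
              dimnames = list(paste0("class", obj$classes), obj$feature_names))
  structure(
    list(k = k, b = stats::setNames(as.numeric(obj$b), paste0("class", obj$classes)),
         centers = stats::setNames(as.numeric(obj$centers), obj$feature_names),
         scales = stats::setNames(as.numeric(obj$scales), obj$feature_names),
         dropped = as.character(obj$dropped), classes = as.integer(obj$classes),
         feature_names = obj$feature_names, scheme = "ovr", cost = obj$cost,
         ovo_fit = NULL, training_accuracy = obj$training_accuracy),
    class = "linear_svm_model"
  )
}
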