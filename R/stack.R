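#' 3D image stack
#'
#' The universal container of the pipeline: a 3D volume of non-negative
#' intensities with a physical depth axis. Axis order is `(z, y, x)` with
#' `z` the depth (one frame per depth plane), `y` the line-scan (row)
#' direction and `x` the fast scan direction within a line. The depth of
#' frame `k` (1-based) is `z0_depth + (k - 1) * z_step` micrometres.
#'
#' @param voxels numeric 3D array, dimensions `(z, y, x)`, all values
#'   finite and `>= 0`.
#' @param z_step physical depth increment between frames, in micrometres
#'   (`> 0`). Deep z-stacks are typically acquired at a 2 um step.
#' @param z0_depth depth of the first frame in micrometres (`>= 0`).
#' @param bit_depth optional record of the original on-disk bit depth
#'   (8, 16 or 32); intensities are always held in double precision
#'   internally.
#' @return An object of class `image_stack` with fields `voxels`,
#'   `z_step`, `z0_depth`, `bit_depth`.
#' @export
image_stack <- function(voxels, z_step = 2, z0_depth = 0, bit_depth = NA_integer_) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) {
    stop("image_stack: all intensities must be finite")
  }
  if (any(voxels < 0)) {
    stop("image_stack: intensities must be non-negative")
  }
  if (!is.numeric(z_step) || length(z_step) != 1L || z_step <= 0) {
    stop("image_stack: z_step must be a single positive number")
  }
  structure(
    list(
      voxels = voxels,
      z_step = as.numeric(z_step),
      z0_depth = as.numeric(z0_depth),
      bit_depth = as.integer(bit_depth)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d frame(s) of %d x %d (y x x), z_step %g um, depths %g..%g um\n",
    d[1], d[2], d[3], x$z_step, x$z0_depth, x$z0_depth + (d[1] - 1) * x$z_step
  ))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Depth coordinate of every frame
#'
#' @param stack an [image_stack].
#' @return numeric vector of depths in micrometres, one per frame.
#' @export
frame_depths <- function(stack) {
  nz <- dim(stack$voxels)[1]
  stack$z0_depth + (seq_len(nz) - 1) * stack$z_step
}

#' Extract a single frame as a y-by-x matrix
#'
#' @param stack an [image_stack].
#' @param k frame index (1-based, increasing depth).
#' @return numeric matrix `(y, x)`.
#' @export
get_frame <- function(stack, k) {
  d <- dim(stack$voxels)
  stopifnot(k >= 1, k <= d[1])
  matrix(stack$voxels[k, , ], d[2], d[3])
}

#' Binary mask volume co-registered with an image stack
#'
#' @param voxels logical 3D array `(z, y, x)`.
#' @param role one of `"signal"`, `"background"`, `"vessel_truth"` — what
#'   the marked voxels represent.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, role = c("vessel_truth", "signal", "background")) {
  role <- match.arg(role)
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1L, dim(voxels)))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask_volume: mask may not contain NA")
  structure(list(voxels = voxels, role = role), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<mask_volume role=%s> %d x %d x %d, %d voxels set (%.2f%%)\n",
    x$role, d[1], d[2], d[3], sum(x$voxels), 100 * mean(x$voxels)
  ))
  invisible(x)
}

as_voxels <- function(x) {
  if (inherits(x, "image_stack") || inherits(x, "mask_volume")) x$voxels else x
}

check_coregistered <- function(a, b, what = "volumes") {
  if (!identical(dim(as_voxels(a)), dim(as_voxels(b)))) {
    stop(sprintf("%s are not co-registered (shape mismatch)", what))
  }
  invisible(TRUE)
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are interpreted as depth planes in file order (increasing depth).
#' Intensities are converted to double precision; `tiff` maps integer
#' samples to `[0, 1]`, which is kept as-is (the original bit depth is
#' recorded in the returned object). If a scaling sidecar written by
#' [write_stack()] is present next to the file, the original intensity
#' scale is restored.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param z_step depth increment in micrometres.
#' @param z0 depth of the first page in micrometres.
#' @return An [image_stack].
#' @export
read_stack <- function(path, z_step = 2, z0 = 0) {
  if (!file.exists(path)) stop(sprintf("read_stack: cannot read '%s'", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop(sprintf("read_stack: '%s' is not a readable TIFF (%s)", path, conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse any extra channels
    p
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop("read_stack: pages have inconsistent shapes")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  vox <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$scale) && !identical(meta$scale, "constant")) {
      vox <- vox * meta$scale + meta$offset
    } else if (identical(meta$scale, "constant")) {
      vox <- vox * 0 + meta$offset
    }
  }
  image_stack(vox, z_step = z_step, z0_depth = z0,
              bit_depth = if (is.null(bits)) NA_integer_ else bits)
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are min-max scaled to the full representable range of the
#' requested sample format (a TIFF stores samples in `[0, 1]`, mapped to
#' the integer range for 8/16-bit output). The affine transform
#' (`offset`, `scale`) needed to recover original units is recorded in a
#' JSON sidecar `<path>.json`; [read_stack()] applies it automatically.
#' Constant stacks are written as zeros with scale flag `"constant"`.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @param dtype `"uint8"`, `"uint16"` or `"float32"` (32-bit samples;
#'   with the underlying TIFF library intensities are quantized at
#'   `2^-32` of the stack's dynamic range, i.e. beyond single
#'   precision).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("float32", "uint16", "uint8")) {
  dtype <- match.arg(dtype)
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  vox <- stack$voxels
  lo <- min(vox); hi <- max(vox)
  if (hi > lo) {
    scaled <- (vox - lo) / (hi - lo)
    meta <- list(offset = lo, scale = hi - lo, dtype = dtype,
                 z_step = stack$z_step, z0_depth = stack$z0_depth)
  } else {
    scaled <- vox * 0
    meta <- list(offset = lo, scale = "constant", dtype = dtype,
                 z_step = stack$z_step, z0_depth = stack$z0_depth)
  }
  frames <- lapply(seq_len(dim(vox)[1]), function(k) {
    matrix(scaled[k, , ], dim(vox)[2], dim(vox)[3])
  })
  ok <- tryCatch(
    tiff::writeTIFF(frames, path, bits.per.sample = bits),
    error = function(e) stop(sprintf("write_stack: cannot write '%s' (%s)", path, conditionMessage(e)))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask volume from a TIFF (non-zero voxels are TRUE)
#'
#' @param path TIFF path.
#' @param role mask role tag, see [mask_volume()].
#' @return A [mask_volume].
#' @export
read_mask <- function(path, role = "vessel_truth") {
  s <- read_stack(path, z_step = 1, z0 = 0)
  mask_volume(s$voxels > 0, role = role)
}

#' Write a mask volume to an 8-bit TIFF (TRUE -> 255)
#'
#' @param mask a [mask_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  s <- image_stack(array(as.numeric(mask$voxels), dim = dim(mask$voxels)), z_step = 1)
  write_stack(s, path, dtype = "uint8")
}

#' Min-max normalize a stack to the unit interval
#'
#' Network input convention: intensities are rescaled per stack to the
#' unit interval; the affine transform is returned so outputs can be
#' mapped back to original units.
#'
#' @param stack an [image_stack].
#' @return list with `stack` (normalized), `offset`, `scale`.
#' @export
normalize_stack <- function(stack) {
  lo <- min(stack$voxels); hi <- max(stack$voxels)
  sc <- if (hi > lo) hi - lo else 1
  out <- stack
  out$voxels <- (stack$voxels - lo) / sc
  list(stack = out, offset = lo, scale = sc)
}
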