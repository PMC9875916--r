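#' Mean-center and range-normalize image intensities
#'
#' `x <- (x - mean(x)) / (max(x) - min(x))`, applied elementwise over the
#' whole image (per volume by default in the pipeline, keeping inter-slice
#' intensity relations). The output always lies within \[-1, 1\].
#'
#' @param image A numeric array (any dimensionality) with at least two
#'   distinct finite values.
#' @return The normalized array.
#' @examples
#' normalize_intensity(c(-2, 0, 2))
#' @export
normalize_intensity <- function(image) {
  if (!all(is.finite(image))) stop("image must contain only finite values")
  rng <- max(image) - min(image)
  if (rng == 0)
    stop("degenerate input: constant image (max equals min)")
  (image - mean(image)) / rng
}

#' Slice a volume along the axial (3rd) axis
#'
#' @param volume A 3D array; axial slice `k` is `volume[, , k]`.
#' @return An object of class `slice_stack`: `slices` (list of matrices),
#'   `source_shape`, `source_slice_shape`.
#' @examples
#' st <- slice_axial(make_volume_fixture(c(4, 5, 6)))
#' length(st$slices); dim(st$slices[[1]])
#' @export
slice_axial <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("volume must be a 3D array")
  slices <- lapply(seq_len(d[3]), function(k) volume[, , k])
  structure(list(slices = slices, source_shape = d,
                 source_slice_shape = d[1:2], pad_shape = NULL),
            class = "slice_stack")
}

# Bilinear interpolation weights from n_in samples to n_out samples
# (half-pixel centre alignment). Returns an n_out x n_in matrix whose rows
# are convex weights, so interpolated values are bounded by the input range.
.resize_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  pos <- (seq_len(n_out) - 0.5) * scale - 0.5   # 0-based input coordinate
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  frac <- pos - lo
  hi <- pmin(lo + 1, n_in - 1)
  W[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
  W[cbind(seq_len(n_out), hi + 1)] <- W[cbind(seq_len(n_out), hi + 1)] + frac
  W
}

#' Resize a 2D slice by bilinear interpolation
#'
#' @param slice A numeric matrix.
#' @param target Integer pair (rows, cols); a scalar is used for both.
#' @return The resized matrix; values are bounded by the input min/max.
#' @export
resize_slice <- function(slice, target = c(128L, 128L)) {
  if (!is.matrix(slice) || any(dim(slice) == 0L)) stop("slice must be a non-empty matrix")
  if (length(target) == 1L) target <- c(target, target)
  target <- as.integer(target)
  if (any(target < 1L)) stop("target must be positive")
  if (all(dim(slice) == target)) return(slice)
  Wr <- .resize_weights(nrow(slice), target[1])
  Wc <- .resize_weights(ncol(slice), target[2])
  Wr %*% slice %*% t(Wc)
}

# Symmetric zero-pad (or centre-crop) a slice to a square of side `side`.
.pad_crop_square <- function(slice, side = max(dim(slice))) {
  out <- matrix(0, side, side)
  d <- dim(slice)
  # source and destination index ranges per axis
  rng <- function(n) {
    if (n >= side) {
      off <- (n - side) %/% 2L
      list(src = seq_len(side) + off, dst = seq_len(side))
    } else {
      off <- (side - n) %/% 2L
      list(src = seq_len(n), dst = seq_len(n) + off)
    }
  }
  ri <- rng(d[1]); ci <- rng(d[2])
  out[ri$dst, ci$dst] <- slice[ri$src, ci$src]
  out
}

.unpad_square <- function(slice, orig) {
  side <- nrow(slice)
  out <- matrix(0, orig[1], orig[2])
  rng <- function(n) {
    if (n >= side) {
      off <- (n - side) %/% 2L
      list(src = seq_len(side), dst = seq_len(side) + off)
    } else {
      off <- (side - n) %/% 2L
      list(src = seq_len(n) + off, dst = seq_len(n))
    }
  }
  ri <- rng(orig[1]); ci <- rng(orig[2])
  out[ri$dst, ci$dst] <- slice[ri$src, ci$src]
  out
}

#' Restack slices into a 3D volume
#'
#' Inverse of [slice_axial()]. When the stack's slices were padded to square
#' and resampled (see [preprocess_volume()]), each slice is bilinearly
#' resampled back to its pre-resample shape and un-padded before stacking, so
#' the result has `source_shape`.
#'
#' @param stack A `slice_stack`, or a plain list of equally shaped matrices.
#' @return A 3D array.
#' @export
stack_to_volume <- function(stack) {
  if (!inherits(stack, "slice_stack")) {
    if (!is.list(stack) || length(stack) == 0L) stop("empty stack")
    stack <- structure(list(slices = stack, source_shape = NULL,
                            source_slice_shape = dim(stack[[1]]),
                            pad_shape = NULL), class = "slice_stack")
  }
  slices <- stack$slices
  if (length(slices) == 0L) stop("empty stack")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slice shapes differ across the stack")
  cur <- dims[, 1]
  if (!is.null(stack$pad_shape) && !all(cur == stack$pad_shape))
    slices <- lapply(slices, resize_slice, target = stack$pad_shape)
  if (!is.null(stack$pad_shape) &&
      !all(stack$pad_shape == stack$source_slice_shape))
    slices <- lapply(slices, .unpad_square, orig = stack$source_slice_shape)
  cur <- dim(slices[[1]])
  if (!all(cur == stack$source_slice_shape))
    stop("slice shape ", paste(cur, collapse = "x"),
         " does not match source_slice_shape")
  vol <- simplify2array(slices)
  dim(vol) <- c(stack$source_slice_shape, length(slices))
  vol
}

#' Condition a volume for the model
#'
#' Applies per-volume intensity normalization ([normalize_intensity()]),
#' slices axially, symmetrically zero-pads each slice to square (no tissue is
#' discarded) and bilinearly resamples to the model input size.
#'
#' @param volume A 3D array.
#' @param size Model input side length (default 128).
#' @param normalize Apply intensity normalization first (default `TRUE`).
#' @return A `slice_stack` whose `slices` are `size x size` matrices in
#'   \[-1, 1\]; `normalized_volume` keeps the normalized (unsliced) volume.
#' @export
preprocess_volume <- function(volume, size = 128L, normalize = TRUE) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("volume must be a 3D array")
  nv <- if (normalize) normalize_intensity(volume) else volume
  st <- slice_axial(nv)
  side <- max(d[1:2])
  st$pad_shape <- c(side, side)
  st$slices <- lapply(st$slices, function(s)
    resize_slice(.pad_crop_square(s, side), c(size, size)))
  st$normalized_volume <- nv
  st
}

#' Fraction of non-background pixels in a slice
#'
#' Intended for filtering near-empty edge slices from training sets.
#'
#' @param slice A numeric matrix.
#' @param background Background value (default the slice minimum).
#' @param tol Tolerance around the background value.
#' @return A proportion in \[0, 1\].
#' @export
slice_foreground_fraction <- function(slice, background = min(slice),
                                      tol = 1e-6) {
  mean(abs(slice - background) > tol)
}
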