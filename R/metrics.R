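#' Structural similarity index (SSIM)
#'
#' `SSIM(x, y) = (2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' with `c1 = (k1 * data_range)^2`, `c2 = (k2 * data_range)^2`. In
#' `"global"` mode the formula is evaluated once on whole-image moments
#' (population variances); in the default `"windowed"` mode it is averaged
#' over all fully interior sliding square windows. Identical images give 1;
#' the value lies in \[-1, 1\].
#'
#' @param x,y Numeric matrices of matching shape.
#' @param mode `"windowed"` (uniform sliding window) or `"global"`.
#' @param data_range Dynamic range of the data (> 0); metrics in this package
#'   are conventionally computed on \[0, 1\]-scaled slices with
#'   `data_range = 1`.
#' @param window Side of the square window in windowed mode.
#' @param k1,k2 Stabilization constants (standard 0.01 and 0.03).
#' @return A scalar in \[-1, 1\].
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' ssim(x, x)
#' @export
ssim <- function(x, y, mode = c("windowed", "global"), data_range = 1,
                 window = 7L, k1 = 0.01, k2 = 0.03) {
  mode <- match.arg(mode)
  if (!identical(dim(x), dim(y))) stop("x and y must have matching shapes")
  stopifnot(data_range > 0)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  if (mode == "global") {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  w <- as.integer(window)
  if (nrow(x) < w || ncol(x) < w)
    stop("images smaller than the ", w, "x", w, " SSIM window")
  n <- w * w
  sx <- .box_sum(x, w); sy <- .box_sum(y, w)
  sxx <- .box_sum(x * x, w); syy <- .box_sum(y * y, w)
  sxy <- .box_sum(x * y, w)
  mx <- sx / n; my <- sy / n
  vx <- sxx / n - mx^2
  vy <- syy / n - my^2
  cxy <- sxy / n - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

# Sums over all w x w interior windows via 2D cumulative sums.
.box_sum <- function(x, w) {
  cs <- apply(apply(x, 2, cumsum), 1, cumsum) # transposed double cumsum
  cs <- t(cs)
  H <- nrow(x); W <- ncol(x)
  P <- matrix(0, H + 1L, W + 1L)
  P[2:(H + 1L), 2:(W + 1L)] <- cs
  i <- seq_len(H - w + 1L)
  j <- seq_len(W - w + 1L)
  P[i + w, j + w, drop = FALSE] - P[i, j + w, drop = FALSE] -
    P[i + w, j, drop = FALSE] + P[i, j, drop = FALSE]
}

#' Mean squared error between two images
#'
#' @param I,K Numeric arrays of matching shape.
#' @return Mean squared elementwise difference (>= 0).
#' @export
mse <- function(I, K) {
  if (!identical(dim(I), dim(K)) || length(I) != length(K))
    stop("I and K must have matching shapes")
  mean((I - K)^2)
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(max_i / sqrt(MSE))` in decibels; `Inf` when the images are
#' identical (MSE 0).
#'
#' @param I,K Numeric arrays of matching shape.
#' @param max_i Maximum possible pixel value (> 0).
#' @return PSNR in dB.
#' @export
psnr <- function(I, K, max_i = 1) {
  if (max_i <= 0) stop("max_i must be positive")
  m <- mse(I, K)
  if (m == 0) return(Inf)
  20 * log10(max_i / sqrt(m))
}

#' Per-subject reconstruction metrics by slice averaging
#'
#' Computes SSIM, PSNR and MSE per aligned slice pair and averages them
#' arithmetically; slices with infinite PSNR (identical pairs) are excluded
#' from the PSNR average and counted.
#'
#' @param slices_x,slices_y Equal-length lists of matrices (or `H x W x N`
#'   arrays), aligned slice by slice.
#' @param mode,data_range,window Passed to [ssim()]; `data_range` is also
#'   used as the PSNR peak value.
#' @return An object of class `metric_report`: a list with `ssim`, `psnr`,
#'   `mse`, `n_slices_averaged`, `n_psnr_excluded`.
#' @export
subject_metrics <- function(slices_x, slices_y, mode = "windowed",
                            data_range = 1, window = 7L) {
  to_list <- function(a) {
    if (is.list(a)) return(a)
    d <- dim(a)
    if (length(d) == 3L) return(lapply(seq_len(d[3]), function(k) a[, , k]))
    if (length(d) == 2L) return(list(a))
    stop("slices must be a list of matrices or a 3D array")
  }
  slices_x <- to_list(slices_x); slices_y <- to_list(slices_y)
  if (length(slices_x) == 0L) stop("empty slice lists")
  if (length(slices_x) != length(slices_y))
    stop("slice lists must have equal length")
  ss <- mapply(function(a, b) ssim(a, b, mode = mode, data_range = data_range,
                                   window = window),
               slices_x, slices_y)
  ms <- mapply(mse, slices_x, slices_y)
  ps <- mapply(function(a, b) psnr(a, b, max_i = data_range),
               slices_x, slices_y)
  fin <- is.finite(ps)
  structure(list(ssim = mean(ss),
                 psnr = if (any(fin)) mean(ps[fin]) else Inf,
                 mse = mean(ms),
                 n_slices_averaged = length(slices_x),
                 n_psnr_excluded = sum(!fin)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("SSIM %.4f | PSNR %.2f dB | MSE %.5f (%d slices, %d excluded from PSNR)\n",
              x$ssim, x$psnr, x$mse, x$n_slices_averaged, x$n_psnr_excluded))
  invisible(x)
}

# map [-1, 1] normalized intensities onto [0, 1] for metric evaluation
.to_unit <- function(x) (x + 1) / 2
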