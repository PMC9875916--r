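#' Voxelwise residual map between input and reconstruction
#'
#' The signed residual is `reconstruction - input` (in normalized intensity
#' units, both volumes restored to the source 3D geometry); atrophy relative
#' to the learned normal anatomy appears as positive signed residual (the
#' model "fills in" missing tissue). `magnitude` is the absolute value.
#'
#' @param input_volume,reconstructed_volume 3D arrays of matching shape.
#' @param subject_id Optional identifier carried along.
#' @return An object of class `residual_map` with `signed`, `magnitude`,
#'   `subject_id`.
#' @export
residual_map <- function(input_volume, reconstructed_volume,
                         subject_id = NA_character_) {
  if (!identical(dim(input_volume), dim(reconstructed_volume)))
    stop("input and reconstruction must have matching shapes")
  signed <- reconstructed_volume - input_volume
  structure(list(signed = signed, magnitude = abs(signed),
                 subject_id = subject_id), class = "residual_map")
}

#' Threshold a residual map into an effective-atrophy mask
#'
#' A voxel is flagged iff its residual value is strictly greater than the
#' threshold ("greater than" semantics). The default threshold, 0.03
#' normalized intensity units, is the value at which background noise outside
#' the brain region is just removed on the reference MRI data; for other data
#' (e.g. phantoms) it should be re-calibrated, see [calibrate_threshold()].
#'
#' @param map A [residual_map()].
#' @param threshold Positive residual cutoff.
#' @param use_signed Threshold the signed residual instead of the magnitude
#'   (default `FALSE`: polarity-agnostic).
#' @return An object of class `atrophy_mask` with logical 3D `mask`,
#'   `threshold`, `use_signed`, `subject_id`.
#' @export
effective_atrophy_mask <- function(map, threshold = 0.03, use_signed = FALSE) {
  stopifnot(inherits(map, "residual_map"))
  if (threshold <= 0) stop("threshold must be > 0")
  v <- if (isTRUE(use_signed)) map$signed else map$magnitude
  structure(list(mask = v > threshold, threshold = threshold,
                 use_signed = isTRUE(use_signed), subject_id = map$subject_id),
            class = "atrophy_mask")
}

#' Group frequency mask from per-subject atrophy masks
#'
#' For each voxel, the frequency is the proportion of subjects whose atrophy
#' mask flags it; the binary mask keeps voxels whose frequency strictly
#' exceeds `freq_threshold` ("exceeding" semantics, default 60%).
#'
#' @param masks A list of [effective_atrophy_mask()] results (or logical
#'   arrays) with a common shape.
#' @param freq_threshold Frequency cutoff in \[0, 1).
#' @return An object of class `frequency_mask` with `frequency` (3D array of
#'   multiples of `1/n_subjects`), `binary`, `freq_threshold`, `n_subjects`.
#' @export
group_frequency_mask <- function(masks, freq_threshold = 0.60) {
  if (length(masks) < 1L) stop("at least one mask is required")
  arrs <- lapply(masks, function(m) {
    if (inherits(m, "atrophy_mask")) m$mask else m
  })
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1))))
    stop("masks must share a common shape")
  freq <- Reduce(`+`, lapply(arrs, function(a) a * 1)) / length(arrs)
  structure(list(frequency = freq, binary = freq > freq_threshold,
                 freq_threshold = freq_threshold, n_subjects = length(arrs)),
            class = "frequency_mask")
}

# Connected-component labelling (union-find over neighbour offsets).
# connectivity: 26 or 6 for 3D arrays, 8 or 4 for 2D matrices.
.label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  nd <- length(d)
  if (nd == 2L) { d <- c(d, 1L); dim(mask) <- d }
  if (is.null(connectivity)) connectivity <- if (nd == 2L) 8L else 26L
  offs <- switch(as.character(connectivity),
    "6" = , "4" = rbind(c(1, 0, 0), c(0, 1, 0), if (nd == 3L) c(0, 0, 1)),
    "26" = , "8" = {
      o <- as.matrix(expand.grid(di = -1:1, dj = -1:1,
                                 dk = if (nd == 3L) 0:1 else 0))
      # keep one of each +/- pair: lexicographically positive offsets
      keep <- o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0)))
      o[keep, , drop = FALSE]
    },
    stop("unsupported connectivity: ", connectivity))
  idx <- which(mask)
  if (length(idx) == 0L)
    return(list(labels = array(0L, if (nd == 2L) d[1:2] else d), sizes = integer(0)))
  pos <- arrayInd(idx, d)
  lab_of <- array(0L, d)
  lab_of[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(offs))) {
    np <- pos
    np[, 1] <- np[, 1] + offs[r, 1]
    np[, 2] <- np[, 2] + offs[r, 2]
    np[, 3] <- np[, 3] + offs[r, 3]
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
          np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    nidx <- (np[ok, 3] - 1L) * d[1] * d[2] + (np[ok, 2] - 1L) * d[1] + np[ok, 1]
    nb <- lab_of[nidx]
    src <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    for (t in seq_along(src)) {
      a <- find(src[t]); b <- find(nb[t])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  comp <- match(roots, unique(roots))
  labels <- array(0L, d)
  labels[idx] <- comp
  if (nd == 2L) dim(labels) <- d[1:2]
  list(labels = labels, sizes = tabulate(comp))
}

#' Remove small connected components from a binary mask
#'
#' Components with fewer than `min_size` voxels are removed; components with
#' `min_size` or more voxels are kept intact (inclusive retention). Default
#' connectivity is 26-neighbourhood in 3D (8 in 2D).
#'
#' @param mask A logical (or 0/1) 2D or 3D array.
#' @param min_size Minimum surviving component size (>= 1).
#' @param connectivity 26 or 6 for volumes, 8 or 4 for matrices.
#' @return A logical array of the same shape.
#' @export
cluster_filter <- function(mask, min_size = 50L, connectivity = NULL) {
  if (min_size < 1L) stop("min_size must be >= 1")
  mask <- mask > 0
  lab <- .label_components(mask, connectivity)
  if (length(lab$sizes) == 0L) return(mask)
  keep <- which(lab$sizes >= min_size)
  out <- array(lab$labels %in% keep, dim(mask))
  out
}

#' Voxelwise two-sample t-test baseline mask
#'
#' The group-level comparison baseline: a pooled-variance two-sample t
#' statistic and two-sided p-value per voxel, thresholded at `p < alpha`
#' (uncorrected) and cluster-extent filtered. Voxels with zero pooled
#' variance are never significant.
#'
#' @param group_a,group_b Lists of 3D arrays (>= 2 subjects each, common
#'   shape).
#' @param alpha Significance level (default 0.05).
#' @param min_size Cluster-extent threshold passed to [cluster_filter()].
#' @param connectivity Passed to [cluster_filter()].
#' @return A list with `t` and `p` (3D arrays), `mask` (logical 3D array),
#'   `df`.
#' @export
voxelwise_ttest_mask <- function(group_a, group_b, alpha = 0.05,
                                 min_size = 50L, connectivity = NULL) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 subjects")
  d <- dim(group_a[[1]])
  all_same <- all(vapply(c(group_a, group_b),
                         function(v) identical(dim(v), d), logical(1)))
  if (!all_same) stop("all volumes must share a common shape")
  suma <- Reduce(`+`, group_a); sumb <- Reduce(`+`, group_b)
  ma <- suma / na; mb <- sumb / nb
  ssa <- Reduce(`+`, lapply(group_a, function(v) (v - ma)^2))
  ssb <- Reduce(`+`, lapply(group_b, function(v) (v - mb)^2))
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- array(0, d)
  p <- array(1, d)
  ok <- se > 0
  tstat[ok] <- (ma[ok] - mb[ok]) / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df)
  mask <- cluster_filter(p < alpha, min_size = min_size,
                         connectivity = connectivity)
  list(t = tstat, p = p, mask = mask, df = df)
}

#' Subject-level residual score
#'
#' The scalar anomaly score of a subject: by default the mean residual
#' magnitude over the brain mask; alternatively the sum of suprathreshold
#' magnitudes.
#'
#' @param map A [residual_map()].
#' @param brain_mask Logical array delimiting tissue (non-empty).
#' @param method `"mean"` (default) or `"suprathreshold_sum"`.
#' @param threshold Cutoff for `"suprathreshold_sum"`.
#' @return A non-negative scalar.
#' @export
subject_residual_score <- function(map, brain_mask,
                                   method = c("mean", "suprathreshold_sum"),
                                   threshold = 0.03) {
  stopifnot(inherits(map, "residual_map"))
  method <- match.arg(method)
  brain_mask <- brain_mask > 0
  if (!any(brain_mask)) stop("brain_mask is empty")
  v <- map$magnitude[brain_mask]
  switch(method,
         mean = mean(v),
         suprathreshold_sum = sum(v[v > threshold]))
}

#' Standardize scores to z-scores
#'
#' `z_i = (s_i - mean(s)) / sd(s)` with the sample (n - 1) standard
#' deviation; the reference group is the score list itself (pass reference
#' statistics explicitly to standardize against another group).
#'
#' @param scores Numeric vector (>= 2 values, non-zero spread).
#' @param center,scale Optional reference mean and sd; defaults to the
#'   mean/sd of `scores`.
#' @return A numeric vector of z-scores.
#' @examples
#' standardize_scores(c(1, 2, 3))
#' @export
standardize_scores <- function(scores, center = NULL, scale = NULL) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (is.null(center)) center <- mean(scores)
  if (is.null(scale)) scale <- stats::sd(scores)
  if (!is.finite(scale) || scale == 0) stop("zero spread: scores are constant")
  (scores - center) / scale
}

#' ROC curve and AUC for subject-level discrimination
#'
#' AUC uses the rank (Mann-Whitney) formulation, equal to the probability
#' that a random positive outscores a random negative, ties counting 1/2.
#' The curve sweeps all score thresholds (descending).
#'
#' @param scores Numeric scores (higher = more anomalous).
#' @param labels Logical or 0/1 vector; `TRUE`/1 = positive (anomalous).
#' @return An object of class `roc_result`: `auc` plus a tibble `curve` with
#'   `threshold`, `fpr`, `tpr`.
#' @examples
#' roc_auc(c(0, 1), c(FALSE, TRUE))$auc
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  np <- as.numeric(sum(labels)); nn <- as.numeric(sum(!labels))
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  # curve over descending thresholds via cumulative counts
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  tp <- cumsum(labels[ord])
  fp <- cumsum(!labels[ord])
  last <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  thr <- c(Inf, s_sorted[last])
  tpr <- c(0, tp[last]) / np
  fpr <- c(0, fp[last]) / nn
  structure(list(auc = auc,
                 curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC with %d thresholds, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Calibrate the effective-atrophy threshold on reference residuals
#'
#' Mirrors the rationale behind the fixed MRI threshold (chosen so that noise
#' outside the brain region is just removed): for a reference group of
#' normal-control residual maps, the threshold is a high quantile of the
#' residual magnitude over the chosen region.
#'
#' @param maps List of [residual_map()]s from normal controls.
#' @param region Logical array: where to measure the noise floor (e.g. the
#'   brain mask for a within-tissue quantile, or its complement for a
#'   background noise floor).
#' @param q Quantile (default 0.95).
#' @return A scalar threshold.
#' @export
calibrate_threshold <- function(maps, region, q = 0.95) {
  stopifnot(length(maps) >= 1L, any(region > 0))
  vals <- unlist(lapply(maps, function(m) m$magnitude[region > 0]))
  stats::quantile(vals, q, names = FALSE)
}

#' Binary erosion of a mask
#'
#' Removes voxels with any 6-neighbour (4-neighbour in 2D) outside the mask,
#' `iterations` times. Residual analyses default to an eroded tissue support
#' because slice resampling and reconstruction concentrate error at the
#' tissue-background interface; a thin boundary rind otherwise dominates
#' thresholded masks.
#'
#' @param mask A logical (or 0/1) 2D or 3D array.
#' @param iterations Number of single-voxel erosion passes (>= 0).
#' @return A logical array of the same shape.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  mask <- mask > 0
  d2 <- is.matrix(mask)
  if (d2) dim(mask) <- c(dim(mask), 1L)
  d <- dim(mask)
  shift <- function(a, ax, by) {
    o <- array(FALSE, d)
    if (abs(by) >= d[ax]) return(o)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- seq(1 + by, d[ax]); src[[ax]] <- seq(1, d[ax] - by) }
    else { dst[[ax]] <- seq(1, d[ax] + by); src[[ax]] <- seq(1 - by, d[ax]) }
    o[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    o
  }
  for (it in seq_len(iterations)) {
    er <- mask &
      shift(mask, 1, 1) & shift(mask, 1, -1) &
      shift(mask, 2, 1) & shift(mask, 2, -1)
    if (d[3] > 1L) er <- er & shift(mask, 3, 1) & shift(mask, 3, -1)
    mask <- er
  }
  if (d2) dim(mask) <- d[1:2]
  mask
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical arrays of matching shape.
#' @return `2|A & B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (!identical(dim(a), dim(b))) stop("masks must have matching shapes")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
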