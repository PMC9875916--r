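#' Specification of a synthetic pseudo-brain population
#'
#' Describes a seeded population of smooth ellipsoidal "brain" volumes
#' (background exactly 0, tissue intensities > 0) lying on a low-dimensional
#' anatomy manifold: every subject shares the same base anatomy and bright
#' sub-structures, individualized by smooth per-subject jitter of structure
#' positions, amplitudes and global intensity, plus additive noise inside the
#' tissue support. A configurable fraction of subjects is anomalous: a
#' ball-shaped region (shared across the population up to a small per-subject
#' shift, mimicking a group-characteristic atrophy site) has its intensity
#' multiplied by `1 - atrophy_magnitude`, and the affected voxels are recorded
#' in a ground-truth mask.
#'
#' @param grid_shape Integer triple of voxel counts (x, y, z; axial = 3rd).
#' @param n_subjects Number of subjects (>= 1).
#' @param n_structures Number of bright sub-structures per subject (>= 1).
#' @param subject_jitter_sd Dimensionless per-subject variation of structure
#'   positions/amplitudes and global intensity (>= 0).
#' @param noise_sd Additive Gaussian noise sd inside the tissue support (>= 0).
#' @param atrophy_fraction Proportion of anomalous subjects in \[0, 1\].
#' @param atrophy_magnitude Fractional intensity reduction in (0, 1\].
#' @param atrophy_radius Lesion ball radius in voxels (>= 1).
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   population.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 24L), n_subjects = 48L,
                         n_structures = 3L, subject_jitter_sd = 0.05,
                         noise_sd = 0.02, atrophy_fraction = 0.25,
                         atrophy_magnitude = 0.5, atrophy_radius = 7,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three positive integers")
  if (n_subjects < 1L || n_structures < 1L)
    stop("n_subjects and n_structures must be >= 1")
  if (subject_jitter_sd < 0 || noise_sd < 0)
    stop("sd values must be >= 0")
  if (atrophy_fraction < 0 || atrophy_fraction > 1)
    stop("atrophy_fraction must lie in [0, 1]")
  if (!(atrophy_magnitude > 0 && atrophy_magnitude <= 1))
    stop("atrophy_magnitude must lie in (0, 1]: a magnitude of 0 produces no ",
         "detectable lesion")
  if (atrophy_radius < 1) stop("atrophy_radius must be >= 1 voxel")
  structure(list(grid_shape = grid_shape, n_subjects = as.integer(n_subjects),
                 n_structures = as.integer(n_structures),
                 subject_jitter_sd = subject_jitter_sd, noise_sd = noise_sd,
                 atrophy_fraction = atrophy_fraction,
                 atrophy_magnitude = atrophy_magnitude,
                 atrophy_radius = atrophy_radius, seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized [-1, 1] coordinate grids for a volume shape
.coord_grids <- function(shape) {
  cg <- function(n) if (n == 1L) 0 else seq(-1, 1, length.out = n)
  list(x = cg(shape[1]), y = cg(shape[2]), z = cg(shape[3]))
}

.ellipsoid_r2 <- function(shape, semi = c(0.85, 0.85, 0.8)) {
  g <- .coord_grids(shape)
  rx <- (g$x / semi[1])^2
  ry <- (g$y / semi[2])^2
  rz <- (g$z / semi[3])^2
  outer(outer(rx, ry, "+"), rz, "+")
}

.gaussian_bump <- function(shape, center, width) {
  g <- .coord_grids(shape)
  dx <- exp(-((g$x - center[1])^2) / (2 * width^2))
  dy <- exp(-((g$y - center[2])^2) / (2 * width^2))
  dz <- exp(-((g$z - center[3])^2) / (2 * width^2))
  outer(outer(dx, dy), dz)
}

.ball_mask <- function(shape, center_vox, radius) {
  di <- (seq_len(shape[1]) - center_vox[1])^2
  dj <- (seq_len(shape[2]) - center_vox[2])^2
  dk <- (seq_len(shape[3]) - center_vox[3])^2
  outer(outer(di, dj, "+"), dk, "+") <= radius^2
}

#' Generate a seeded phantom population
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_population`: a list of subjects, each
#'   with `volume` (3D array), `is_anomalous`, `truth_mask` (logical 3D array,
#'   all-`FALSE` for normal subjects), `support` (tissue mask) and
#'   `subject_id`. Attributes carry the spec, the shared lesion center and
#'   the population-level common lesion mask.
#' @examples
#' pop <- make_population(phantom_spec(n_subjects = 4, grid_shape = c(24, 24, 12)))
#' sum(vapply(pop, function(s) s$is_anomalous, logical(1)))
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)

  shape <- spec$grid_shape
  r2 <- .ellipsoid_r2(shape)
  support <- r2 <= 1
  base <- ifelse(support, 0.55 * (1 - 0.35 * r2), 0)

  # population-level structure anatomy, shared by all subjects
  centers <- matrix(stats::runif(3 * spec$n_structures, -0.45, 0.45),
                    ncol = 3L)
  widths <- stats::runif(spec$n_structures, 0.18, 0.30)
  amps <- stats::runif(spec$n_structures, 0.25, 0.45)

  # shared lesion site: a fixed interior position of the ellipsoid
  lesion_rel <- c(0.3, -0.2, 0.1)
  center_vox <- round((lesion_rel + 1) / 2 * (shape - 1)) + 1
  common_mask <- .ball_mask(shape, center_vox, spec$atrophy_radius) & support

  n_anom <- round(spec$atrophy_fraction * spec$n_subjects)
  anom <- rep(FALSE, spec$n_subjects)
  if (n_anom > 0) anom[sample.int(spec$n_subjects, n_anom)] <- TRUE

  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    vol <- base * (1 + stats::rnorm(1, sd = spec$subject_jitter_sd))
    for (k in seq_len(spec$n_structures)) {
      ck <- centers[k, ] + stats::rnorm(3, sd = spec$subject_jitter_sd)
      ak <- amps[k] * (1 + stats::rnorm(1, sd = spec$subject_jitter_sd))
      vol <- vol + ak * .gaussian_bump(shape, ck, widths[k])
    }
    vol[!support] <- 0
    vol[support] <- pmax(vol[support], 0.05)

    truth <- array(FALSE, shape)
    if (anom[s]) {
      jit <- pmin(pmax(round(stats::rnorm(3, sd = 1)), -2), 2)
      truth <- .ball_mask(shape, center_vox + jit, spec$atrophy_radius) & support
      vol[truth] <- vol[truth] * (1 - spec$atrophy_magnitude)
    } else {
      stats::rnorm(3) # keep subject RNG streams aligned across labels
    }

    if (spec$noise_sd > 0) {
      noise <- stats::rnorm(sum(support), sd = spec$noise_sd)
      vol[support] <- vol[support] + noise
    } else {
      # draw nothing: noiseless populations stay comparable across noise_sd
    }

    subjects[[s]] <- structure(list(
      volume = vol, is_anomalous = anom[s], truth_mask = truth,
      support = support, subject_id = sprintf("S%03d", s)
    ), class = "phantom_subject")
  }
  structure(subjects, class = "phantom_population", spec = spec,
            lesion_center = center_vox, common_mask = common_mask)
}

#' Deterministic volume fixtures for geometry tests
#'
#' @param shape Positive integer triple.
#' @param fill `"ramp"` (linearly increasing values), `"zeros"`, or a
#'   vectorized function of normalized coordinates `f(x, y, z)`.
#' @return A 3D array of the requested shape.
#' @examples
#' dim(make_volume_fixture(c(91, 109, 91)))
#' @export
make_volume_fixture <- function(shape, fill = "ramp") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive integers")
  n <- prod(shape)
  if (is.function(fill)) {
    g <- .coord_grids(shape)
    co <- expand.grid(x = g$x, y = g$y, z = g$z)
    vol <- array(fill(co$x, co$y, co$z), shape)
  } else {
    vol <- switch(match.arg(fill, c("ramp", "zeros")),
                  ramp = array(seq(0, 1, length.out = n), shape),
                  zeros = array(0, shape))
  }
  vol
}

#' Write a phantom population as NIfTI volumes plus a CSV sidecar
#'
#' Writes `<id>.nii.gz` per subject, `<id>_mask.nii.gz` for anomalous
#' subjects, and `subjects.csv` with columns `subject_id`, `is_anomalous`,
#' `volume`, `mask`.
#'
#' @param population A [make_population()] result.
#' @param dir Output directory (created if needed).
#' @return The sidecar CSV path, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "phantom_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(population, function(s) {
    vpath <- file.path(dir, paste0(s$subject_id, ".nii.gz"))
    RNifti::writeNifti(s$volume, vpath)
    mpath <- ""
    if (s$is_anomalous) {
      mpath <- file.path(dir, paste0(s$subject_id, "_mask.nii.gz"))
      RNifti::writeNifti(array(as.numeric(s$truth_mask), dim(s$truth_mask)),
                         mpath)
    }
    data.frame(subject_id = s$subject_id, is_anomalous = s$is_anomalous,
               volume = basename(vpath),
               mask = if (nzchar(mpath)) basename(mpath) else NA_character_)
  })
  csv <- file.path(dir, "subjects.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
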