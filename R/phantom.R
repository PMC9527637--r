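#' Configuration for the synthetic cardiomyocyte phantom
#'
#' The phantom emulates the statistical structure of volume-EM stacks of
#' cardiac muscle: myofibril bundles running along one axis with periodic
#' sarcomere banding, thin Z-disc planes at sarcomere boundaries that occupy
#' well under 1\% of the voxels, ellipsoidal mitochondria packed into the
#' inter-myofibril space, and a low-contrast noisy intensity image.
#'
#' Defaults use the textbook sarcomere period of 2 µm and a Z-disc thickness
#' of 0.1 µm. Because every sarcomere boundary carries a Z-disc, the Z-disc
#' voxel fraction equals `myofibril_fill_fraction * zdisc_thickness_um /
#' sarcomere_period_um`; the default fill fraction of 0.15 keeps the Z-disc
#' class below 1\% of all voxels, reproducing the extreme class imbalance
#' that makes Z-disc segmentation hard in real data.
#'
#' @param shape_voxels integer length 3, volume shape (z, y, x).
#' @param voxel_size_um numeric length 3 (or 1), µm per voxel (z, y, x).
#' @param sarcomere_period_um spacing of Z-disc planes along the fibril
#'   axis (x), µm.
#' @param zdisc_thickness_um thickness of each Z-disc plane, µm; must be
#'   smaller than the sarcomere period.
#' @param myofibril_fill_fraction fraction of the cross-section occupied by
#'   myofibril bundles, in (0, 1).
#' @param mito_count number of mitochondria to place.
#' @param mito_semiaxes_um ellipsoid semi-axes (z, y, x), µm.
#' @param mito_jitter relative jitter applied to each semi-axis, in \[0, 1).
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param contrast_map named numeric of mean intensities in \[0, 1\] for
#'   `background`, `mitochondria`, `myofibrils`, `zdisc`.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   volumes.
#' @return object of class `PhantomConfig`.
#' @export
phantom_config <- function(shape_voxels = c(128L, 256L, 256L),
                           voxel_size_um = c(0.02, 0.02, 0.02),
                           sarcomere_period_um = 2.0,
                           zdisc_thickness_um = 0.1,
                           myofibril_fill_fraction = 0.15,
                           mito_count = 60L,
                           mito_semiaxes_um = c(0.45, 0.30, 0.30),
                           mito_jitter = 0.25,
                           noise_sd = 0.08,
                           contrast_map = c(background = 0.55,
                                            mitochondria = 0.30,
                                            myofibrils = 0.45,
                                            zdisc = 0.15),
                           seed = 0L) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels <= 0L))
    stop("shape_voxels must be 3 positive integers (z, y, x)")
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3L)
  if (any(voxel_size_um <= 0)) stop("voxel_size_um must be positive")
  if (sarcomere_period_um <= 0 || zdisc_thickness_um <= 0)
    stop("sarcomere period and Z-disc thickness must be positive")
  if (zdisc_thickness_um >= sarcomere_period_um)
    stop("zdisc_thickness_um must be smaller than sarcomere_period_um")
  if (myofibril_fill_fraction <= 0 || myofibril_fill_fraction >= 1)
    stop("myofibril_fill_fraction must lie in (0, 1)")
  if (mito_count < 0) stop("mito_count must be non-negative")
  if (any(mito_semiaxes_um <= 0)) stop("mito_semiaxes_um must be positive")
  if (mito_jitter < 0 || mito_jitter >= 1)
    stop("mito_jitter must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  cm <- contrast_map[c("background", "mitochondria", "myofibrils", "zdisc")]
  if (any(is.na(cm)) || any(cm < 0) || any(cm > 1))
    stop("contrast_map needs background/mitochondria/myofibrils/zdisc in [0,1]")
  structure(list(shape_voxels = shape_voxels,
                 voxel_size_um = voxel_size_um,
                 sarcomere_period_um = sarcomere_period_um,
                 zdisc_thickness_um = zdisc_thickness_um,
                 myofibril_fill_fraction = myofibril_fill_fraction,
                 mito_count = as.integer(mito_count),
                 mito_semiaxes_um = as.numeric(mito_semiaxes_um),
                 mito_jitter = mito_jitter,
                 noise_sd = noise_sd,
                 contrast_map = cm,
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

#' Generate a synthetic cardiomyocyte EM volume with ground-truth labels
#'
#' Builds the label volume first — myofibril bundles (class 2) as bands
#' across the cross-section, Z-disc planes (class 3) every sarcomere period
#' along the fibril axis, mitochondria (class 1) as jittered ellipsoids
#' rejection-sampled into the inter-myofibril space (never overwriting
#' myofibrils or Z-discs) — then renders intensity as the class mean
#' intensity plus clipped Gaussian noise.
#'
#' @param config a [phantom_config()].
#' @return object of class `PhantomVolume`: list with `intensity`
#'   (`IntensityVolume`), `labels` (`LabelVolume`) and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(shape_voxels = c(8, 64, 64),
#'                                       voxel_size_um = 0.05,
#'                                       mito_count = 2))
#' mean(vol_data(ph$labels) == 3)  # sparse Z-disc class
#' @export
generate_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "PhantomConfig"))
    stop("config must be a PhantomConfig")
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(config) {
  d <- config$shape_voxels
  vs <- config$voxel_size_um
  labels <- array(0L, d)

  ## myofibril bands: stripes along y, extended over all z and x
  w0 <- max(1L, as.integer(round(0.5 / vs[2L])))      # ~0.5 um bundle width
  Y <- d[2L]
  k <- max(1L, as.integer(round(config$myofibril_fill_fraction * Y / w0)))
  w <- max(1L, as.integer(round(config$myofibril_fill_fraction * Y / k)))
  w <- min(w, Y)
  gap <- (Y - k * w) / (k + 1)
  starts <- round(gap * seq_len(k) + w * (seq_len(k) - 1L)) + 1L
  jit <- if (gap > 2) sample.int(max(1L, floor(gap / 4)), k, replace = TRUE) -
    ceiling(max(1L, floor(gap / 4)) / 2) else rep(0L, k)
  starts <- pmin(pmax(starts + jit, 1L), Y - w + 1L)
  myo_y <- sort(unique(unlist(lapply(starts, function(s) s:(s + w - 1L)))))

  ## Z-disc planes every sarcomere period along x, inside myofibrils only
  period <- max(2L, as.integer(round(config$sarcomere_period_um / vs[3L])))
  thick <- max(1L, as.integer(round(config$zdisc_thickness_um / vs[3L])))
  thick <- min(thick, period - 1L)
  phase <- sample.int(period, 1L) - 1L
  x_idx <- seq_len(d[3L])
  zd_x <- x_idx[((x_idx - 1L + phase) %% period) < thick]
  labels[, myo_y, ] <- 2L
  if (length(zd_x)) labels[, myo_y, zd_x] <- 3L

  ## mitochondria: axis-aligned ellipsoids in the inter-myofibril space
  semi_vox <- config$mito_semiaxes_um / vs
  placed <- 0L
  if (config$mito_count > 0L) {
    for (m in seq_len(config$mito_count)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        s <- semi_vox * stats::runif(3L, 1 - config$mito_jitter,
                                     1 + config$mito_jitter)
        s <- pmax(s, 1)
        lo <- ceiling(s) + 1
        hi <- d - ceiling(s)
        if (any(hi < lo)) break
        ctr <- vapply(1:3, function(a) {
          lo[a] + stats::runif(1) * (hi[a] - lo[a])
        }, numeric(1))
        rng <- lapply(1:3, function(a) {
          max(1L, floor(ctr[a] - s[a])):min(d[a], ceiling(ctr[a] + s[a]))
        })
        ez <- ((rng[[1L]] - ctr[1L]) / s[1L])^2
        ey <- ((rng[[2L]] - ctr[2L]) / s[2L])^2
        ex <- ((rng[[3L]] - ctr[3L]) / s[3L])^2
        inside <- outer(outer(ez, ey, "+"), ex, "+") <= 1
        sub <- labels[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
        if (all(sub[inside] == 0L)) {
          sub[inside] <- 1L
          labels[rng[[1L]], rng[[2L]], rng[[3L]]] <- sub
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(
          "mitochondrion placement failed after 1000 retries (placed %d of %d)",
          placed, config$mito_count))
      placed <- placed + 1L
    }
  }

  means <- unname(config$contrast_map)[labels + 1L]
  intensity <- means + stats::rnorm(length(labels), 0, config$noise_sd)
  intensity <- array(pmin(pmax(intensity, 0), 1), d)

  structure(list(intensity = intensity_volume(intensity, vs),
                 labels = label_volume(labels, vs),
                 config = config),
            class = "PhantomVolume")
}

#' @export
print.PhantomVolume <- function(x, ...) {
  cat("<PhantomVolume>\n")
  print(x$labels)
  frac <- mean(vol_data(x$labels) == 3L)
  cat(sprintf("  Z-disc voxel fraction: %.3f%%\n", 100 * frac))
  invisible(x)
}

#' Corrupt a label volume by random class flips
#'
#' Reassigns exactly `round(flip_rate * n_voxels)` voxels (chosen uniformly
#' without replacement) to a uniformly random *different* class from
#' `0:(n_classes - 1)`. Used to manufacture imperfect predictions with a
#' known error rate for metric tests.
#'
#' @param labels `LabelVolume` or integer array.
#' @param flip_rate fraction of voxels to reassign, in \[0, 1\].
#' @param seed integer RNG seed.
#' @param n_classes size of the class alphabet (default 4).
#' @return same type as `labels`.
#' @export
degrade_labels <- function(labels, flip_rate, seed = 0L, n_classes = 4L) {
  if (!is.numeric(flip_rate) || length(flip_rate) != 1L ||
      is.na(flip_rate) || flip_rate < 0 || flip_rate > 1)
    stop("flip_rate must be a single value in [0, 1]")
  arr <- vol_data(labels)
  n <- length(arr)
  n_flip <- as.integer(round(flip_rate * n))
  if (n_flip > 0L) {
    arr <- with_seed(seed, {
      idx <- sample.int(n, n_flip)
      offs <- sample.int(n_classes - 1L, n_flip, replace = TRUE)
      arr[idx] <- (arr[idx] + offs) %% n_classes
      arr
    })
  }
  if (inherits(labels, "LabelVolume"))
    label_volume(arr, labels$voxel_size_um)
  else arr
}

#' Build a smooth slice sequence by translating a base slice
#'
#' Slice `i` (0-based) is `base_slice` shifted by `i * step_voxels` columns
#' with zero fill, so consecutive slices have small, equal Jaccard distance
#' while distant slices drift apart — a controlled fixture for the
#' slice-ordering stage.
#'
#' @param base_slice 2D integer matrix.
#' @param n number of slices (>= 2).
#' @param step_voxels shift per slice in voxels (may be 0).
#' @return a [slice_stack()].
#' @export
translate_slice_sequence <- function(base_slice, n, step_voxels) {
  if (!is.matrix(base_slice)) stop("base_slice must be a 2D matrix")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be at least 2")
  step_voxels <- as.integer(step_voxels)
  nc <- ncol(base_slice)
  if (abs((n - 1L) * step_voxels) >= nc)
    stop("total shift exceeds the slice extent")
  shift_cols <- function(m, s) {
    out <- matrix(0L, nrow(m), ncol(m))
    if (s >= 0) {
      if (s < ncol(m)) out[, (s + 1L):ncol(m)] <- m[, 1L:(ncol(m) - s)]
    } else {
      s <- -s
      if (s < ncol(m)) out[, 1L:(ncol(m) - s)] <- m[, (s + 1L):ncol(m)]
    }
    out
  }
  slice_stack(lapply(0:(n - 1L),
                     function(i) shift_cols(base_slice, i * step_voxels)))
}
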