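#' Write a volume to multi-page TIFF with a JSON sidecar
#'
#' Label volumes are written as 8-bit pages (class ids 0..255) and round-trip
#' bit-identically; intensity volumes are written as 32-bit float pages.
#' Voxel size (µm) and the volume kind are stored in `<path>.json` next to
#' the TIFF and in the TIFF resolution tags.
#'
#' @param vol `IntensityVolume` or `LabelVolume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "Volume"))
    stop("vol must be an IntensityVolume or LabelVolume")
  arr <- vol$data
  pages <- lapply(seq_len(dim(arr)[1L]), function(i) arr[i, , ])
  kind <- if (inherits(vol, "LabelVolume")) "labels" else "intensity"
  if (kind == "labels") {
    if (max(arr) > 255L) stop("label values exceed 8-bit range")
    tiff::writeTIFF(lapply(pages, function(p) p / 255), path,
                    bits.per.sample = 8L)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(
    list(kind = kind, voxel_size_um = vol$voxel_size_um,
         shape_voxels = dim(arr)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a volume from multi-page TIFF
#'
#' Reads all pages into a (z, y, x) array. The kind (`labels` vs
#' `intensity`) and voxel size come from the JSON sidecar when present and
#' can be overridden; without metadata, `kind = "auto"` treats 8-bit data
#' whose rescaled values are integers as labels.
#'
#' @param path TIFF path.
#' @param kind `"auto"`, `"intensity"` or `"labels"`.
#' @param voxel_size_um optional voxel-size override, µm (z, y, x).
#' @return `IntensityVolume` or `LabelVolume`.
#' @export
read_volume <- function(path, kind = c("auto", "intensity", "labels"),
                        voxel_size_um = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (kind == "auto")
    kind <- if (!is.null(meta$kind)) meta$kind else {
      v <- pages[[1L]] * 255
      if (max(abs(v - round(v))) < 1e-9 && max(v) <= 64) "labels" else "intensity"
    }
  if (is.null(voxel_size_um))
    voxel_size_um <- if (!is.null(meta$voxel_size_um)) meta$voxel_size_um
      else c(1, 1, 1)
  d <- c(length(pages), dim(pages[[1L]]))
  arr <- array(0, d)
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (kind == "labels") {
    lab <- round(arr * 255)
    if (max(abs(arr * 255 - lab)) > 1e-6)
      stop("non-integer pixel data cannot be read as labels")
    label_volume(array(as.integer(lab), d), voxel_size_um)
  } else {
    intensity_volume(arr, voxel_size_um)
  }
}

#' Extract non-overlapping random 2D patches from a volume
#'
#' Samples `n` square patches of side `patch_size` from the (y, x) planes of
#' a volume; footprints never overlap within a slice. Placement first tries
#' rejection sampling of free positions and falls back to a seeded random
#' subset of the aligned grid, so any request within capacity succeeds.
#' Capacity per slice is `floor(Y/patch_size) * floor(X/patch_size)` (the
#' maximum number of disjoint axis-aligned squares); requests beyond total
#' capacity raise an error.
#'
#' @param volume `Volume` or 3D array.
#' @param patch_size patch side length, voxels.
#' @param n number of patches.
#' @param policy placement policy; only `"random_nonoverlap"` is defined.
#' @param seed RNG seed.
#' @return data.frame with columns `slice`, `y`, `x` (1-based top-left
#'   corners), one row per patch, in placement order.
#' @export
extract_patches <- function(volume, patch_size, n,
                            policy = "random_nonoverlap", seed = 0L) {
  policy <- match.arg(policy, "random_nonoverlap")
  arr <- vol_data(volume)
  d <- dim(arr)
  ps <- as.integer(patch_size)
  if (ps > d[2L] || ps > d[3L])
    stop("patch_size exceeds the slice extents")
  cap_per_slice <- (d[2L] %/% ps) * (d[3L] %/% ps)
  if (n > cap_per_slice * d[1L])
    stop(sprintf(
      "cannot place %d non-overlapping %dx%d patches: capacity is %d",
      n, ps, ps, cap_per_slice * d[1L]))
  with_seed(seed, {
    placed <- data.frame(slice = integer(), y = integer(), x = integer())
    overlaps <- function(z, y, x) {
      same <- placed[placed$slice == z, , drop = FALSE]
      any(abs(same$y - y) < ps & abs(same$x - x) < ps)
    }
    tries <- 0L
    while (nrow(placed) < n && tries < 200L * n) {
      z <- sample.int(d[1L], 1L)
      y <- sample.int(d[2L] - ps + 1L, 1L)
      x <- sample.int(d[3L] - ps + 1L, 1L)
      if (!overlaps(z, y, x))
        placed <- rbind(placed, data.frame(slice = z, y = y, x = x))
      tries <- tries + 1L
    }
    if (nrow(placed) < n) {
      ## dense request: restart from a seeded subset of the aligned grid,
      ## which always succeeds within capacity
      grid <- expand.grid(slice = seq_len(d[1L]),
                          y = seq(1L, d[2L] - ps + 1L, by = ps),
                          x = seq(1L, d[3L] - ps + 1L, by = ps))
      placed <- grid[sample.int(nrow(grid), n), , drop = FALSE]
    }
    rownames(placed) <- NULL
    attr(placed, "patch_size") <- ps
    placed
  })
}

#' Cut one patch out of a volume
#'
#' @param volume `Volume` or 3D array.
#' @param footprint one row of the data.frame returned by
#'   [extract_patches()] (or a list with `slice`, `y`, `x`).
#' @param patch_size patch side; defaults to the `patch_size` attribute of
#'   the footprint table.
#' @return 2D matrix.
#' @export
crop_patch <- function(volume, footprint, patch_size = NULL) {
  arr <- vol_data(volume)
  ps <- patch_size %||% attr(footprint, "patch_size")
  if (is.null(ps)) stop("patch_size not given and not found on footprint")
  arr[footprint$slice[1L],
      footprint$y[1L]:(footprint$y[1L] + ps - 1L),
      footprint$x[1L]:(footprint$x[1L] + ps - 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' K-fold train/validation/test splits with exact counts
#'
#' Permutes the ids once under `seed`, then for fold `k` takes the k-th
#' circular block of `counts[2]` ids as validation, the following
#' `counts[3]` as test, and the remainder as training — so each fold
#' respects the requested counts exactly and validation blocks are disjoint
#' across folds whenever `n_folds * counts[2] <= length(patch_ids)`.
#'
#' @param patch_ids vector of patch identifiers.
#' @param counts integer length 3: (train, val, test); must sum to
#'   `length(patch_ids)`.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return list of `DatasetSplit` objects (one per fold), each a list with
#'   `train`, `val`, `test`, `fold_index`, `n_folds`, `seed`.
#' @export
make_split <- function(patch_ids, counts, n_folds = 1L, seed = 0L) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 0L))
    stop("counts must be 3 non-negative integers (train, val, test)")
  n <- length(patch_ids)
  if (sum(counts) != n)
    stop(sprintf("counts sum to %d but there are %d patch ids",
                 sum(counts), n))
  perm <- with_seed(seed, patch_ids[sample.int(n)])
  lapply(seq_len(n_folds), function(k) {
    rot <- c(perm, perm)  # circular blocks
    off <- (k - 1L) * max(counts[2L], 1L)
    take <- function(start, len)
      if (len == 0L) perm[0L] else rot[((start + seq_len(len) - 1L) %% n) + 1L]
    val <- take(off, counts[2L])
    test <- take(off + counts[2L], counts[3L])
    train <- setdiff(perm, c(val, test))
    structure(list(train = train, val = val, test = test,
                   fold_index = k, n_folds = n_folds, seed = seed),
              class = "DatasetSplit")
  })
}

#' Build consecutive slice-pair records for conditional GAN training
#'
#' Record `i` pairs slice `i` with slice `i + 1` and carries a one-hot
#' `pair_label` of length `length(stack) - 1` identifying the pair's
#' position in the stack, so the generator can be conditioned on through-
#' plane position. Records are returned in stack order (training consumes
#' them unshuffled). Pairs that span a missing (`NULL`) slice are dropped
#' with a warning.
#'
#' @param stack a [slice_stack()] of length >= 2.
#' @return list of `SlicePairRecord`s: `slice_a`, `slice_b`, `pair_index`,
#'   `pair_label`.
#' @export
build_slice_pair_records <- function(stack) {
  if (!inherits(stack, "SliceStack")) stack <- slice_stack(stack)
  n <- length(stack)
  if (n < 2L) stop("stack must contain at least 2 slices")
  recs <- list()
  dropped <- 0L
  for (i in seq_len(n - 1L)) {
    a <- stack[[i]]
    b <- stack[[i + 1L]]
    if (is.null(a) || is.null(b)) {
      dropped <- dropped + 1L
      next
    }
    lab <- numeric(n - 1L)
    lab[i] <- 1
    recs[[length(recs) + 1L]] <- structure(
      list(slice_a = a, slice_b = b, pair_index = i, pair_label = lab),
      class = "SlicePairRecord")
  }
  if (dropped > 0L)
    warning(sprintf("%d slice pair(s) spanning missing slices were dropped",
                    dropped))
  recs
}
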