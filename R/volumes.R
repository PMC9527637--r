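#' @keywords internal
"_PACKAGE"

#' 3D volume containers
#'
#' `intensity_volume()` wraps a 3D numeric array of grayscale values in
#' \[0, 1\]; `label_volume()` wraps a 3D integer array of class ids
#' (0 = background, 1 = mitochondria, 2 = myofibrils, 3 = Z-disc).
#' Both carry a per-axis voxel size in micrometres, ordered (z, y, x) to
#' match the array dimensions.
#'
#' @param data 3D array (z, y, x).
#' @param voxel_size_um numeric length 3 (or 1, recycled), micrometres per
#'   voxel along (z, y, x).
#' @return An object of class `IntensityVolume` or `LabelVolume`.
#' @export
intensity_volume <- function(data, voxel_size_um = c(1, 1, 1)) {
  data <- as_volume_array(data)
  storage.mode(data) <- "double"
  new_volume(data, voxel_size_um, "IntensityVolume")
}

#' @rdname intensity_volume
#' @export
label_volume <- function(data, voxel_size_um = c(1, 1, 1)) {
  data <- as_volume_array(data)
  if (any(data != round(data)))
    stop("label data must be integer-valued")
  storage.mode(data) <- "integer"
  if (any(data < 0L))
    stop("label values must be non-negative")
  new_volume(data, voxel_size_um, "LabelVolume")
}

new_volume <- function(data, voxel_size_um, class) {
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3L)
  if (any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("voxel_size_um must be positive and finite")
  structure(list(data = data, voxel_size_um = voxel_size_um),
            class = c(class, "Volume"))
}

as_volume_array <- function(data) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (z, y, x)")
  data
}

#' Extract the raw array from a volume (or pass an array through)
#' @param x a `Volume` or a plain array.
#' @return the underlying array.
#' @export
vol_data <- function(x) {
  if (inherits(x, "Volume")) x$data else x
}

vol_voxel_size <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "Volume")) x$voxel_size_um else rep_len(default, 3L)
}

#' @export
print.Volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels (z,y,x), voxel size %s um\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              paste(signif(x$voxel_size_um, 4), collapse = " x ")))
  if (inherits(x, "LabelVolume")) {
    tab <- table(x$data)
    cat("  classes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.Volume <- function(x) dim(x$data)

#' Ordered stack of 2D label slices
#'
#' A `SliceStack` is a list of equally sized 2D integer matrices, the unit
#' that the slice-ordering and GAN-sampling steps exchange. Slices that are
#' `NULL` mark missing/unusable planes (dropped when building training
#' pair records).
#'
#' @param slices list of 2D integer matrices (or a 3D array, split along z).
#' @return object of class `SliceStack`.
#' @export
slice_stack <- function(slices) {
  if (is.array(slices) && length(dim(slices)) == 3L)
    slices <- lapply(seq_len(dim(slices)[1L]), function(i) slices[i, , ])
  if (!is.list(slices) || length(slices) < 1L)
    stop("slices must be a non-empty list of 2D matrices")
  dims <- NULL
  for (s in slices) {
    if (is.null(s)) next
    if (!is.matrix(s)) stop("each slice must be a 2D matrix or NULL")
    if (is.null(dims)) dims <- dim(s)
    if (!identical(dim(s), dims)) stop("all slices must share one shape")
  }
  structure(slices, class = "SliceStack")
}

#' @export
print.SliceStack <- function(x, ...) {
  n_missing <- sum(vapply(x, is.null, logical(1)))
  d <- dim(x[[which(!vapply(x, is.null, logical(1)))[1L]]])
  cat(sprintf("<SliceStack> %d slices of %d x %d (%d missing)\n",
              length(x), d[1L], d[2L], n_missing))
  invisible(x)
}

# Run expr with a locally seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
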