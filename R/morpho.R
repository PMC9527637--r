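#' Label 3D connected components of one class
#'
#' Breadth-first labelling of the voxels equal to `class_id` under 6- or
#' 26-connectivity. Component ids are assigned deterministically in array
#' scan order (column-major linear index of each component's first voxel),
#' so id 1 is always the component encountered first.
#'
#' @param mask `LabelVolume` or integer array.
#' @param class_id class to extract.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of component ids (0 = not in class), with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, class_id, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  arr <- vol_data(mask)
  d <- dim(arr)
  fg <- which(arr == class_id)
  comp <- array(0L, d)
  if (length(fg) == 0L) {
    attr(comp, "n_components") <- 0L
    return(comp)
  }
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]
  if (connectivity == 6L)
    offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  nzy <- d[1L] * d[2L]
  in_class <- array(FALSE, d)
  in_class[fg] <- TRUE
  cur <- 0L
  for (seed in fg) {
    if (comp[seed] != 0L) next
    cur <- cur + 1L
    comp[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      i0 <- frontier - 1L
      z <- i0 %% d[1L]
      y <- (i0 %/% d[1L]) %% d[2L]
      x <- i0 %/% nzy
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        zz <- z + offs[o, 1L]; yy <- y + offs[o, 2L]; xx <- x + offs[o, 3L]
        keep <- zz >= 0L & zz < d[1L] & yy >= 0L & yy < d[2L] &
          xx >= 0L & xx < d[3L]
        if (!any(keep)) next
        lin <- zz[keep] + d[1L] * yy[keep] + nzy * xx[keep] + 1L
        lin <- lin[in_class[lin] & comp[lin] == 0L]
        if (length(lin)) {
          comp[lin] <- cur
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  attr(comp, "n_components") <- cur
  comp
}

#' Per-component 3D shape statistics
#'
#' For each connected component computes volume (voxels and µm³), surface
#' area S (µm²), surface-area-to-volume ratio, compactness
#' \eqn{C = 36\pi V^2 / S^3}, sphericity \eqn{\psi = C^{1/3}}, elongation
#' \eqn{\sqrt{\lambda_1/\lambda_2}}, flatness \eqn{\sqrt{\lambda_2/\lambda_3}}
#' (with \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3} the principal second
#' moments of the voxel coordinates in µm) and spareness, the ratio of the
#' component volume to that of its covariance-matched ellipsoid (semi-axes
#' \eqn{\sqrt{5\lambda_i}}). Components of fewer than `min_voxels` voxels
#' are kept but flagged `unreliable`.
#'
#' Surface estimators: `"coarea"` (default) integrates the gradient
#' magnitude of a Gaussian-smoothed indicator function — for a smoothed
#' binary interface the co-area formula makes this integral equal the
#' interface area, with a curvature bias of order \eqn{(\sigma/r)^2};
#' `"voxel_faces"` counts exposed voxel faces, which is simple but biased
#' high (about 1.5x on a ball) and will depress compactness/sphericity.
#'
#' @param comp component-id array from [label_components()] (or a logical /
#'   0-1 array treated as a single foreground whose components are taken
#'   as-is via ids).
#' @param voxel_size_um voxel size (z, y, x) in µm.
#' @param surface_estimator `"coarea"` or `"voxel_faces"`.
#' @param min_voxels reliability threshold (default 4).
#' @param smooth_sigma Gaussian sigma in voxels for the coarea estimator.
#' @return `ShapeStatsTable` data.frame, one row per component.
#' @export
shape_stats <- function(comp, voxel_size_um = c(1, 1, 1),
                        surface_estimator = c("coarea", "voxel_faces"),
                        min_voxels = 4L, smooth_sigma = 0.9) {
  surface_estimator <- match.arg(surface_estimator)
  arr <- vol_data(comp)
  vs <- rep_len(as.numeric(voxel_size_um), 3L)
  ids <- setdiff(sort(unique(as.vector(arr))), 0L)
  if (length(ids) == 0L) stop("no components present")
  vox_vol <- prod(vs)
  rows <- lapply(ids, function(id) {
    idx <- which(arr == id)
    n <- length(idx)
    co <- arrayInd(idx, dim(arr))           # (z, y, x), voxel units
    co_um <- sweep(co, 2L, vs, `*`)
    V <- n * vox_vol
    S <- component_surface(arr == id, vs, surface_estimator, smooth_sigma)
    cov <- stats::cov(co_um) * (n - 1) / max(n, 1)   # population moments
    if (n < 2L) cov <- diag(0, 3)
    lam <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
                     0), decreasing = TRUE)
    elong <- if (lam[2L] > 0) sqrt(lam[1L] / lam[2L]) else NaN
    flat <- if (lam[3L] > 0) sqrt(lam[2L] / lam[3L]) else NaN
    semi <- sqrt(5 * lam)
    ell_vol <- 4 / 3 * pi * prod(semi)
    spare <- if (ell_vol > 0) V / ell_vol else NaN
    C <- 36 * pi * V^2 / S^3
    data.frame(component = id, n_voxels = n, volume_um3 = V,
               surface_um2 = S, sa_to_v = S / V,
               compactness = C, sphericity = C^(1 / 3),
               elongation = elong, flatness = flat, spareness = spare,
               unreliable = n < min_voxels)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ShapeStatsTable", class(out))
  out
}

component_surface <- function(mask, vs, estimator, sigma = 0.9) {
  d <- dim(mask)
  if (estimator == "voxel_faces") {
    face_area <- c(vs[2L] * vs[3L], vs[1L] * vs[3L], vs[1L] * vs[2L])
    S <- 0
    for (ax in 1:3) {
      n <- d[ax]
      idx_a <- lapply(d, seq_len); idx_a[[ax]] <- 1L:max(n - 1L, 1L)
      idx_b <- lapply(d, seq_len); idx_b[[ax]] <- if (n > 1L) 2L:n else 1L
      a <- do.call(`[`, c(list(mask), idx_a, list(drop = FALSE)))
      b <- do.call(`[`, c(list(mask), idx_b, list(drop = FALSE)))
      inner <- if (n > 1L) sum(a != b) else 0
      ## faces on the array border
      edge1 <- lapply(d, seq_len); edge1[[ax]] <- 1L
      edge2 <- lapply(d, seq_len); edge2[[ax]] <- n
      border <- sum(do.call(`[`, c(list(mask), edge1))) +
        sum(do.call(`[`, c(list(mask), edge2)))
      S <- S + (inner + border) * face_area[ax]
    }
    return(S)
  }
  ## coarea: pad, smooth the indicator, integrate |grad|
  pad <- as.integer(ceiling(3 * sigma)) + 2L
  dp <- d + 2L * pad
  u <- array(0, dp)
  u[pad + seq_len(d[1L]), pad + seq_len(d[2L]), pad + seq_len(d[3L])] <-
    as.numeric(mask)
  u <- gauss_smooth3(u, sigma)
  ## central differences; the zero padding makes the borders flat, so the
  ## replicated-edge stencil contributes nothing there
  g2 <- array(0, dp)
  for (ax in 1:3) {
    n <- dp[ax]
    idx_lo <- lapply(dp, seq_len); idx_lo[[ax]] <- c(1L, 1L:(n - 1L))
    idx_hi <- lapply(dp, seq_len); idx_hi[[ax]] <- c(2L:n, n)
    lo <- do.call(`[`, c(list(u), idx_lo, list(drop = FALSE)))
    hi <- do.call(`[`, c(list(u), idx_hi, list(drop = FALSE)))
    g2 <- g2 + ((hi - lo) / (2 * vs[ax]))^2
  }
  sum(sqrt(g2)) * prod(vs)
}

## separable Gaussian smoothing of a 3D array (sigma in voxels)
gauss_smooth3 <- function(u, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(u)
  ## convolve along axis 1 by matricizing: dims (d1, d2*d3)
  conv_axis1 <- function(a) {
    dd <- dim(a)
    m <- matrix(a, dd[1L], prod(dd[-1L]))
    out <- matrix(0, dd[1L], ncol(m))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      src <- seq_len(dd[1L]) + off
      ok <- src >= 1L & src <= dd[1L]
      out[ok, ] <- out[ok, ] + k[i] * m[src[ok], ]
    }
    array(out, dd)
  }
  u <- conv_axis1(u)
  u <- aperm(conv_axis1(aperm(u, c(2, 1, 3))), c(2, 1, 3))
  aperm(conv_axis1(aperm(u, c(3, 2, 1))), c(3, 2, 1))
}

#' Sliding-kernel mitochondria/myofibril density map
#'
#' Slides a physical window (default 4 µm per axis) across the volume with
#' a fixed stride (default 0.4 µm) and records, for every fully interior
#' window, the ratio of mitochondria voxels (class `num_class`) to
#' myofibril voxels (class `den_class`). Windows containing no myofibril
#' voxels are undefined and stored as `NA` (their count is reported).
#'
#' @param labels `LabelVolume` (voxel size required) or array plus
#'   `voxel_size_um`.
#' @param kernel_um window edge length(s) in µm (length 1 or 3).
#' @param stride_um stride in µm (length 1 or 3).
#' @param num_class,den_class numerator/denominator classes (default 1, 2).
#' @param voxel_size_um override when `labels` is a bare array.
#' @return object of class `DensityMap`: list with `map` (3D array of
#'   ratios), `kernel_vox`, `stride_vox`, `origins` (per-axis 1-based
#'   window starts), `n_undefined`.
#' @export
density_map <- function(labels, kernel_um = 4, stride_um = 0.4,
                        num_class = 1L, den_class = 2L,
                        voxel_size_um = NULL) {
  arr <- vol_data(labels)
  vs <- if (!is.null(voxel_size_um)) rep_len(voxel_size_um, 3L)
    else vol_voxel_size(labels)
  d <- dim(arr)
  kv <- pmax(1L, as.integer(round(rep_len(kernel_um, 3L) / vs)))
  sv <- pmax(1L, as.integer(round(rep_len(stride_um, 3L) / vs)))
  if (any(kv > d)) stop("kernel is larger than the volume")
  origins <- lapply(1:3, function(ax) seq(1L, d[ax] - kv[ax] + 1L, by = sv[ax]))
  ## integral image with zero padding on the low side
  integral3 <- function(mask) {
    a <- array(0, d + 1L)
    a[-1L, -1L, -1L] <- mask * 1
    a <- apply(a, c(2, 3), cumsum)
    a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
    aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
  }
  win_sum <- function(I) {
    o <- origins
    lo <- lapply(1:3, function(ax) o[[ax]])            # index into I (=pos)
    hi <- lapply(1:3, function(ax) o[[ax]] + kv[ax])
    I[hi[[1L]], hi[[2L]], hi[[3L]], drop = FALSE] -
      I[lo[[1L]], hi[[2L]], hi[[3L]], drop = FALSE] -
      I[hi[[1L]], lo[[2L]], hi[[3L]], drop = FALSE] -
      I[hi[[1L]], hi[[2L]], lo[[3L]], drop = FALSE] +
      I[lo[[1L]], lo[[2L]], hi[[3L]], drop = FALSE] +
      I[lo[[1L]], hi[[2L]], lo[[3L]], drop = FALSE] +
      I[hi[[1L]], lo[[2L]], lo[[3L]], drop = FALSE] -
      I[lo[[1L]], lo[[2L]], lo[[3L]], drop = FALSE]
  }
  In <- integral3(arr == num_class)
  Id <- integral3(arr == den_class)
  num <- win_sum(In)
  den <- win_sum(Id)
  map <- num / den
  map[den == 0] <- NA_real_
  structure(list(map = map, kernel_um = rep_len(kernel_um, 3L),
                 stride_um = rep_len(stride_um, 3L),
                 kernel_vox = kv, stride_vox = sv, origins = origins,
                 n_undefined = sum(den == 0)),
            class = "DensityMap")
}

#' Compare two samples of a shape metric
#'
#' One-way ANOVA for equality of means (`F`, `p`, eta-squared effect size)
#' and an F-ratio test for equality of variances, as used to ask whether
#' generated and segmented volumes share shape-metric distributions.
#'
#' @param sample_a,sample_b numeric vectors (length >= 2, NA dropped).
#' @return list with `f`, `p`, `eta_sq`, `var_f`, `var_p`, `n` and a
#'   `degenerate` flag (both samples constant).
#' @export
compare_distributions <- function(sample_a, sample_b) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 finite values per sample")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(f = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                eta_sq = NA_real_, var_f = NaN, var_p = NaN,
                n = c(length(a), length(b)), degenerate = TRUE))
  }
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  x <- c(a, b)
  fit <- stats::anova(stats::lm(x ~ g))
  ssb <- fit[["Sum Sq"]][1L]
  sst <- sum(fit[["Sum Sq"]])
  vt <- stats::var.test(a, b)
  list(f = fit[["F value"]][1L], p = fit[["Pr(>F)"]][1L],
       eta_sq = ssb / sst,
       var_f = unname(vt$statistic), var_p = vt$p.value,
       n = c(length(a), length(b)), degenerate = FALSE)
}

#' Pairwise Jaccard distances between whole volumes
#'
#' @param volumes list of `LabelVolume`s/arrays of identical shape.
#' @param mode passed to [jaccard_distance()].
#' @return symmetric matrix with zero diagonal.
#' @export
mutual_volume_jaccard <- function(volumes,
                                  mode = c("per_class_mean", "foreground")) {
  mode <- match.arg(mode)
  k <- length(volumes)
  if (k < 2L) stop("need at least 2 volumes")
  M <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    M[i, j] <- M[j, i] <- jaccard_distance(volumes[[i]], volumes[[j]], mode)
  }
  M
}
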