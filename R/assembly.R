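#' Jaccard distance between two label arrays
#'
#' `foreground` mode compares the binarized (label > 0) masks:
#' `1 - |A ∩ B| / |A ∪ B|`. `per_class_mean` averages the per-class
#' distances over all nonzero classes present in either array (unweighted).
#' Two empty masks have distance 0 by convention.
#'
#' @param a,b label arrays (2D or 3D) or `LabelVolume`s of identical shape.
#' @param mode `"per_class_mean"` (default) or `"foreground"`.
#' @return scalar in \[0, 1\].
#' @export
jaccard_distance <- function(a, b, mode = c("per_class_mean", "foreground")) {
  mode <- match.arg(mode)
  a <- vol_data(a)
  b <- vol_data(b)
  if (!identical(dim(a), dim(b)))
    stop("arrays must have identical shape")
  one <- function(ma, mb) {
    uni <- sum(ma | mb)
    if (uni == 0) return(0)
    1 - sum(ma & mb) / uni
  }
  if (mode == "foreground") return(one(a > 0, b > 0))
  classes <- sort(setdiff(unique(c(a[a > 0], b[b > 0])), 0))
  if (length(classes) == 0L) return(0)
  mean(vapply(classes, function(k) one(a == k, b == k), numeric(1)))
}

#' Order slices to minimize total consecutive Jaccard distance
#'
#' Finds a linear order of the slices minimizing
#' \eqn{\sum_i d(s_{\pi(i)}, s_{\pi(i+1)})} (an open path, not a cycle).
#' `method = "exhaustive"` returns a certified global minimum via
#' Held–Karp dynamic programming over all subsets (equivalent to scanning
#' every permutation; limited to 10 slices) and, among all minimizers,
#' the lexicographically smallest permutation — which also resolves the
#' reversal degeneracy in favour of the smaller first index.
#' `method = "greedy"` seeds the chain with the globally closest pair and
#' repeatedly appends the nearest unused slice to either end (ties broken
#' toward smaller indices); it scales to long stacks but is not optimal.
#'
#' @param slices a [slice_stack()] or list of 2D label matrices (>= 2).
#' @param method `"greedy"` or `"exhaustive"`.
#' @param mode Jaccard mode passed to [jaccard_distance()].
#' @return object of class `OrderingResult`: list with `permutation`
#'   (1-based slice indices), `total_cost`, `method`, `mode` and the
#'   pairwise `distance_matrix`.
#' @export
order_slices <- function(slices, method = c("greedy", "exhaustive"),
                         mode = c("per_class_mean", "foreground")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (!inherits(slices, "SliceStack")) slices <- slice_stack(slices)
  n <- length(slices)
  if (n < 2L) stop("need at least 2 slices")
  if (any(vapply(slices, is.null, logical(1))))
    stop("cannot order a stack with missing slices")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- jaccard_distance(slices[[i]], slices[[j]], mode)
  }
  perm <- if (method == "exhaustive") {
    if (n > 10L)
      stop("exhaustive ordering is limited to 10 slices; use method = \"greedy\"")
    order_exact(D)
  } else {
    order_greedy(D)
  }
  structure(list(permutation = perm,
                 total_cost = path_cost(D, perm),
                 method = method, mode = mode,
                 distance_matrix = D),
            class = "OrderingResult")
}

path_cost <- function(D, perm) {
  n <- length(perm)
  sum(D[cbind(perm[-n], perm[-1L])])
}

## Exact open-path minimization (Held-Karp). f[S, j] = min cost of a path
## that visits exactly the slices in S and starts at j. Reconstruction
## prefers the smallest index at every step, yielding the lexicographically
## smallest optimal permutation.
order_exact <- function(D, eps = 1e-9) {
  n <- nrow(D)
  full <- bitwShiftL(1L, n) - 1L
  f <- matrix(Inf, full, n)          # row = subset bitmask, col = start
  for (j in seq_len(n)) f[bitwShiftL(1L, j - 1L), j] <- 0
  masks <- order(vapply(seq_len(full), function(m) sum(bitwAnd(
    m, bitwShiftL(1L, 0:(n - 1L))) > 0L), numeric(1)))
  for (S in masks) {
    members <- which(bitwAnd(S, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    if (length(members) < 2L) next
    for (j in members) {
      rest <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
      others <- setdiff(members, j)
      f[S, j] <- min(D[j, others] + f[rest, others])
    }
  }
  best <- min(f[full, ])
  perm <- integer(n)
  S <- full
  j <- which(f[full, ] <= best + eps)[1L]
  perm[1L] <- j
  for (pos in 2L:n) {
    rest <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
    members <- which(bitwAnd(rest, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    k <- members[which(D[j, members] + f[rest, members] <=
                         f[S, j] + eps)][1L]
    perm[pos] <- k
    S <- rest
    j <- k
  }
  perm
}

order_greedy <- function(D) {
  n <- nrow(D)
  Dw <- D
  diag(Dw) <- Inf
  start <- which(Dw == min(Dw), arr.ind = TRUE)
  start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
  chain <- as.integer(sort(start))
  used <- logical(n)
  used[chain] <- TRUE
  while (length(chain) < n) {
    free <- which(!used)
    head_d <- D[chain[1L], free]
    tail_d <- D[chain[length(chain)], free]
    if (min(head_d) < min(tail_d) ||
        (min(head_d) == min(tail_d) &&
         free[which.min(head_d)] <= free[which.min(tail_d)])) {
      k <- free[which.min(head_d)]
      chain <- c(k, chain)
    } else {
      k <- free[which.min(tail_d)]
      chain <- c(chain, k)
    }
    used[k] <- TRUE
  }
  if (chain[1L] > chain[length(chain)]) chain <- rev(chain)
  chain
}

#' Stack ordered slices into a labelled 3D volume
#'
#' @param slices a [slice_stack()] or list of 2D label matrices.
#' @param ordering an `OrderingResult` (or bare permutation vector).
#' @param voxel_size_um voxel size (z, y, x) in µm recorded on the result;
#'   the z entry is the slice spacing.
#' @return `LabelVolume` with an `extent_um` attribute giving the physical
#'   (z, y, x) extent in µm.
#' @export
assemble_volume <- function(slices, ordering, voxel_size_um = c(1, 1, 1)) {
  if (!inherits(slices, "SliceStack")) slices <- slice_stack(slices)
  perm <- if (inherits(ordering, "OrderingResult")) ordering$permutation
    else as.integer(ordering)
  n <- length(slices)
  if (length(perm) != n || !setequal(perm, seq_len(n)))
    stop("ordering must be a permutation of the slice indices")
  dims <- dim(slices[[perm[1L]]])
  arr <- array(0L, c(n, dims))
  for (i in seq_len(n)) {
    s <- slices[[perm[i]]]
    if (!identical(dim(s), dims)) stop("inconsistent slice shapes")
    arr[i, , ] <- s
  }
  vol <- label_volume(arr, voxel_size_um)
  attr(vol, "extent_um") <- dim(arr) * rep_len(voxel_size_um, 3L)
  vol
}
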