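# Fixtures are generated in code; nothing is stored on disk.

# filled disc as a binary 2D matrix
make_disc <- function(radius, cx, cy, n = 64L) {
  co <- expand.grid(y = seq_len(n), x = seq_len(n))
  m <- matrix(0L, n, n)
  m[as.matrix(co[(co$y - cy)^2 + (co$x - cx)^2 <= radius^2, c("y", "x")])] <- 1L
  m
}

# solid axis-aligned digital ellipsoid in a padded box
digital_ellipsoid <- function(semi, pad = 4L) {
  d <- 2L * ceiling(semi) + 2L * pad + 1L
  ctr <- (d + 1) / 2
  co <- as.matrix(expand.grid(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L])))
  q <- ((co[, 1L] - ctr[1L]) / semi[1L])^2 +
    ((co[, 2L] - ctr[2L]) / semi[2L])^2 +
    ((co[, 3L] - ctr[3L]) / semi[3L])^2
  arr <- array(0L, d)
  arr[co[q <= 1, , drop = FALSE]] <- 1L
  arr
}

# phantom sized for 64x64 training patches: one sarcomere period fits a patch
training_phantom_config <- function(seed, shape = c(30L, 192L, 192L),
                                    mito_count = 40L,
                                    mito_semiaxes_um = c(0.25, 0.2, 0.2)) {
  phantom_config(shape_voxels = shape, voxel_size_um = 0.04,
                 mito_count = mito_count,
                 mito_semiaxes_um = mito_semiaxes_um,
                 myofibril_fill_fraction = 0.3, seed = seed)
}

# phantom whose slices are 32x32, for GAN training records
gan_phantom_config <- function(seed, n_slices = 40L) {
  phantom_config(shape_voxels = c(n_slices, 32L, 32L), voxel_size_um = 0.1,
                 mito_count = 4L, mito_semiaxes_um = c(0.3, 0.3, 0.3),
                 mito_jitter = 0.1, myofibril_fill_fraction = 0.3,
                 zdisc_thickness_um = 0.2, seed = seed)
}

# phantom with many mitochondria for shape-distribution comparisons
morpho_phantom_config <- function(seed) {
  phantom_config(shape_voxels = c(48L, 160L, 160L), voxel_size_um = 0.05,
                 mito_count = 45L, mito_semiaxes_um = c(0.3, 0.22, 0.22),
                 myofibril_fill_fraction = 0.3, seed = seed)
}

# all permutations of 1:n, rows in lexicographic order (test oracle)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out[r + seq_len(nrow(sub)), 1L] <- first
    out[r + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

# brute-force minimal open-path cost over every permutation (test oracle)
brute_force_min_cost <- function(D) {
  P <- all_permutations(nrow(D))
  costs <- rep(0, nrow(P))
  for (i in seq_len(ncol(P) - 1L))
    costs <- costs + D[cbind(P[, i], P[, i + 1L])]
  list(cost = min(costs), perm = P[which.min(costs), ])
}

# brute-force Rand F-score over all ordered pixel pairs (self-pairs
# included), evaluated on the same thinned-foreground mask as the package
rand_fscore_oracle <- function(pred, truth, mask) {
  p <- pred[mask]
  t <- truth[mask]
  n <- length(p)
  same_both <- same_pred <- same_truth <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sp <- p[i] == p[j]
    st <- t[i] == t[j]
    same_pred <- same_pred + sp
    same_truth <- same_truth + st
    same_both <- same_both + (sp && st)
  }
  prec <- same_both / same_pred
  rec <- same_both / same_truth
  2 * prec * rec / (prec + rec)
}

# entropy-based normalized mutual information from explicit frequencies
info_fscore_oracle <- function(pred, truth, mask) {
  p <- pred[mask]
  t <- truth[mask]
  n <- length(p)
  joint <- table(p, t) / n
  hp <- -sum(tapply(rep(1 / n, n), p, sum) * log(tapply(rep(1 / n, n), p, sum)))
  ht <- -sum(tapply(rep(1 / n, n), t, sum) * log(tapply(rep(1 / n, n), t, sum)))
  mi <- 0
  for (i in rownames(joint)) for (j in colnames(joint)) {
    pij <- joint[i, j]
    if (pij > 0)
      mi <- mi + pij * log(pij / (sum(joint[i, ]) * sum(joint[, j])))
  }
  if (hp + ht == 0) return(1)
  2 * mi / (hp + ht)
}

# independent FID oracle: symmetric eigendecomposition route
# Tr sqrt(S1 S2) = sum of sqrt eigenvalues of sqrt(S1) S2 sqrt(S1)
fid_oracle <- function(A, B) {
  mu1 <- colMeans(A)
  mu2 <- colMeans(B)
  pcov <- function(M) stats::cov(M) * (nrow(M) - 1) / nrow(M)
  S1 <- pcov(A)
  S2 <- pcov(B)
  e1 <- eigen(S1, symmetric = TRUE)
  sq1 <- e1$vectors %*% diag(sqrt(pmax(e1$values, 0))) %*% t(e1$vectors)
  M <- sq1 %*% S2 %*% sq1
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) -
    2 * sum(sqrt(pmax(ev, 0)))
}

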