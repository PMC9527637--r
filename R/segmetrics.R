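#' One-vs-rest confusion counts for a class
#'
#' @param pred,truth `LabelVolume`s or integer arrays of identical shape.
#' @param class_id the class evaluated as "positive".
#' @return object of class `ConfusionCounts`: list with `tp`, `fp`, `fn`,
#'   `tn`, `class_id`, `n` (`tp + fp + fn + tn == n`).
#' @export
confusion_counts <- function(pred, truth, class_id) {
  p <- vol_data(pred)
  t <- vol_data(truth)
  if (!identical(dim(p), dim(t)))
    stop("pred and truth must have identical shape")
  pp <- p == class_id
  tt <- t == class_id
  structure(list(tp = sum(pp & tt), fp = sum(pp & !tt),
                 fn = sum(!pp & tt), tn = sum(!pp & !tt),
                 class_id = class_id, n = length(p)),
            class = "ConfusionCounts")
}

#' Confusion-matrix metrics for one class
#'
#' Computes accuracy `(TP+TN)/n`, specificity `TN/(TN+FP)`, positive and
#' negative predictive value `TP/(TP+FP)` and `TN/(TN+FN)`, recall
#' `TP/(TP+FN)` and Jaccard `TP/(TP+FP+FN)`. A zero denominator yields
#' `NaN` with a warning — degenerate cases are surfaced, never silently
#' reported as 0.
#'
#' @param counts a [confusion_counts()] result.
#' @return named numeric vector with the six metrics.
#' @export
basic_metrics <- function(counts) {
  if (!inherits(counts, "ConfusionCounts"))
    stop("counts must be ConfusionCounts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined for class %s (zero denominator)",
                      what, counts$class_id), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  with(counts, c(
    accuracy = safe_div(tp + tn, n, "accuracy"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    ppv = safe_div(tp, tp + fp, "PPV"),
    npv = safe_div(tn, tn + fn, "NPV"),
    recall = safe_div(tp, tp + fn, "recall"),
    jaccard = safe_div(tp, tp + fp + fn, "Jaccard")))
}

#' Full per-class evaluation report
#'
#' One row per class with the [basic_metrics()] values, plus the
#' border-thinned Rand and information scores on pooled foreground.
#'
#' @param pred,truth label volumes/arrays of identical shape.
#' @param classes class ids to report (default 0:3).
#' @param thinning_radius border-thinning radius for the V-scores.
#' @return data.frame; attributes `v_rand_thinned` and `v_info_thinned`
#'   also appear as columns repeated per row for CSV friendliness.
#' @export
segmentation_report <- function(pred, truth, classes = 0:3,
                                thinning_radius = 1L) {
  rows <- lapply(classes, function(k)
    as.data.frame(as.list(basic_metrics(confusion_counts(pred, truth, k)))))
  out <- do.call(rbind, rows)
  out <- cbind(class = classes, out)
  out$v_rand_thinned <- v_rand_thinned(pred, truth, thinning_radius)
  out$v_info_thinned <- v_info_thinned(pred, truth, thinning_radius)
  rownames(out) <- NULL
  out
}

## Evaluation set for the thinned V-scores: truth-foreground voxels at
## Chebyshev distance > radius from the nearest truth label interface.
## Voxels adjacent to a differing label are at distance 1, so radius 0
## excludes nothing and radius 1 strips exactly the one-voxel border zone.
thinned_eval_mask <- function(truth, radius) {
  t <- vol_data(truth)
  d <- dim(t)
  nd <- length(d)
  boundary <- array(FALSE, d)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    if (n < 2L) next
    idx_a <- lapply(d, seq_len); idx_a[[ax]] <- 1L:(n - 1L)
    idx_b <- lapply(d, seq_len); idx_b[[ax]] <- 2L:n
    a <- do.call(`[`, c(list(t), idx_a, list(drop = FALSE)))
    b <- do.call(`[`, c(list(t), idx_b, list(drop = FALSE)))
    diff <- a != b
    cur <- do.call(`[`, c(list(boundary), idx_a, list(drop = FALSE)))
    boundary <- do.call(`[<-`, c(list(boundary), idx_a, list(cur | diff)))
    cur <- do.call(`[`, c(list(boundary), idx_b, list(drop = FALSE)))
    boundary <- do.call(`[<-`, c(list(boundary), idx_b, list(cur | diff)))
  }
  if (radius <= 0L) return(t > 0L)
  excl <- boundary
  if (radius > 1L)
    for (r in seq_len(radius - 1L)) excl <- dilate_chebyshev1(excl)
  (t > 0L) & !excl
}

## One step of Chebyshev (box) dilation, separable along the axes.
dilate_chebyshev1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (ax in seq_along(d)) {
    n <- d[ax]
    if (n < 2L) next
    idx_a <- lapply(d, seq_len); idx_a[[ax]] <- 1L:(n - 1L)
    idx_b <- lapply(d, seq_len); idx_b[[ax]] <- 2L:n
    a <- do.call(`[`, c(list(out), idx_a, list(drop = FALSE)))
    b <- do.call(`[`, c(list(out), idx_b, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_a, list(a | b)))
    cur_b <- do.call(`[`, c(list(out), idx_b, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_b, list(cur_b | a)))
  }
  out
}

contingency_on_mask <- function(pred, truth, mask) {
  p <- vol_data(pred)[mask]
  t <- vol_data(truth)[mask]
  table(factor(p), factor(t))
}

#' Border-thinned foreground-restricted Rand F-score
#'
#' Restricts evaluation to voxels whose ground-truth label is foreground
#' and that lie further than `radius` (Chebyshev) from any ground-truth
#' label boundary, then scores agreement of the two label partitions by
#' the Rand F-score over all ordered voxel pairs:
#' \deqn{V = \frac{\sum_{ij} n_{ij}^2}{\tfrac12\sum_i a_i^2 +
#'   \tfrac12\sum_j b_j^2}}
#' with \eqn{n_{ij}} the joint label histogram and \eqn{a_i, b_j} its
#' margins. 1 for identical segmentations; invariant to permuting segment
#' ids. An empty evaluation set (e.g. radius larger than the image) gives
#' `NaN` with a warning.
#'
#' @param pred,truth label volumes/arrays of identical shape (2D or 3D).
#' @param radius border-thinning radius in voxels (default 1).
#' @return scalar in \[0, 1\] (or `NaN`).
#' @export
v_rand_thinned <- function(pred, truth, radius = 1L) {
  check_same_shape(pred, truth)
  mask <- thinned_eval_mask(truth, radius)
  if (!any(mask)) {
    warning("empty thinned foreground: V_rand undefined", call. = FALSE)
    return(NaN)
  }
  n_ij <- contingency_on_mask(pred, truth, mask)
  sum(n_ij^2) / (0.5 * sum(rowSums(n_ij)^2) + 0.5 * sum(colSums(n_ij)^2))
}

#' Border-thinned foreground-restricted information-theoretic F-score
#'
#' Same evaluation set as [v_rand_thinned()], scored by the normalized
#' mutual information \eqn{V = 2 I(P;T) / (H(P) + H(T))} of the joint label
#' histogram. Identical partitions (including the degenerate single-segment
#' case) score 1; invariant to permuting segment ids.
#'
#' @inheritParams v_rand_thinned
#' @return scalar in \[0, 1\] (or `NaN`).
#' @export
v_info_thinned <- function(pred, truth, radius = 1L) {
  check_same_shape(pred, truth)
  mask <- thinned_eval_mask(truth, radius)
  if (!any(mask)) {
    warning("empty thinned foreground: V_info undefined", call. = FALSE)
    return(NaN)
  }
  n_ij <- contingency_on_mask(pred, truth, mask)
  p <- n_ij / sum(n_ij)
  pi_ <- rowSums(p)
  pj <- colSums(p)
  ent <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  hp <- ent(pi_)
  ht <- ent(pj)
  ## mutual information from the joint histogram
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pi_[row(p)][nz] * pj[col(p)][nz])))
  if (hp + ht == 0) {
    ## both partitions are a single segment: identical by definition
    return(1)
  }
  2 * mi / (hp + ht)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop("arrays must have identical shape")
  invisible(TRUE)
}
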