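#' Fréchet distance between two feature sets
#'
#' Fits a Gaussian (mean and covariance) to each set of d-dimensional
#' feature vectors and computes
#' \deqn{\mathrm{FID} = \lVert\mu_1-\mu_2\rVert^2 +
#'   \mathrm{Tr}\left(\Sigma_1+\Sigma_2-2(\Sigma_1\Sigma_2)^{1/2}\right).}
#' The matrix square root uses the Denman–Beavers iteration
#' (`pracma::sqrtm`); near-singular covariances are epsilon-regularized
#' with a warning, tiny imaginary/negative leakage in the trace is clamped,
#' and the result is never negative. The covariance convention is
#' population (divide by n) by default.
#'
#' @param features_a,features_b numeric matrices, one row per sample
#'   (>= 2 rows), equal column count.
#' @param covariance `"population"` (divide by n, default) or `"sample"`.
#' @param eps regularization added to the covariance diagonal when the
#'   product matrix is near-singular.
#' @return object of class `FIDResult`: list with `value`, `mu1`, `mu2`,
#'   `sigma1`, `sigma2`, `n`, `extractor` (filled by [feature_extractor()]
#'   pipelines), `covariance`.
#' @export
fid <- function(features_a, features_b,
                covariance = c("population", "sample"), eps = 1e-10) {
  covariance <- match.arg(covariance)
  A <- as.matrix(features_a)
  B <- as.matrix(features_b)
  if (ncol(A) != ncol(B)) stop("feature dimensionality mismatch")
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("need at least 2 feature vectors per set")
  mu1 <- colMeans(A)
  mu2 <- colMeans(B)
  covm <- function(M) {
    S <- stats::cov(M)
    if (covariance == "population") S <- S * (nrow(M) - 1) / nrow(M)
    S
  }
  S1 <- covm(A)
  S2 <- covm(B)
  d <- ncol(A)
  if (d == 1L) {
    tr <- S1[1L] + S2[1L] - 2 * sqrt(max(S1[1L] * S2[1L], 0))
  } else {
    P <- S1 %*% S2
    if (rcond(P) < 1e-12) {
      warning("near-singular covariance product: regularizing", call. = FALSE)
      S1 <- S1 + diag(eps, d)
      S2 <- S2 + diag(eps, d)
      P <- S1 %*% S2
    }
    sq <- tryCatch(pracma::sqrtm(P)$B, error = function(e) NULL)
    if (is.null(sq) || any(!is.finite(sq))) {
      warning("matrix square root failed to converge: regularizing",
              call. = FALSE)
      S1 <- S1 + diag(max(eps, 1e-8), d)
      S2 <- S2 + diag(max(eps, 1e-8), d)
      sq <- pracma::sqrtm(S1 %*% S2)$B
    }
    tr <- sum(diag(S1)) + sum(diag(S2)) - 2 * sum(Re(diag(sq)))
  }
  value <- sum((mu1 - mu2)^2) + tr
  structure(list(value = max(value, 0), mu1 = mu1, mu2 = mu2,
                 sigma1 = S1, sigma2 = S2,
                 n = c(nrow(A), nrow(B)), covariance = covariance),
            class = "FIDResult")
}

#' @export
print.FIDResult <- function(x, ...) {
  cat(sprintf("<FIDResult> %.6g (d = %d, n = %d/%d, %s covariance)\n",
              x$value, length(x$mu1), x$n[1L], x$n[2L], x$covariance))
  invisible(x)
}

#' Deterministic feature extractor for FID monitoring
#'
#' The default `downsample_pixels` extractor average-pools each image to
#' `pool_to` x `pool_to` and flattens it — a deterministic, training-free
#' embedding suitable for CPU-scale FID monitoring of label maps. Any
#' function mapping a list of images to a feature matrix can be plugged in
#' instead (e.g. a pretrained network at full scale).
#'
#' @param images list of numeric matrices of one shape, values in \[0, 1\].
#' @param extractor `"downsample_pixels"` or a function
#'   `function(images) -> matrix`.
#' @param pool_to output grid side for the default extractor.
#' @return numeric matrix, one row per image, with attribute `extractor`.
#' @export
feature_extractor <- function(images, extractor = "downsample_pixels",
                              pool_to = 8L) {
  if (length(images) == 0L) stop("empty image set")
  if (is.function(extractor)) {
    out <- extractor(images)
    attr(out, "extractor") <- "custom"
    return(out)
  }
  extractor <- match.arg(extractor, "downsample_pixels")
  pool <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- ceiling(seq_len(nr) / (nr / pool_to))
    ci <- ceiling(seq_len(nc) / (nc / pool_to))
    as.vector(t(rowsum(t(rowsum(m, ri)), ci)) /
                tcrossprod(tabulate(ri, pool_to), tabulate(ci, pool_to)))
  }
  out <- t(vapply(images, pool, numeric(pool_to^2)))
  attr(out, "extractor") <- sprintf("downsample_pixels_%d", pool_to)
  out
}
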