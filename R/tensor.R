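#' Fit the diffusion tensor voxelwise
#'
#' Weighted log-linear least squares: the log-signal model
#' \deqn{\log S = \log S_0 - b\, g^T D g}
#' is solved per voxel with weights equal to the squared signal (the
#' first-order variance weighting for log-transformed data). Signal values
#' at or below zero are floored at `.Machine$double.eps * S0` before the
#' log, since Rician magnitude data cannot be log-transformed at zero.
#' Negative eigenvalues are clamped to zero and the voxel flagged.
#'
#' @param dwi a [dwi_volume()] with at least 7 volumes including a b0 and a
#'   brain mask.
#' @param mask voxels to fit (defaults to the brain mask).
#' @return A `tensor_field`: per-voxel eigenvalues (descending, mm^2/s),
#'   eigenvectors (orthonormal columns), `valid` mask of successful fits and
#'   `clamped` mask of voxels with clamped eigenvalues.
#' @export
fit_tensor <- function(dwi, mask = dwi$masks$brain) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gtab <- dwi$gtab
  n <- length(gtab$bvals)
  if (n < 7) stop("tensor fit needs at least 7 volumes")
  if (is.null(mask)) stop("a brain mask is required")
  d <- dim(dwi$signal)
  nvox <- prod(d[1:3])

  b <- gtab$bvals
  gx <- gtab$bvecs[1, ]; gy <- gtab$bvecs[2, ]; gz <- gtab$bvecs[3, ]
  X <- cbind(1, -b * gx^2, -b * gy^2, -b * gz^2,
             -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz)

  S <- matrix(dwi$signal, nvox, n)
  b0mean <- rowMeans(S[, b == 0, drop = FALSE])
  idx <- which(as.vector(mask) & b0mean > 0 & rowSums(S) > 0)

  evals <- matrix(0, nvox, 3)
  evecs <- array(0, c(nvox, 3, 3))
  valid <- rep(FALSE, nvox)
  clamped <- rep(FALSE, nvox)
  s0 <- max(b0mean)
  floor_s <- .Machine$double.eps * max(s0, 1)

  for (v in idx) {
    y <- S[v, ]
    w <- y^2
    y <- log(pmax(y, floor_s))
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% y), error = function(e) NULL)
    if (is.null(beta)) next
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)      # eigenvalues already descending
    lam <- e$values
    if (any(lam < 0)) {
      clamped[v] <- TRUE
      lam <- pmax(lam, 0)
    }
    evals[v, ] <- lam
    evecs[v, , ] <- e$vectors
    valid[v] <- TRUE
  }

  structure(list(evals = evals, evecs = evecs,
                 valid = array(valid, d[1:3]),
                 clamped = array(clamped, d[1:3]),
                 dims = d[1:3], voxsize = dwi$voxsize,
                 session = dwi$session), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("Tensor field (%s): %d valid voxels (%d clamped) on a %s grid\n",
              x$session %||% "?", sum(x$valid), sum(x$clamped),
              paste(x$dims, collapse = "x")))
  invisible(x)
}

#' Diffusion scalar maps from a tensor field
#'
#' Computes one of the standard rotation-invariant tensor scalars from the
#' sorted eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}:
#' \describe{
#'   \item{FA}{\eqn{\sqrt{3/2}\,\|\lambda - \bar\lambda\| / \|\lambda\|},
#'     dimensionless in `[0, 1]` (0 for the all-zero tensor).}
#'   \item{MD}{\eqn{(\lambda_1+\lambda_2+\lambda_3)/3}, mm^2/s.}
#'   \item{RD}{\eqn{(\lambda_2+\lambda_3)/2} (the mean of the two minor
#'     eigenvalues), mm^2/s.}
#' }
#' Invalid voxels propagate as invalid (NA in the value array).
#'
#' @param tensors a `tensor_field` from [fit_tensor()].
#' @param kind `"fa"`, `"md"` or `"rd"`.
#' @return A `scalar_map` with `values` (3D array, NA outside the valid
#'   mask), `kind`, `units` and `valid`.
#' @export
scalar_map <- function(tensors, kind = c("fa", "md", "rd")) {
  stopifnot(inherits(tensors, "tensor_field"))
  kind <- match.arg(kind)
  lam <- tensors$evals
  vals <- switch(kind,
    fa = {
      mbar <- rowMeans(lam)
      num <- sqrt(rowSums((lam - mbar)^2))
      den <- sqrt(rowSums(lam^2))
      ifelse(den > 0, sqrt(1.5) * num / den, 0)
    },
    md = rowMeans(lam),
    rd = (lam[, 2] + lam[, 3]) / 2)
  vals[!as.vector(tensors$valid)] <- NA_real_
  structure(list(values = array(vals, tensors$dims), kind = toupper(kind),
                 units = if (kind == "fa") "dimensionless" else "mm^2/s",
                 valid = tensors$valid, voxsize = tensors$voxsize,
                 session = tensors$session), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("%s map (%s, %s): mean %.4g over %d valid voxels\n",
              x$kind, x$session %||% "?", x$units, mean(v), length(v)))
  invisible(x)
}
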