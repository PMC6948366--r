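#' Diffusion gradient table
#'
#' Bundles the per-volume b-values (s/mm^2) and unit gradient directions of a
#' diffusion acquisition. b0 volumes carry a zero direction vector.
#'
#' @param bvals numeric vector of b-values, one per volume, all `>= 0`; at
#'   least one must be zero (the b0 reference).
#' @param bvecs 3 x n matrix of gradient directions; columns for nonzero
#'   b-values must have unit Euclidean norm (tolerance 1e-6).
#' @return An object of class `gradient_table` with elements `bvals` and
#'   `bvecs`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop("bvecs must be a 3 x length(bvals) matrix")
  if (any(bvals < 0)) stop("b-values must be non-negative")
  if (!any(bvals == 0)) stop("gradient table must contain at least one b0 volume")
  nrm <- sqrt(colSums(bvecs^2))
  dwi <- bvals > 0
  if (any(abs(nrm[dwi] - 1) > 1e-6))
    stop("gradient directions of diffusion-weighted volumes must be unit vectors")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("Gradient table:", length(x$bvals), "volumes (",
      sum(x$bvals == 0), "b0,", sum(x$bvals > 0), "diffusion-weighted ), b =",
      paste(unique(x$bvals[x$bvals > 0]), collapse = "/"), "s/mm^2\n")
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Default single-shell acquisition scheme
#'
#' One b0 volume followed by `ndir` diffusion directions spread over the
#' sphere by electrostatic repulsion of antipodal point pairs (deterministic
#' Fibonacci-hemisphere initialisation followed by repulsion descent).
#' Defaults mirror a clinical DTI protocol: 32 directions at b = 800 s/mm^2.
#'
#' @param ndir number of diffusion-weighted directions.
#' @param bval b-value of the diffusion-weighted volumes (s/mm^2).
#' @param nb0 number of leading b0 volumes.
#' @return A [gradient_table()].
#' @export
default_gradient_table <- function(ndir = 32, bval = 800, nb0 = 1) {
  v <- fibonacci_hemisphere(ndir)
  v <- repel_directions(v, iters = 200, lr = 0.05)
  bvals <- c(rep(0, nb0), rep(bval, ndir))
  bvecs <- cbind(matrix(0, 3, nb0), t(v))
  gradient_table(bvals, bvecs)
}

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper hemisphere only: axial symmetry
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Gradient descent on the electrostatic energy sum 1/|vi - vj| + 1/|vi + vj|
# (antipodal pairs count, as diffusion directions are axial).
repel_directions <- function(v, iters = 200, lr = 0.05) {
  n <- nrow(v)
  for (it in seq_len(iters)) {
    g <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(v[-i, , drop = FALSE], 2, v[i, ], function(a, b) b - a)
      d2 <- sweep(v[-i, , drop = FALSE], 2, v[i, ], `+`)
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      g[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    # cap the per-point step: near-coincident pairs produce huge forces
    # that would otherwise make the descent oscillate
    step <- lr / sqrt(it) * g
    nrm <- sqrt(rowSums(step^2))
    big <- nrm > 0.1
    step[big, ] <- step[big, ] * (0.1 / nrm[big])
    v <- v + step
    v <- v / sqrt(rowSums(v^2))
  }
  v
}

#' Read and write FSL-dialect bvals/bvecs files
#'
#' `bvals` is one whitespace-delimited row of b-values; `bvecs` is three rows
#' (x, y, z) of direction components, one column per volume.
#'
#' @param bval_path,bvec_path file paths.
#' @return `read_bvalbvec()` returns a [gradient_table()].
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) != 3L) stop("bvecs file must have exactly 3 rows")
  dimnames(bv) <- NULL
  gradient_table(bvals, bv)
}

#' @rdname read_bvalbvec
#' @param gtab a [gradient_table()].
#' @export
write_bvalbvec <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(gtab$bvecs, 1, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")), bvec_path)
  invisible(NULL)
}
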