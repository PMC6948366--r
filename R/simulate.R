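#' Construct a DWI volume container
#'
#' @param signal 4D non-negative array (x, y, z, volume).
#' @param gtab a [gradient_table()] with one entry per volume.
#' @param voxsize voxel size in mm.
#' @param session session tag, `"pre"` or `"post"`.
#' @param masks list of binary 3D arrays `brain`, `gm`, `wm`, `air`
#'   (mutually disjoint tissue masks on the same grid).
#' @return A `dwi_volume` object.
#' @export
dwi_volume <- function(signal, gtab, voxsize, session = "pre", masks = list()) {
  dims <- dim(signal)
  if (length(dims) != 4L) stop("signal must be a 4D array")
  if (dims[4] != length(gtab$bvals))
    stop("number of volumes must equal the gradient-table length")
  if (any(signal < 0)) stop("signal must be non-negative")
  for (m in masks)
    if (!is.null(m) && !identical(dim(m), dims[1:3]))
      stop("mask shapes must equal the spatial shape of the signal")
  if (all(c("gm", "wm", "air") %in% names(masks))) {
    if (any(masks$gm & masks$wm) || any(masks$gm & masks$air) ||
        any(masks$wm & masks$air))
      stop("GM, WM and air masks must be mutually disjoint")
  }
  structure(list(signal = signal, gtab = gtab, voxsize = as.numeric(voxsize),
                 session = session, masks = masks), class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI volume (%s session): %dx%dx%d voxels x %d volumes @ %s mm\n",
              x$session, d[1], d[2], d[3], d[4],
              paste(x$voxsize, collapse = "x")))
  print(x$gtab)
  invisible(x)
}

#' Simulate a DWI session from a phantom
#'
#' Generates the noiseless ball-and-stick signal
#' \deqn{S(g, b) = S_0 [(1 - \sum f_i) e^{-b d} + \sum_i f_i e^{-b d (g \cdot v_i)^2}]}
#' in white-matter voxels (with the white-matter diffusivity for both ball
#' and sticks), isotropic attenuation \eqn{S_0 e^{-b d_{tissue}}} in GM/CSF,
#' and zero signal in air, then applies Rician noise of parameter `sigma`
#' (magnitude of the signal plus complex Gaussian noise).
#'
#' @param phantom a [make_phantom()] result.
#' @param gtab a [gradient_table()].
#' @param sigma Rician noise parameter (signal units, `>= 0`; 0 gives the
#'   exact closed-form signal).
#' @param seed RNG seed; the same seed reproduces the volume exactly.
#' @param session session tag stored in the result.
#' @return A [dwi_volume()].
#' @export
simulate_dwi <- function(phantom, gtab, sigma = 0, seed = NULL,
                         session = "pre") {
  stopifnot(inherits(phantom, "dwi_phantom"), sigma >= 0)
  if (any(phantom$f1 + phantom$f2 > 1 + 1e-12))
    stop("stick volume fractions sum above 1 in ", sum(phantom$f1 + phantom$f2 > 1),
         " voxel(s)")
  spec <- phantom$spec
  dims <- phantom$dims
  nvox <- prod(dims)
  nvol <- length(gtab$bvals)
  tissue <- as.vector(phantom$tissue)
  S <- matrix(0, nvox, nvol)

  wm <- tissue == 2L
  gm <- tissue == 1L
  csf <- tissue == 3L
  for (v in seq_len(nvol)) {
    b <- gtab$bvals[v]
    g <- gtab$bvecs[, v]
    col <- numeric(nvox)
    if (any(wm)) {
      c1 <- phantom$orient1[wm, , drop = FALSE] %*% g
      c2 <- phantom$orient2[wm, , drop = FALSE] %*% g
      fb <- 1 - phantom$f1[wm] - phantom$f2[wm]
      col[wm] <- spec$S0 * (fb * exp(-b * spec$d_wm) +
        phantom$f1[wm] * exp(-b * spec$d_wm * c1^2) +
        phantom$f2[wm] * exp(-b * spec$d_wm * c2^2))
    }
    col[gm] <- spec$S0 * exp(-b * spec$d_gm)
    col[csf] <- spec$S0 * exp(-b * spec$d_csf)
    S[, v] <- col
  }

  out <- dwi_volume(array(S, c(dims, nvol)), gtab, phantom$voxsize, session,
                    masks = phantom$masks[c("brain", "gm", "wm", "air")])
  add_rician_noise(out, sigma, seed)
}

#' Add Rician noise to a DWI volume
#'
#' Replaces the signal with the magnitude of the signal plus complex
#' Gaussian noise, \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with
#' \eqn{n_i \sim N(0, \sigma)} — the noise distribution of magnitude MR
#' images. The study pipeline adds noise *after* the artifact attenuation:
#' susceptibility dropout dephases the MR signal before receiver noise
#' enters, so attenuated regions keep the full noise floor.
#'
#' @param dwi a [dwi_volume()].
#' @param sigma noise parameter (`>= 0`; 0 returns the input unchanged).
#' @param seed RNG seed.
#' @return The noisy [dwi_volume()].
#' @export
add_rician_noise <- function(dwi, sigma, seed = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"), sigma >= 0)
  if (sigma == 0) return(dwi)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dwi$signal)
  dwi$signal[] <- sqrt((dwi$signal + rnorm(n, 0, sigma))^2 +
                         rnorm(n, 0, sigma)^2)
  dwi
}

#' Apply a signal-dropout artifact region
#'
#' Multiplies the signal inside the artifact mask by the attenuation factor
#' in every volume, emulating susceptibility dropout near DBS hardware.
#' Voxels outside the mask are untouched.
#'
#' @param dwi a [dwi_volume()].
#' @param mask binary 3D array on the DWI grid.
#' @param attenuation factor in `[0, 1]` (0 erases the signal, 1 is the
#'   identity).
#' @return The modified [dwi_volume()].
#' @export
apply_artifact <- function(dwi, mask, attenuation) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation factor must lie in [0, 1]")
  if (!identical(dim(mask), dim(dwi$signal)[1:3]))
    stop("artifact mask shape must match the DWI grid")
  idx <- which(as.vector(mask) > 0)
  nvox <- prod(dim(dwi$signal)[1:3])
  for (v in seq_len(dim(dwi$signal)[4])) {
    off <- (v - 1) * nvox
    dwi$signal[off + idx] <- dwi$signal[off + idx] * attenuation
  }
  dwi
}

#' Draw random per-volume rigid head motion
#'
#' Independent Gaussian translations (mm) and rotations (degrees) per
#' non-b0 volume; the b0 reference volume stays at identity.
#'
#' @param gtab gradient table (identifies the b0 volumes).
#' @param trans_sd,rot_sd per-axis standard deviations (mm, degrees).
#' @param seed RNG seed.
#' @return Data frame with columns `tx, ty, tz, rx, ry, rz`, one row per
#'   volume.
#' @export
random_rigid_motion <- function(gtab, trans_sd = 0.7, rot_sd = 0.7,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(gtab$bvals)
  m <- data.frame(tx = rnorm(n, 0, trans_sd), ty = rnorm(n, 0, trans_sd),
                  tz = rnorm(n, 0, trans_sd), rx = rnorm(n, 0, rot_sd),
                  ry = rnorm(n, 0, rot_sd), rz = rnorm(n, 0, rot_sd))
  m[gtab$bvals == 0, ] <- 0
  m
}

#' Apply per-volume rigid motion to a DWI volume
#'
#' Each volume is resampled under its rigid transform (rotation about the
#' grid centre then translation, trilinear interpolation). The ground-truth
#' transforms are stored in the `motion_truth` attribute for recovery
#' testing.
#'
#' @param dwi a [dwi_volume()].
#' @param transforms data frame as produced by [random_rigid_motion()]; the
#'   b0 rows must be identity (the b0 is the registration reference).
#' @return The moved [dwi_volume()] with attribute `motion_truth`.
#' @export
apply_motion <- function(dwi, transforms) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$signal)
  if (nrow(transforms) != d[4])
    stop("need exactly one transform per volume")
  b0 <- dwi$gtab$bvals == 0
  if (any(abs(as.matrix(transforms[b0, ])) > 1e-12))
    stop("b0 volume transforms must be identity (b0 is the reference)")
  brain <- dwi$masks$brain
  nbrain <- sum(brain)
  for (v in seq_len(d[4])) {
    tr <- as.numeric(transforms[v, c("rx", "ry", "rz")])
    tt <- as.numeric(transforms[v, c("tx", "ty", "tz")])
    if (all(tr == 0) && all(tt == 0)) next
    nout <- cpp_count_outside(as.integer(brain), d[1:3], dwi$voxsize, tr, tt)
    if (nout > 0.25 * nbrain)
      stop("transform for volume ", v, " moves more than 25% of brain ",
           "voxels outside the grid")
    dwi$signal[, , , v] <- array(
      cpp_resample_rigid(as.numeric(dwi$signal[, , , v]), d[1:3],
                         dwi$voxsize, tr, tt), d[1:3])
  }
  attr(dwi, "motion_truth") <- transforms
  dwi
}
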