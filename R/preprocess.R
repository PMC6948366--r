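#' Register every DWI volume to the b0 image
#'
#' Estimates a rigid transform per diffusion-weighted volume by maximising
#' normalised mutual information (NMI) against the b0 reference (diffusion
#' contrast differs across directions, so a least-squares cost is
#' inappropriate), resamples each volume into b0 space, rotates the gradient
#' directions by each transform's rotation component, and reports the
#' estimated head motion (the inverse of the applied correction) per volume.
#'
#' Two-stage scheme. Capture stage: NMI on Gaussian-presmoothed copies
#' (`smooth_sigma` voxels, widening the capture range), coarse grid search
#' over translations then rotations, and cyclic coordinate descent from two
#' starts. Precision stage: NMI on lightly smoothed copies with a finer
#' histogram, evaluated under *symmetric half-transform resampling* — the
#' moving volume is resampled by half the candidate transform and the
#' reference by the inverse half, so both carry exactly one interpolation
#' and the interpolation-blur bias toward the identity cancels — refined by
#' coordinate descent plus a Nelder-Mead polish. The estimated transform is
#' applied to the *original* (unsmoothed) volume. A volume on which the
#' optimiser cannot beat the identity transform is left uncorrected with a
#' warning and flagged in the report.
#'
#' @param dwi a [dwi_volume()] with exactly one b0 volume designated as
#'   reference (the first b0 if several).
#' @param bins histogram bins for the NMI cost.
#' @param coarse_t translations (mm) tried per axis in the grid-search stage.
#' @param coarse_r rotations (degrees) tried per axis.
#' @param smooth_sigma presmoothing width in voxels.
#' @param maxit Nelder-Mead iteration cap per volume.
#' @return List with `dwi` (corrected volume, gradients rotated) and
#'   `report` (a `motion_report`: per-volume estimated translations in mm and
#'   rotations in degrees, plus convergence flags).
#' @export
register_to_b0 <- function(dwi, bins = 32, coarse_t = c(-3, 0, 3),
                           coarse_r = c(-5, 0, 5), smooth_sigma = 1,
                           maxit = 500) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$signal)
  b0i <- which(dwi$gtab$bvals == 0)
  if (length(b0i) == 0) stop("no b0 reference volume present")
  b0 <- as.numeric(dwi$signal[, , , b0i[1]])
  rng <- range(dwi$signal)  # shared bin range for all volumes
  lo <- min(rng[1], 0); hi <- max(rng[2], 1e-9)
  to_bin <- function(x, bins) pmin(bins - 1L, pmax(0L, as.integer(
    (x - lo) / (hi - lo) * bins)))
  nmi_of_hist <- function(j, bins) {
    p <- j / sum(j)
    px <- rowSums(matrix(p, bins)); py <- colSums(matrix(p, bins))
    H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
    (H(px) + H(py)) / max(H(p), 1e-12)
  }
  # two resolutions: wide smoothing for capture range, light smoothing with
  # a finer histogram for precision
  stages <- list(list(sigma = smooth_sigma, bins = bins),
                 list(sigma = smooth_sigma, bins = round(1.5 * bins)))
  ref1_bin <- to_bin(cpp_gauss_smooth(b0, d[1:3], stages[[1]]$sigma),
                     stages[[1]]$bins)
  ref2 <- cpp_gauss_smooth(b0, d[1:3], stages[[2]]$sigma)

  # cyclic coordinate descent with shrinking brackets: robust on the
  # shallow 6-D cost surface where a Nelder-Mead simplex collapses early
  ccd <- function(cost, p0, sweeps = 1:4) {
    p <- p0
    val <- cost(p)
    for (sweep in sweeps) {
      half <- c(rep(3, 3), rep(6, 3)) / 2^(sweep - 1)
      for (i in 1:6) {
        o <- optimize(function(x) { q <- p; q[i] <- x; cost(q) },
                      lower = p[i] - half[i], upper = p[i] + half[i],
                      tol = 1e-3)
        if (o$objective < val) { p[i] <- o$minimum; val <- o$objective }
      }
    }
    list(par = p, value = val)
  }

  est <- matrix(0, d[4], 6)
  converged <- rep(TRUE, d[4])
  for (v in seq_len(d[4])) {
    if (v %in% b0i) next
    mov <- as.numeric(dwi$signal[, , , v])
    movs1 <- cpp_gauss_smooth(mov, d[1:3], stages[[1]]$sigma)
    movs2 <- cpp_gauss_smooth(mov, d[1:3], stages[[2]]$sigma)
    b1 <- stages[[1]]$bins
    cost <- function(p) -nmi_of_hist(tabulate(
      to_bin(cpp_resample_rigid(movs1, d[1:3], dwi$voxsize, p[4:6], p[1:3]),
             b1) * b1 + ref1_bin + 1L, nbins = b1 * b1), b1)
    # precision cost: symmetric half-transform resampling, so both images
    # carry exactly one interpolation and the blur bias toward the identity
    # cancels
    b2 <- stages[[2]]$bins
    cost_sym <- function(p) {
      inv <- invert_rigid(p[4:6] / 2, p[1:3] / 2)
      a <- cpp_resample_rigid(movs2, d[1:3], dwi$voxsize, p[4:6] / 2,
                              p[1:3] / 2)
      b <- cpp_resample_rigid(ref2, d[1:3], dwi$voxsize, inv$rot_deg,
                              inv$trans_mm)
      -nmi_of_hist(tabulate(to_bin(a, b2) * b2 + to_bin(b, b2) + 1L,
                            nbins = b2 * b2), b2)
    }
    tg <- as.matrix(expand.grid(coarse_t, coarse_t, coarse_t))
    ct <- apply(tg, 1, function(tt) cost(c(tt, 0, 0, 0)))
    t0 <- tg[which.min(ct), ]
    rg <- as.matrix(expand.grid(coarse_r, coarse_r, coarse_r))
    cr <- apply(rg, 1, function(rr) cost(c(t0, rr)))
    # two candidate starts (coarse rotation estimate and zero rotation)
    # guard against settling in a spurious-rotation basin
    starts <- unique(list(c(t0, rg[which.min(cr), ]), c(t0, 0, 0, 0)))
    cands <- lapply(starts, function(p0) ccd(cost, p0))
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
    # precision stage on the lightly smoothed images
    best <- ccd(cost_sym, best$par, sweeps = 3:6)
    fit <- optim(best$par, cost_sym, method = "Nelder-Mead",
                 control = list(reltol = 1e-7, maxit = maxit))
    if (fit$value > best$value) fit <- best
    if (!is.finite(fit$value)) {
      warning("registration did not converge for volume ", v,
              "; identity transform recorded")
      converged[v] <- FALSE
      next
    }
    # identity at least as good as anything found: a clean no-motion estimate
    if (fit$value >= cost_sym(rep(0, 6))) next
    est[v, ] <- fit$par
    dwi$signal[, , , v] <- array(
      cpp_resample_rigid(mov, d[1:3], dwi$voxsize, fit$par[4:6], fit$par[1:3]),
      d[1:3])
    # rotate the gradient direction by the correction rotation
    dwi$gtab$bvecs[, v] <- rotation_matrix(fit$par[4:6]) %*% dwi$gtab$bvecs[, v]
  }

  # report the estimated motion = inverse of the applied correction
  mot <- t(vapply(seq_len(d[4]), function(v) {
    inv <- invert_rigid(est[v, 4:6], est[v, 1:3])
    c(inv$trans_mm, inv$rot_deg)
  }, numeric(6)))
  rep_df <- data.frame(volume = seq_len(d[4]), tx = mot[, 1], ty = mot[, 2],
                       tz = mot[, 3], rx = mot[, 4], ry = mot[, 5],
                       rz = mot[, 6], converged = converged)
  rep_df <- rep_df[-b0i, , drop = FALSE]
  report <- structure(list(per_volume = rep_df, session = dwi$session),
                      class = "motion_report")
  list(dwi = dwi, report = report)
}

#' @export
print.motion_report <- function(x, ...) {
  s <- summarize_motion(x)
  cat(sprintf("Motion report (%s): mean |translation| %.3f mm, mean |rotation| %.3f deg over %d volumes\n",
              x$session %||% "?", s$mean_translation, s$mean_rotation,
              nrow(x$per_volume)))
  invisible(x)
}

#' Summarise head motion
#'
#' The amount of translation of a volume is the Euclidean magnitude of its
#' (x, y, z) translation vector in mm, and likewise for rotation in
#' degrees; the session summary is the mean of these magnitudes across
#' volumes. Given a second report, also returns the ratio of the two
#' sessions' mean translations and rotations (this/reference); a zero
#' reference yields NaN with a warning.
#'
#' @param report a `motion_report` from [register_to_b0()].
#' @param reference optional second `motion_report` to compare against
#'   (typically post vs pre).
#' @return List with `mean_translation` (mm), `mean_rotation` (degrees), and
#'   when `reference` is given, `translation_ratio` and `rotation_ratio`.
#' @export
summarize_motion <- function(report, reference = NULL) {
  stopifnot(inherits(report, "motion_report"))
  pv <- report$per_volume
  if (nrow(pv) == 0) stop("motion report is empty")
  out <- list(
    mean_translation = mean(sqrt(rowSums(
      as.matrix(pv[, c("tx", "ty", "tz")])^2))),
    mean_rotation = mean(sqrt(rowSums(
      as.matrix(pv[, c("rx", "ry", "rz")])^2))),
    session = report$session)
  if (!is.null(reference)) {
    rs <- summarize_motion(reference)
    if (rs$mean_translation == 0 || rs$mean_rotation == 0)
      warning("reference motion is zero; ratio undefined (NaN)")
    out$translation_ratio <- if (rs$mean_translation == 0) NaN
      else out$mean_translation / rs$mean_translation
    out$rotation_ratio <- if (rs$mean_rotation == 0) NaN
      else out$mean_rotation / rs$mean_rotation
  }
  out
}

#' Serialize a motion report as tidy CSV
#'
#' @param report a `motion_report`.
#' @param path output CSV path (one row per volume:
#'   `volume, tx, ty, tz, rx, ry, rz, converged`).
#' @export
write_motion_report <- function(report, path) {
  write.csv(report$per_volume, path, row.names = FALSE)
  invisible(path)
}
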