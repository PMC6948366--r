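#' Define a fiber bundle for the synthetic phantom
#'
#' A bundle is a tube of given radius around a centerline through the
#' supplied waypoints (0-based voxel coordinates). Voxels inside the tube
#' become white matter and carry the centerline tangent as their stick
#' orientation, with stick volume fraction `f`.
#'
#' @param waypoints numeric matrix (rows = points, columns = x,y,z) of
#'   centerline waypoints in voxel coordinates; two points give a straight
#'   bundle, more are interpolated by cubic splines.
#' @param radius tube radius in voxels (> 0).
#' @param f stick volume fraction in (0, 1].
#' @param name optional bundle name.
#' @return A `fiber_bundle` list.
#' @export
fiber_bundle <- function(waypoints, radius, f = 0.7, name = NULL) {
  waypoints <- as.matrix(waypoints)
  if (ncol(waypoints) != 3L || nrow(waypoints) < 2L)
    stop("waypoints must be an n x 3 matrix with n >= 2")
  if (radius <= 0) stop("bundle radius must be > 0")
  if (f <= 0 || f > 1) stop("stick volume fraction must be in (0, 1]")
  structure(list(waypoints = waypoints, radius = radius, f = f,
                 name = name %||% "bundle"), class = "fiber_bundle")
}

#' Specify a synthetic DWI phantom
#'
#' Describes the geometry and signal model of a synthetic head: a spherical
#' brain containing fiber bundles (white matter), gray matter elsewhere, an
#' optional CSF sphere, spherical ROIs with seed/target/distractor roles, and
#' a spherical susceptibility-artifact region emulating DBS electrode signal
#' dropout.
#'
#' @param dims grid shape in voxels (length 3).
#' @param voxsize voxel size in mm (length 3).
#' @param bundles list of [fiber_bundle()] objects.
#' @param brain_radius brain radius in voxels, centred on the grid; a triple
#'   gives an ellipsoid (the default study phantom uses one, since a head
#'   outline is not rotation-symmetric).
#' @param rois data frame with columns `name`, `role`
#'   (`"seed"`, `"target"` or `"distractor"`), `cx`, `cy`, `cz`, `radius`
#'   (voxel coordinates/units). Labels are assigned as the row order.
#' @param artifact list with `center` (voxel coords), `radius` (voxels) and
#'   `attenuation` in `[0, 1]`; `NULL` for no artifact region.
#' @param csf optional list with `center` and `radius` for a CSF sphere.
#' @param S0 non-diffusion-weighted signal level.
#' @param d_wm,d_gm,d_csf tissue diffusivities in mm^2/s. White-matter voxels
#'   use `d_wm` for both the ball and the stick compartments; gray matter and
#'   CSF attenuate isotropically.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dims = c(24, 24, 24), voxsize = c(2, 2, 2),
                         bundles = list(), brain_radius = 10.5,
                         rois = NULL, artifact = NULL, csf = NULL,
                         S0 = 1000, d_wm = 1.2e-3, d_gm = 0.9e-3,
                         d_csf = 3.0e-3) {
  stopifnot(length(dims) == 3, all(dims >= 4), length(voxsize) == 3,
            all(voxsize > 0), brain_radius > 0, S0 > 0)
  if (!is.null(artifact)) {
    if (artifact$attenuation < 0 || artifact$attenuation > 1)
      stop("artifact attenuation factor must lie in [0, 1]")
    if (artifact$radius <= 0) stop("artifact radius must be > 0")
  }
  if (!is.null(rois)) {
    need <- c("name", "role", "cx", "cy", "cz", "radius")
    if (!all(need %in% names(rois))) stop("rois must have columns ",
                                          paste(need, collapse = ", "))
    if (!all(rois$role %in% c("seed", "target", "distractor")))
      stop("roi roles must be seed, target or distractor")
  }
  structure(list(dims = as.integer(dims), voxsize = as.numeric(voxsize),
                 bundles = bundles, brain_radius = brain_radius, rois = rois,
                 artifact = artifact, csf = csf, S0 = S0, d_wm = d_wm,
                 d_gm = d_gm, d_csf = d_csf), class = "phantom_spec")
}

#' Default phantom: three tracts, artifact bisecting one of them
#'
#' A 24^3 grid of 2 mm isotropic voxels with three bundles standing in for
#' the nigrostriatal, dentato-rubro-thalamic and hyperdirect pathways (one
#' straight, one straight orthogonal, one quarter-arc), seed and target ROIs
#' at the bundle ends (gray-matter structures whose cores touch the bundle,
#' as striatum/thalamus/cortex seeds do), ten distractor ROIs in gray
#' matter, and a spherical signal-dropout region centred on the first
#' bundle's midpoint (emulating the DBS connection-wire artifact), which
#' also overlaps three distractors — two substantially, one marginally — so
#' roughly a fifth of the ROIs classify as artifact-affected.
#'
#' @param attenuation artifact attenuation factor applied to the
#'   post-operative session.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(attenuation = 0.15) {
  b1 <- fiber_bundle(rbind(c(4, 11.5, 11.5), c(19, 11.5, 11.5)),
                     radius = 1.6, f = 0.7, name = "nigrostriatal")
  b2 <- fiber_bundle(rbind(c(11.5, 5, 6.5), c(11.5, 18, 6.5)),
                     radius = 1.6, f = 0.7, name = "dentatorubrothalamic")
  t <- seq(0, pi / 2, length.out = 9)
  b3 <- fiber_bundle(cbind(16.5 - 10 * cos(t), 16.5, 6.5 + 10 * sin(t)),
                     radius = 1.6, f = 0.7, name = "hyperdirect")
  rois <- rbind(
    data.frame(name = "STR",  role = "seed",   cx = 5,    cy = 11.5, cz = 11.5, radius = 2),
    data.frame(name = "SN",   role = "target", cx = 18,   cy = 11.5, cz = 11.5, radius = 2),
    data.frame(name = "THAL", role = "seed",   cx = 11.5, cy = 5.5,  cz = 6.5,  radius = 2),
    data.frame(name = "DN",   role = "target", cx = 11.5, cy = 17.5, cz = 6.5,  radius = 2),
    data.frame(name = "CTX",  role = "seed",   cx = 6.5,  cy = 16.5, cz = 6.5,  radius = 2),
    data.frame(name = "STN",  role = "target", cx = 16.5, cy = 16.5, cz = 16.5, radius = 2),
    data.frame(name = sprintf("GM%02d", 1:10), role = "distractor",
               cx = c(11.5, 6,  17, 6,  18,   11.5, 11.5, 10,   13,   8.5),
               cy = c(11.5, 6,  6,  17, 12,   14,   7,    11.5, 11,   14),
               cz = c(17.5, 14, 13, 14, 8,    13,   16,   10.5, 12.5, 5),
               radius = 2))
  phantom_spec(bundles = list(b1, b2, b3), rois = rois,
               brain_radius = c(10.5, 9, 7.5),
               artifact = list(center = c(11.5, 11.5, 11.5), radius = 3.5,
                               attenuation = attenuation))
}

# Densely resample a centerline and return sample points and unit tangents.
sample_centerline <- function(waypoints, ds = 0.2) {
  d <- sqrt(rowSums(diff(waypoints)^2))
  s <- c(0, cumsum(d))
  n <- max(2L, ceiling(s[length(s)] / ds))
  sg <- seq(0, s[length(s)], length.out = n)
  if (nrow(waypoints) == 2) {
    pts <- sapply(1:3, function(j) approx(s, waypoints[, j], xout = sg)$y)
  } else {
    pts <- sapply(1:3, function(j) spline(s, waypoints[, j], xout = sg)$y)
  }
  tan <- rbind(pts[2, ] - pts[1, ],
               (pts[-(1:2), , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]) / 2,
               pts[n, ] - pts[n - 1, ])
  tan <- tan / sqrt(rowSums(tan^2))
  list(points = pts, tangents = tan)
}

sphere_mask <- function(dims, center, radius) {
  # radius may be a triple (ellipsoid); a head outline is never spherical,
  # and the asymmetry is what makes rigid registration well-posed
  radius <- rep(radius, length.out = 3)
  g <- expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1), z = 0:(dims[3] - 1))
  m <- ((g$x - center[1]) / radius[1])^2 + ((g$y - center[2]) / radius[2])^2 +
    ((g$z - center[3]) / radius[3])^2 <= 1
  array(m, dims)
}

#' Build a phantom from its specification
#'
#' Rasterises the bundles into a voxelwise orientation field (up to two
#' orientations where bundles cross), assigns tissue classes
#' (air/GM/WM/CSF), rasterises ROI labels and the artifact mask.
#'
#' @param spec a [phantom_spec()].
#' @return A `dwi_phantom` object with the orientation field (`orient1`,
#'   `orient2`, voxel-indexed matrices), stick fractions `f1`/`f2`, fiber
#'   count `nfib`, `tissue` (0 air, 1 GM, 2 WM, 3 CSF), `labels` with the
#'   ROI table, `artifact` mask and binary `masks` (brain/gm/wm/air).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  nvox <- prod(dims)
  ctr <- (dims - 1) / 2
  g <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                             z = 0:(dims[3] - 1)))

  orient1 <- matrix(0, nvox, 3)
  orient2 <- matrix(0, nvox, 3)
  f1 <- numeric(nvox); f2 <- numeric(nvox)
  nfib <- integer(nvox)

  for (b in spec$bundles) {
    cl <- sample_centerline(b$waypoints)
    if (any(cl$points < -0.5) ||
        any(sweep(cl$points, 2, dims - 0.5, `>=`)))
      stop("bundle '", b$name, "' leaves the grid")
    # nearest centerline sample (and its tangent) for every voxel in the tube
    best <- rep(Inf, nvox); arg <- integer(nvox)
    for (i in seq_len(nrow(cl$points))) {
      d2 <- (g[, 1] - cl$points[i, 1])^2 + (g[, 2] - cl$points[i, 2])^2 +
        (g[, 3] - cl$points[i, 3])^2
      upd <- d2 < best
      best[upd] <- d2[upd]; arg[upd] <- i
    }
    inside <- which(best <= b$radius^2)
    for (v in inside) {
      tng <- cl$tangents[arg[v], ]
      if (nfib[v] == 0L) {
        orient1[v, ] <- tng; f1[v] <- b$f; nfib[v] <- 1L
      } else if (axial_angle(orient1[v, ], tng) < 20) {
        # same orientation: merge, keep the larger fraction
        f1[v] <- max(f1[v], b$f)
      } else if (nfib[v] == 1L) {
        orient2[v, ] <- tng; f2[v] <- b$f; nfib[v] <- 2L
      } else stop("more than two bundles overlap at a voxel; at most two ",
                  "fiber populations per voxel are supported")
    }
  }

  brain <- sphere_mask(dims, ctr, spec$brain_radius)
  wm <- array(nfib > 0L, dims) & brain
  csf <- if (!is.null(spec$csf))
    sphere_mask(dims, spec$csf$center, spec$csf$radius) & brain & !wm
  else array(FALSE, dims)
  gm <- brain & !wm & !csf
  # background noise is sampled away from the head: a 2-voxel guard band
  # keeps partial-volume bleed (motion, interpolation) out of the air mask
  air <- !sphere_mask(dims, ctr, rep(spec$brain_radius, length.out = 3) + 2)
  tissue <- array(0L, dims)
  tissue[gm] <- 1L; tissue[wm] <- 2L; tissue[csf] <- 3L

  labels <- array(0L, dims)
  roi_table <- NULL
  if (!is.null(spec$rois)) {
    roi_table <- spec$rois
    roi_table$label <- seq_len(nrow(roi_table))
    roi_masks <- lapply(seq_len(nrow(roi_table)), function(i)
      sphere_mask(dims, unlist(roi_table[i, c("cx", "cy", "cz")]),
                  roi_table$radius[i]))
    st <- which(roi_table$role %in% c("seed", "target"))
    if (length(st) > 1)
      for (a in st) for (b in st) if (a < b &&
          any(roi_masks[[a]] & roi_masks[[b]]))
        stop("seed/target labels overlap: '", roi_table$name[a], "' and '",
             roi_table$name[b], "'")
    for (i in seq_len(nrow(roi_table))) {
      take <- roi_masks[[i]] & labels == 0L
      labels[take] <- roi_table$label[i]
    }
    empty <- setdiff(roi_table$label, unique(as.vector(labels)))
    if (length(empty))
      warning("ROI(s) rasterised to zero voxels: ",
              paste(roi_table$name[roi_table$label %in% empty], collapse = ", "))
  }

  artifact <- if (!is.null(spec$artifact))
    sphere_mask(dims, spec$artifact$center, spec$artifact$radius)
  else array(FALSE, dims)

  structure(list(dims = dims, voxsize = spec$voxsize, orient1 = orient1,
                 orient2 = orient2, f1 = f1, f2 = f2,
                 nfib = array(nfib, dims), tissue = tissue, labels = labels,
                 roi_table = roi_table, artifact = artifact,
                 masks = list(brain = brain, gm = gm, wm = wm, air = air,
                              csf = csf),
                 spec = spec), class = "dwi_phantom")
}

#' @export
print.dwi_phantom <- function(x, ...) {
  cat("DWI phantom:", paste(x$dims, collapse = "x"), "voxels @",
      paste(x$voxsize, collapse = "x"), "mm\n")
  cat("  bundles:", length(x$spec$bundles),
      " WM voxels:", sum(x$masks$wm),
      " GM voxels:", sum(x$masks$gm),
      " crossing voxels:", sum(x$nfib == 2L), "\n")
  if (!is.null(x$roi_table))
    cat("  ROIs:", nrow(x$roi_table),
        " artifact voxels:", sum(x$artifact), "\n")
  invisible(x)
}
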