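# Small phantom builders shared across test files. All fixtures are built
# in code; nothing is read from disk.

# A minimal single-voxel-style phantom: every voxel identical, so any voxel
# can be inspected. `kind` selects the tissue/fiber content.
uniform_phantom <- function(kind = c("stick", "iso", "crossing", "csf"),
                            dims = c(5, 5, 5), f = 0.7,
                            orient = c(1, 0, 0), orient2 = c(0, 1, 0),
                            f2 = 0.4, S0 = 1000,
                            d_wm = 1.2e-3, d_gm = 0.9e-3, d_csf = 3.0e-3) {
  kind <- match.arg(kind)
  nvox <- prod(dims)
  ph <- list(dims = dims, voxsize = c(2, 2, 2),
             orient1 = matrix(0, nvox, 3), orient2 = matrix(0, nvox, 3),
             f1 = numeric(nvox), f2 = numeric(nvox),
             nfib = array(0L, dims), tissue = array(1L, dims),
             labels = array(0L, dims), roi_table = NULL,
             artifact = array(FALSE, dims),
             masks = list(brain = array(TRUE, dims), gm = array(TRUE, dims),
                          wm = array(FALSE, dims), air = array(FALSE, dims),
                          csf = array(FALSE, dims)),
             spec = list(S0 = S0, d_wm = d_wm, d_gm = d_gm, d_csf = d_csf))
  class(ph) <- "dwi_phantom"
  if (kind == "stick" || kind == "crossing") {
    ph$orient1[] <- rep(orient / sqrt(sum(orient^2)), each = nvox)
    ph$f1[] <- f
    ph$nfib[] <- 1L
    ph$tissue[] <- 2L
    ph$masks$gm[] <- FALSE; ph$masks$wm[] <- TRUE
    if (kind == "crossing") {
      ph$orient2[] <- rep(orient2 / sqrt(sum(orient2^2)), each = nvox)
      ph$f2[] <- f2
      ph$nfib[] <- 2L
    }
  } else if (kind == "csf") {
    ph$tissue[] <- 3L
    ph$masks$gm[] <- FALSE
  }
  ph
}

center_mask <- function(dims = c(5, 5, 5)) {
  m <- array(FALSE, dims)
  m[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- TRUE
  m
}

# Straight-bundle phantom for tracking tests: bundle along x, seed box at
# the low-x end, target box at the high-x end.
straight_bundle_phantom <- function(dims = c(20, 20, 20)) {
  sp <- phantom_spec(dims = dims, voxsize = c(2, 2, 2),
                     bundles = list(fiber_bundle(
                       rbind(c(2, 9.5, 9.5), c(17, 9.5, 9.5)),
                       radius = 1, f = 1)),
                     brain_radius = c(9.5, 8.5, 8))
  ph <- make_phantom(sp)
  seedm <- array(FALSE, dims)
  seedm[3, 9:11, 9:11] <- ph$nfib[3, 9:11, 9:11] > 0
  targm <- array(FALSE, dims)
  targm[16:17, 8:12, 8:12] <- TRUE
  list(phantom = ph, seed = seedm, target = targm)
}

# Deterministic single-sample fiber model over an explicit orientation
# assignment: `sel` is a logical vector over voxels, `orient` an n x 3
# matrix (or single vector) of unit directions.
field_model <- function(dims, sel, orient) {
  nvox <- prod(dims)
  ors <- matrix(0, nvox, 3)
  if (is.matrix(orient)) ors[sel, ] <- orient
  else ors[sel, ] <- rep(orient, each = sum(sel))
  ph <- list(dims = dims, voxsize = c(2, 2, 2), orient1 = ors,
             orient2 = matrix(0, nvox, 3), f1 = as.numeric(sel),
             f2 = numeric(nvox), nfib = array(as.integer(sel), dims))
  class(ph) <- "dwi_phantom"
  fiber_model_from_phantom(ph)
}

angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

# Small acquisition for tests that do not need the full 32-direction scheme
small_gtab <- function(ndir = 12, bval = 800) default_gradient_table(ndir, bval)
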