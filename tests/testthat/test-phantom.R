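test_that("gradient tables validate their invariants", {
  gt <- default_gradient_table(32, 800, 1)
  expect_length(gt, 33)
  expect_equal(sum(gt$bvals == 0), 1)
  nrm <- sqrt(colSums(gt$bvecs[, gt$bvals > 0]^2))
  expect_true(all(abs(nrm - 1) < 1e-6))
  # directions are well spread: no two closer than 15 degrees (axially)
  v <- t(gt$bvecs[, gt$bvals > 0])
  cosmax <- max(abs(v %*% t(v))[upper.tri(diag(32))])
  expect_lt(cosmax, cos(15 * pi / 180))

  expect_error(gradient_table(c(800, 800), matrix(c(1, 0, 0, 0, 1, 0), 3)),
               "b0")
  expect_error(gradient_table(c(0, -1), matrix(0, 3, 2)), "non-negative")
  expect_error(gradient_table(c(0, 800), cbind(c(0, 0, 0), c(2, 0, 0))),
               "unit")
})

test_that("bvals/bvecs round-trip through FSL-dialect text files", {
  gt <- default_gradient_table(12)
  bv <- tempfile(); bc <- tempfile()
  write_bvalbvec(gt, bv, bc)
  gt2 <- read_bvalbvec(bv, bc)
  expect_equal(gt2$bvals, gt$bvals)
  expect_equal(unname(gt2$bvecs), unname(gt$bvecs), tolerance = 1e-9)
  expect_length(readLines(bc), 3)
})

test_that("straight and crossing bundles rasterise with correct orientations", {
  sp <- phantom_spec(dims = c(20, 20, 20),
                     bundles = list(fiber_bundle(
                       rbind(c(2, 9.5, 9.5), c(17, 9.5, 9.5)), radius = 1)),
                     brain_radius = 9)
  ph <- make_phantom(sp)
  bundle_vox <- which(as.vector(ph$nfib) > 0)
  expect_gt(length(bundle_vox), 10)
  expect_true(all(abs(ph$orient1[bundle_vox, 1]) == 1))
  expect_true(all(ph$orient1[bundle_vox, 2:3] == 0))

  spx <- phantom_spec(dims = c(20, 20, 20),
                      bundles = list(
                        fiber_bundle(rbind(c(2, 9.5, 9.5), c(17, 9.5, 9.5)), radius = 1),
                        fiber_bundle(rbind(c(9.5, 2, 9.5), c(9.5, 17, 9.5)), radius = 1)),
                      brain_radius = 9)
  phx <- make_phantom(spx)
  cross <- which(as.vector(phx$nfib) == 2L)
  expect_gt(length(cross), 0)
  for (v in cross) {
    expect_equal(abs(phx$orient1[v, ]), c(1, 0, 0))
    expect_equal(abs(phx$orient2[v, ]), c(0, 1, 0))
  }
})

test_that("curved-bundle orientations track the analytic tangent within 10 degrees", {
  # quarter circle of radius 8 voxels in the x-z plane
  t <- seq(0, pi / 2, length.out = 9)
  wp <- cbind(10 - 8 * cos(t), 9.5, 2 + 8 * sin(t))
  sp <- phantom_spec(dims = c(20, 20, 20),
                     bundles = list(fiber_bundle(wp, radius = 1)),
                     brain_radius = 9.5)
  ph <- make_phantom(sp)
  g <- as.matrix(expand.grid(x = 0:19, y = 0:19, z = 0:19))
  for (v in which(as.vector(ph$nfib) > 0)) {
    # analytic tangent at the angle of this voxel on the arc
    ang <- atan2(g[v, 3] - 2, 10 - g[v, 1])
    tang <- c(sin(ang), 0, cos(ang))
    expect_lt(angle_deg(ph$orient1[v, ], tang), 10)
  }
})

test_that("invalid phantom geometry is rejected with informative errors", {
  expect_error(make_phantom(phantom_spec(
    dims = c(10, 10, 10),
    bundles = list(fiber_bundle(rbind(c(2, 5, 5), c(15, 5, 5)), 1)))),
    "leaves the grid")
  rois <- rbind(
    data.frame(name = "A", role = "seed", cx = 5, cy = 5, cz = 5, radius = 2),
    data.frame(name = "B", role = "target", cx = 6, cy = 5, cz = 5, radius = 2))
  expect_error(make_phantom(phantom_spec(dims = c(12, 12, 12),
                                         brain_radius = 5, rois = rois)),
               "'A' and 'B'")
  expect_error(phantom_spec(artifact = list(center = c(5, 5, 5), radius = 2,
                                            attenuation = 1.5)),
               "\\[0, 1\\]")
  expect_error(fiber_bundle(rbind(c(0, 0, 0), c(1, 1, 1)), radius = 0),
               "radius")
})

test_that("noiseless simulated signal matches the ball-and-stick closed form", {
  gt <- gradient_table(c(0, 800, 800, 800),
                       cbind(c(0, 0, 0), diag(3)))
  # isotropic voxel, d_gm = 1.0e-3: S = S0 exp(-0.8) in every DW volume
  ph <- uniform_phantom("iso", d_gm = 1.0e-3)
  dwi <- simulate_dwi(ph, gt, sigma = 0)
  S <- matrix(dwi$signal, prod(ph$dims), 4)
  expect_equal(S[, 1], rep(1000, nrow(S)))
  expect_lt(max(abs(S[, 2:4] / (1000 * exp(-0.8)) - 1)), 1e-12)

  # stick f = 1 along x: perpendicular gradient leaves S = S0
  phs <- uniform_phantom("stick", f = 1, orient = c(1, 0, 0))
  dws <- simulate_dwi(phs, gt, sigma = 0)
  Ss <- matrix(dws$signal, prod(phs$dims), 4)
  expect_equal(Ss[, 3], rep(1000, nrow(Ss)))  # gradient (0,1,0)
  expect_equal(Ss[, 4], rep(1000, nrow(Ss)))  # gradient (0,0,1)
  expect_equal(Ss[, 2], rep(1000 * exp(-800 * 1.2e-3), nrow(Ss)),
               tolerance = 1e-12)             # parallel gradient
  expect_equal(Ss[, 1], rep(1000, nrow(Ss)))  # b0 independent of orientation

  # crossing voxel: both sticks plus ball, exact closed form
  phx <- uniform_phantom("crossing", f = 0.4, f2 = 0.4)
  dwx <- simulate_dwi(phx, gt, sigma = 0)
  Sx <- matrix(dwx$signal, prod(phx$dims), 4)
  d <- 1.2e-3; b <- 800
  # gradient (1,0,0): parallel to stick 1, perpendicular to stick 2
  expected <- 1000 * (0.2 * exp(-b * d) + 0.4 * exp(-b * d) + 0.4)
  expect_equal(Sx[, 2], rep(expected, nrow(Sx)), tolerance = 1e-12)

  # fractions above 1 are rejected
  phbad <- uniform_phantom("crossing", f = 0.7, f2 = 0.7)
  expect_error(simulate_dwi(phbad, gt, 0), "sum above 1")
})

test_that("Rician noise has the theoretical background moments and is seed-reproducible", {
  gt <- small_gtab()
  sp <- phantom_spec(dims = c(24, 24, 24), brain_radius = 4)
  ph <- make_phantom(sp)
  sigma <- 50
  dwi <- simulate_dwi(ph, gt, sigma = sigma, seed = 7)
  air <- as.vector(ph$masks$air)
  S <- matrix(dwi$signal, prod(ph$dims), length(gt$bvals))
  bg <- as.vector(S[air, ])          # >= 1e5 samples
  expect_gt(length(bg), 1e5)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(sd(bg), sigma * sqrt(2 - pi / 2), tolerance = 0.02)

  dwi2 <- simulate_dwi(ph, gt, sigma = sigma, seed = 7)
  expect_identical(dwi$signal, dwi2$signal)
  dwi3 <- simulate_dwi(ph, gt, sigma = sigma, seed = 8)
  expect_false(identical(dwi$signal, dwi3$signal))
})

test_that("artifact application is a pure masked multiplication", {
  gt <- small_gtab(6)
  ph <- uniform_phantom("iso")
  dwi <- simulate_dwi(ph, gt, sigma = 10, seed = 1)
  mask <- center_mask(ph$dims)

  out1 <- apply_artifact(dwi, mask, 1)
  expect_identical(out1$signal, dwi$signal)

  out0 <- apply_artifact(dwi, mask, 0)
  expect_true(all(out0$signal[3, 3, 3, ] == 0))
  expect_identical(out0$signal[-3, , , ], dwi$signal[-3, , , ])

  outp <- apply_artifact(dwi, mask, 0.1)
  expect_equal(outp$signal[3, 3, 3, ], 0.1 * dwi$signal[3, 3, 3, ])
  expect_error(apply_artifact(dwi, mask, 1.2), "\\[0, 1\\]")
})

test_that("rigid motion resampling honours identity, integer shifts and determinism", {
  gt <- small_gtab(6)
  ph <- make_phantom(phantom_spec(dims = c(16, 16, 16), brain_radius = 5))
  dwi <- simulate_dwi(ph, gt, sigma = 5, seed = 1)
  n <- length(gt$bvals)
  idt <- data.frame(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0)[rep(1, n), ]
  expect_equal(apply_motion(dwi, idt)$signal, dwi$signal, tolerance = 1e-6)

  # 1-voxel (2 mm) translation is an exact index shift under trilinear
  sh <- idt; sh$tx[2] <- 2
  shifted <- apply_motion(dwi, sh)
  expect_equal(shifted$signal[1:15, , , 2], dwi$signal[2:16, , , 2],
               tolerance = 1e-12)

  m <- random_rigid_motion(gt, 0.5, 0.5, seed = 3)
  expect_true(all(m[gt$bvals == 0, ] == 0))
  a <- apply_motion(dwi, m)
  b <- apply_motion(dwi, m)
  expect_identical(a$signal, b$signal)

  big <- idt; big$tx[-1] <- 30
  expect_error(apply_motion(dwi, big), "25%")
  nb0 <- idt; nb0$tx[1] <- 1
  expect_error(apply_motion(dwi, nb0), "b0")
})

test_that("session directories round-trip through NIfTI + bval/bvec files", {
  gt <- small_gtab(6)
  ph <- make_phantom(default_phantom_spec())
  dwi <- simulate_dwi(ph, gt, sigma = 2.4, seed = 1)
  dir <- file.path(tempdir(), "sess")
  write_session(dwi, dir, labels = ph$labels, artifact = ph$artifact,
                truth = list(sigma = 2.4))
  expect_true(all(file.exists(file.path(dir, c("dwi.nii.gz", "bvals", "bvecs",
                                               "labels.nii.gz", "truth.json")))))
  back <- read_session(dir)
  expect_equal(back$signal, dwi$signal, tolerance = 1e-5)
  expect_equal(back$gtab$bvals, gt$bvals)
  expect_equal(back$voxsize, dwi$voxsize)
  expect_equal(attr(back, "labels"), array(as.integer(ph$labels), dim(ph$labels)))
  unlink(dir, recursive = TRUE)
})
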