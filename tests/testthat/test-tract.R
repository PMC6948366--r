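# Ball-and-stick fitting and probabilistic tracking. The MCMC tests fit a
# single voxel of a uniform phantom; tracking oracles use deterministic
# single-sample models built from ground-truth orientation fields.

test_that("a noiseless single-stick voxel is recovered by the MCMC fit", {
  gt <- default_gradient_table()
  ph <- uniform_phantom("stick", f = 0.7, orient = c(1, 0, 0))
  dwi <- simulate_dwi(ph, gt, sigma = 0)
  mask <- center_mask(ph$dims)
  fm <- fit_ball_and_stick(dwi, mask = mask, seed = 1)
  expect_gte(fm$support[3, 3, 3], 1L)
  sd1 <- stick_directions(fm, c(3, 3, 3))
  expect_lt(angle_deg(sd1[[1]]$direction, c(1, 0, 0)), 5)
  expect_lt(abs(sd1[[1]]$mean_f - 0.7), 0.05)
  v <- which(as.vector(mask))
  expect_lt(abs(mean(fm$d[, v]) - 1.2e-3), 2e-4)
  expect_equal(fm$K, 50)
  expect_true(fm$acceptance[3, 3, 3] > 0.05 && fm$acceptance[3, 3, 3] < 0.95)
})

test_that("isotropic voxels do not grow spurious sticks", {
  gt <- default_gradient_table()
  ph <- uniform_phantom("iso")
  mask <- center_mask(ph$dims)
  supported <- 0
  for (r in 1:10) {
    dwi <- simulate_dwi(ph, gt, sigma = 25, seed = 100 + r)
    fm <- suppressWarnings(fit_ball_and_stick(dwi, mask = mask, seed = 200 + r))
    if (fm$support[3, 3, 3] > 0) supported <- supported + 1
  }
  expect_lte(supported, 1)  # no stick support in >= 90% of repeats
})

test_that("two orthogonal sticks are resolved at SNR 40", {
  gt <- default_gradient_table()
  ph <- uniform_phantom("crossing", f = 0.4, f2 = 0.4)
  mask <- center_mask(ph$dims)
  good <- 0
  for (r in 1:5) {
    dwi <- simulate_dwi(ph, gt, sigma = 25, seed = r)  # S0/sigma = 40
    fm <- suppressWarnings(fit_ball_and_stick(dwi, mask = mask, seed = 100 + r))
    if (fm$support[3, 3, 3] != 2L) next
    ds <- stick_directions(fm, c(3, 3, 3))
    e1 <- min(angle_deg(ds[[1]]$direction, c(1, 0, 0)),
              angle_deg(ds[[1]]$direction, c(0, 1, 0)))
    e2 <- min(angle_deg(ds[[2]]$direction, c(1, 0, 0)),
              angle_deg(ds[[2]]$direction, c(0, 1, 0)))
    sep <- angle_deg(ds[[1]]$direction, ds[[2]]$direction)
    if (e1 < 15 && e2 < 15 && sep > 60) good <- good + 1
  }
  expect_gte(good, 4)
})

test_that("fiber model samples satisfy their invariants", {
  gt <- default_gradient_table()
  ph <- uniform_phantom("crossing", f = 0.45, f2 = 0.35)
  dwi <- simulate_dwi(ph, gt, sigma = 25, seed = 5)
  mask <- array(FALSE, ph$dims); mask[2:3, 3, 3] <- TRUE
  fm <- suppressWarnings(fit_ball_and_stick(dwi, mask = mask, seed = 6))
  for (v in which(as.vector(mask))) {
    expect_true(all(fm$f1[, v] >= 0 & fm$f2[, v] >= 0))
    expect_true(all(fm$f1[, v] + fm$f2[, v] <= 1 + 1e-12))
    expect_true(all(fm$d[, v] > 0))
  }
  expect_gte(fm$K, 50)
})

test_that("a straight noise-free bundle tracks seed-to-target with certainty", {
  sb <- straight_bundle_phantom()
  fm <- fiber_model_from_phantom(sb$phantom)
  tp <- tracking_params(samples = 100, step = 0.5, curvature = 0.2)
  res <- track(fm, sb$seed, sb$target, tp, seed = 1)
  expect_true(all(res$success[sb$seed] == 100))
  expect_equal(connection_probability_index(res), 100)
  expect_equal(streamline_density(res), 100)
  # visitation conservation: seed voxel itself plus the path
  expect_gte(sum(res$visitation > 0), 2)
  expect_true(all(res$visitation[res$visitation > 0] >= 1))

  expect_error(track(fm, array(FALSE, sb$phantom$dims), sb$target, tp),
               "empty")
  expect_error(track(fm, sb$seed, sb$seed, tp), "intersect")
})

test_that("an instantaneous 90-degree turn terminates all streamlines at threshold 0.2", {
  dims <- c(20, 20, 20)
  g <- as.matrix(expand.grid(x = 0:19, y = 0:19, z = 0:19))
  sel1 <- g[, 1] < 10 & g[, 2] == 10 & g[, 3] == 10
  sel2 <- g[, 1] == 10 & g[, 2] >= 10 & g[, 3] == 10
  ors <- matrix(0, prod(dims), 3)
  ors[sel1, ] <- rep(c(1, 0, 0), each = sum(sel1))
  ors[sel2, ] <- rep(c(0, 1, 0), each = sum(sel2))
  fm <- field_model(dims, sel1 | sel2, ors[sel1 | sel2, ])
  seedm <- array(FALSE, dims); seedm[3, 11, 11] <- TRUE
  targm <- array(FALSE, dims); targm[11, 18:20, 11] <- TRUE
  res <- track(fm, seedm, targm, tracking_params(samples = 100), seed = 2)
  expect_equal(sum(res$success), 0)

  # threshold -1 admits any bend: the turn becomes passable
  res2 <- track(fm, seedm, targm,
                tracking_params(samples = 100, curvature = -1), seed = 3)
  expect_gt(sum(res2$success), 0)
})

test_that("stricter curvature thresholds never admit more streamlines", {
  # deterministic quarter-arc: per-step bend cos ~ 0.9997, so success
  # collapses exactly when the threshold crosses it
  t <- seq(0, pi / 2, length.out = 12)
  wp <- cbind(15 - 12 * cos(t), 9.5, 3 + 12 * sin(t))
  sp <- phantom_spec(dims = c(20, 20, 20),
                     bundles = list(fiber_bundle(wp, radius = 1.2)),
                     brain_radius = 9.5)
  ph <- make_phantom(sp)
  fm <- fiber_model_from_phantom(ph)
  seedm <- array(FALSE, ph$dims); seedm[4, 10, 4] <- ph$nfib[4, 10, 4] > 0
  expect_true(any(seedm))
  targm <- array(FALSE, ph$dims); targm[15:16, 9:11, 14:16] <- TRUE
  succ <- vapply(c(0.0, 0.2, 0.9, 0.9995, 0.99999), function(cv)
    sum(track(fm, seedm, targm, tracking_params(samples = 50, curvature = cv),
              seed = 4)$success), numeric(1))
  expect_true(all(diff(succ) <= 0))
  expect_gt(succ[2], 0)      # 0.2 passes a gentle arc
  expect_equal(succ[5], 0)   # near-1 threshold forbids any bend
})

test_that("success counts scatter like binomial draws across RNG streams", {
  # partial mid-bundle dropout at the post-session noise level puts the
  # per-sample success probability well inside (0, 1)
  ph <- make_phantom(default_phantom_spec())
  gt <- default_gradient_table()
  fitmask <- array(FALSE, ph$dims); fitmask[3:22, 9:15, 9:15] <- TRUE
  post <- add_rician_noise(
    apply_artifact(simulate_dwi(ph, gt, 0, session = "post"),
                   ph$artifact, 0.6), 93, seed = 12)
  fm <- suppressWarnings(fit_ball_and_stick(post, mask = fitmask & ph$masks$brain,
                                            seed = 22))
  seedm <- ph$labels == 1
  targm <- ph$labels == 2
  n <- 60
  runs <- vapply(1:20, function(r)
    as.vector(track(fm, seedm, targm, tracking_params(samples = n),
                    ph$masks$brain, seed = 400 + r)$success[seedm]),
    numeric(sum(seedm)))
  phat <- rowMeans(runs) / n
  keep <- phat > 0.05 & phat < 0.95
  expect_gt(sum(keep), 5)
  var_obs <- apply(runs[keep, , drop = FALSE], 1, var)
  var_bin <- n * phat[keep] * (1 - phat[keep])
  ratio <- mean(var_obs / var_bin)
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 2.5)
})

test_that("successful streamlines visit at least seed plus one voxel", {
  sb <- straight_bundle_phantom()
  fm <- fiber_model_from_phantom(sb$phantom)
  res <- track(fm, sb$seed, sb$target, tracking_params(samples = 10), seed = 9)
  nsucc <- sum(res$success)
  expect_gt(nsucc, 0)
  # each success increments at least 2 distinct voxels in the visitation map
  expect_gte(sum(res$visitation), 2 * nsucc)
  expect_true(all(res$visitation[!sb$phantom$masks$brain &
                                   !array(FALSE, sb$phantom$dims)] >= 0))
})
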