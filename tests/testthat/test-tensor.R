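# The independent tensor oracle (simulate_tensor_signal / tensor_dwi) lives
# in helper-oracles.R; it forward-simulates the mono-exponential closed form
# without touching the phantom machinery.

test_that("noiseless single-tensor data recovers eigenvalues to 1e-9 relative", {
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  tf <- fit_tensor(tensor_dwi(lam))
  v <- which(as.vector(tf$valid))[1]
  expect_equal(tf$evals[v, ], lam, tolerance = 1e-9)
  # rotated tensor: eigenvalues invariant, principal eigenvector recovered
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  tfr <- fit_tensor(tensor_dwi(lam, evecs = R))
  expect_equal(tfr$evals[v, ], lam, tolerance = 1e-9)
  expect_lt(angle_deg(tfr$evecs[v, , 1], R[, 1]), 0.01)
})

test_that("degenerate voxels are handled: isotropy, zero diffusivity, zero signal", {
  lamiso <- rep(1e-3, 3)
  tf <- fit_tensor(tensor_dwi(lamiso))
  v <- which(as.vector(tf$valid))[1]
  expect_equal(tf$evals[v, ], lamiso, tolerance = 1e-9)

  # constant signal for all b: zero tensor
  gt <- default_gradient_table(12)
  dims <- c(4, 4, 4)
  arr <- array(1000, c(dims, length(gt$bvals)))
  dwi <- dwi_volume(arr, gt, c(2, 2, 2), "pre",
                    masks = list(brain = array(TRUE, dims)))
  tf0 <- fit_tensor(dwi)
  expect_equal(max(abs(tf0$evals)), 0, tolerance = 1e-12)

  # all-zero voxel is invalid, not an error
  arr[1, 1, 1, ] <- 0
  dwi2 <- dwi_volume(arr, gt, c(2, 2, 2), "pre",
                     masks = list(brain = array(TRUE, dims)))
  tf2 <- fit_tensor(dwi2)
  expect_false(tf2$valid[1, 1, 1])
  expect_true(tf2$valid[2, 1, 1])
})

test_that("scalar maps obey the FA/MD/RD closed forms", {
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  tf <- fit_tensor(tensor_dwi(lam))
  v <- which(as.vector(tf$valid))[1]
  fa <- scalar_map(tf, "fa"); md <- scalar_map(tf, "md"); rd <- scalar_map(tf, "rd")
  # hand-evaluated: MD = 0.76667e-3, RD = 0.3e-3,
  # FA = sqrt(3/2)*||lam - mean||/||lam|| = 0.79905
  expect_equal(as.vector(md$values)[v], 0.76667e-3, tolerance = 1e-4)
  expect_equal(as.vector(rd$values)[v], 0.3e-3, tolerance = 1e-9)
  expect_equal(as.vector(fa$values)[v], 0.799, tolerance = 1e-3)
  expect_equal(as.vector(fa$values)[v],
               sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2)),
               tolerance = 1e-12)

  tfi <- fit_tensor(tensor_dwi(rep(1e-3, 3)))
  expect_equal(as.vector(scalar_map(tfi, "fa")$values)[v], 0, tolerance = 1e-6)
  expect_equal(as.vector(scalar_map(tfi, "md")$values)[v], 1e-3, tolerance = 1e-9)
  expect_equal(as.vector(scalar_map(tfi, "rd")$values)[v], 1e-3, tolerance = 1e-9)

  # perfect anisotropy limit via a synthetic tensor field
  tf1 <- tf
  tf1$evals[v, ] <- c(1, 0, 0)
  expect_equal(as.vector(scalar_map(tf1, "fa")$values)[v], 1, tolerance = 1e-12)

  expect_error(scalar_map(tf, "adc"), "arg")
})

test_that("FA stays in [0,1] and MD is rotation invariant", {
  ph <- make_phantom(default_phantom_spec())
  gt <- default_gradient_table()
  dwi <- simulate_dwi(ph, gt, sigma = 40, seed = 11)
  tf <- fit_tensor(dwi)
  fa <- scalar_map(tf, "fa")
  vals <- fa$values[fa$valid]
  expect_true(all(vals >= 0 & vals <= 1))
  md <- scalar_map(tf, "md")
  expect_true(all(md$values[md$valid] >= 0))

  # rotating gradients and fiber together leaves MD unchanged
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  gt0 <- default_gradient_table(12)
  v1 <- c(1, 0, 0)
  ph1 <- uniform_phantom("stick", orient = v1)
  ph2 <- uniform_phantom("stick", orient = as.numeric(R %*% v1))
  gt2 <- gt0; gt2$bvecs <- R %*% gt0$bvecs
  md1 <- scalar_map(fit_tensor(simulate_dwi(ph1, gt0, 0)), "md")
  md2 <- scalar_map(fit_tensor(simulate_dwi(ph2, gt2, 0)), "md")
  i <- which(as.vector(md1$valid))[1]
  expect_equal(as.vector(md2$values)[i], as.vector(md1$values)[i],
               tolerance = 1e-6)
})

test_that("low SNR biases FA upward in isotropic tissue", {
  # small all-GM phantom; mean FA over the region must not decrease as
  # sigma rises through 0, 20, 40, 80
  sp <- phantom_spec(dims = c(10, 10, 10), brain_radius = 4)
  ph <- make_phantom(sp)
  gt <- default_gradient_table()
  sigmas <- c(0, 20, 40, 80)
  reps <- 5
  mean_fa <- vapply(sigmas, function(sg) {
    mean(vapply(seq_len(reps), function(r) {
      dwi <- simulate_dwi(ph, gt, sigma = sg, seed = 1000 * sg + r)
      fa <- scalar_map(fit_tensor(dwi), "fa")
      mean(fa$values[ph$masks$gm & fa$valid])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fa) >= 0))
  expect_lt(mean_fa[1], 1e-6)     # noiseless isotropic: FA ~ 0
  expect_gt(mean_fa[4], 0.05)     # heavy noise: clear upward bias
})
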