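# Independent oracle for the tensor stage: forward-simulate noiseless
# signal from a known tensor with the mono-exponential closed form
# S = S0 exp(-b g'Dg), bypassing the package's phantom machinery.
simulate_tensor_signal <- function(gtab, lambda, evecs = diag(3), S0 = 1000) {
  D <- evecs %*% diag(lambda) %*% t(evecs)
  vapply(seq_along(gtab$bvals), function(v) {
    g <- gtab$bvecs[, v]
    S0 * exp(-gtab$bvals[v] * as.numeric(t(g) %*% D %*% g))
  }, numeric(1))
}

tensor_dwi <- function(lambda, evecs = diag(3), dims = c(4, 4, 4),
                       gtab = default_gradient_table()) {
  sig <- simulate_tensor_signal(gtab, lambda, evecs)
  arr <- array(rep(sig, each = prod(dims)), c(dims, length(sig)))
  dwi_volume(arr, gtab, c(2, 2, 2), "pre",
             masks = list(brain = array(TRUE, dims), gm = array(TRUE, dims),
                          wm = array(FALSE, dims), air = array(FALSE, dims)))
}
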