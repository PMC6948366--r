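#' Tracking parameters
#'
#' Defaults follow common probabilistic-tractography practice: 5000 samples
#' per seed voxel, 0.5 mm steps, curvature threshold 0.2 (the minimum cosine
#' between successive step directions, about a 78.5 degree maximal bend per
#' step) and loop checking on. Test-scale runs typically reduce `samples` to
#' 500.
#'
#' @param samples streamline samples per seed voxel (`>= 1`).
#' @param step step length in mm (`> 0`).
#' @param curvature minimum cosine between successive step directions, in
#'   `[-1, 1]`.
#' @param loopcheck terminate streamlines that double back (entry directions
#'   recorded on a half-resolution grid; re-entry with direction reversed
#'   beyond 90 degrees terminates).
#' @param max_steps cap on steps per half-tract.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(samples = 5000, step = 0.5, curvature = 0.2,
                            loopcheck = TRUE, max_steps = 2000) {
  stopifnot(samples >= 1, step > 0, curvature >= -1, curvature <= 1,
            max_steps >= 1)
  structure(list(samples = as.integer(samples), step = step,
                 curvature = curvature, loopcheck = loopcheck,
                 max_steps = as.integer(max_steps)),
            class = "tracking_params")
}

#' Fit the Bayesian ball-and-stick fiber model by MCMC
#'
#' Per brain voxel, a Metropolis-Hastings chain samples the posterior of the
#' ball-and-stick parameters (S0, diffusivity d, up to two stick fractions
#' f1/f2 with orientations) under a Gamma prior on d, a uniform-on-sphere
#' prior on orientations and an automatic-relevance (ARD) prior on the stick
#' fractions that shrinks unsupported sticks toward zero. The noise
#' precision is Gibbs-updated with a floor of `sigma_floor_frac * S0` so
#' that noise-free inputs remain numerically fittable. Retained samples
#' (after burn-in, thinned) form the per-voxel posterior set used by
#' [track()].
#'
#' Per-voxel fiber support is decided from the posterior mean fractions:
#' 2 sticks if both mean fractions exceed `f_threshold` and the two
#' posterior mean dyads are at least `merge_angle` degrees apart, 1 if a
#' single stick is supported, else 0. Two aligned sticks are one fiber
#' modeled twice — the likelihood cannot apportion a fraction between
#' coincident sticks — so their samples are merged (fractions summed into
#' the first stick). Voxels whose post-burn-in acceptance rate falls
#' outside [0.05, 0.95] are flagged (a warning reports the count).
#'
#' @param dwi a [dwi_volume()] (single shell, at least one b0).
#' @param mask voxels to fit (defaults to the brain mask).
#' @param njumps post-burn-in jumps; `njumps / thin` samples are retained
#'   (at least 50 with the defaults).
#' @param burnin burn-in iterations (proposal widths adapt here).
#' @param thin thinning interval.
#' @param d_shape,d_rate Gamma prior on the diffusivity (default mean
#'   `d_shape / d_rate` = 1.2e-3 mm^2/s).
#' @param ard_f1,ard_f2 apply the ARD shrinkage prior to each stick.
#' @param f_threshold posterior-mean fraction needed to support a stick.
#' @param merge_angle sticks whose posterior mean dyads are closer than
#'   this angle (degrees) count as one fiber and are merged.
#' @param sigma_floor_frac noise-sigma floor as a fraction of the voxel S0.
#' @param seed RNG seed.
#' @return A `fiber_model`: K x nvox posterior sample matrices (`f1`, `f2`,
#'   `th1`, `ph1`, `th2`, `ph2`, `d`, `s0`), per-voxel `support` (0/1/2),
#'   `acceptance` and `flagged`.
#' @export
fit_ball_and_stick <- function(dwi, mask = dwi$masks$brain, njumps = 1250,
                               burnin = 1000, thin = 25, d_shape = 3,
                               d_rate = 2500, ard_f1 = TRUE, ard_f2 = TRUE,
                               f_threshold = 0.05, merge_angle = 30,
                               sigma_floor_frac = 1e-3, seed = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (!any(dwi$gtab$bvals == 0)) stop("at least one b0 volume is required")
  if (is.null(mask)) stop("a brain mask is required")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(dwi$signal)
  nvox <- prod(d[1:3])
  idx <- which(as.vector(mask) > 0)
  S <- matrix(dwi$signal, nvox, d[4])
  fit <- cpp_bedpost(t(S[idx, , drop = FALSE]), dwi$gtab$bvals,
                     dwi$gtab$bvecs, as.integer(njumps), as.integer(burnin),
                     as.integer(thin), d_shape, d_rate, ard_f1, ard_f2,
                     sigma_floor_frac)
  K <- nrow(fit$f1)
  full <- function(m) {
    out <- matrix(0, K, nvox)
    out[, idx] <- m
    out
  }
  dyad_dir <- function(th, ph) {
    d <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    eigen(crossprod(d) / nrow(d), symmetric = TRUE)$vectors[, 1]
  }
  mf1 <- colMeans(fit$f1); mf2 <- colMeans(fit$f2)
  merge_cos <- cos(merge_angle * pi / 180)
  support <- integer(nvox)
  for (j in seq_along(idx)) {
    if (fit$flagged[j]) next
    a <- mf1[j] > f_threshold; b <- mf2[j] > f_threshold
    if (!a && !b) next
    v <- idx[j]
    if (a && b) {
      d1 <- dyad_dir(fit$th1[, j], fit$ph1[, j])
      d2 <- dyad_dir(fit$th2[, j], fit$ph2[, j])
      if (abs(sum(d1 * d2)) > merge_cos) {
        # coincident sticks are one fiber modeled twice: merge
        fit$f1[, j] <- fit$f1[, j] + fit$f2[, j]
        fit$f2[, j] <- 0
        support[v] <- 1L
      } else support[v] <- 2L
    } else if (a) {
      support[v] <- 1L
    } else {
      # the fiber lives in chain 2 only: swap the chains
      for (nm in c("f", "th", "ph")) {
        tmp <- fit[[paste0(nm, "1")]][, j]
        fit[[paste0(nm, "1")]][, j] <- fit[[paste0(nm, "2")]][, j]
        fit[[paste0(nm, "2")]][, j] <- tmp
      }
      support[v] <- 1L
    }
  }
  nflag <- sum(fit$flagged)
  if (nflag > 0)
    warning(nflag, " voxel(s) flagged: MCMC acceptance rate outside [0.05, 0.95]")
  acceptance <- numeric(nvox); acceptance[idx] <- fit$acceptance
  flagged <- logical(nvox); flagged[idx] <- fit$flagged
  structure(list(f1 = full(fit$f1), f2 = full(fit$f2), th1 = full(fit$th1),
                 ph1 = full(fit$ph1), th2 = full(fit$th2),
                 ph2 = full(fit$ph2), d = full(fit$d), s0 = full(fit$s0),
                 support = array(support, d[1:3]),
                 acceptance = array(acceptance, d[1:3]),
                 flagged = array(flagged, d[1:3]),
                 K = K, dims = d[1:3], voxsize = dwi$voxsize,
                 session = dwi$session), class = "fiber_model")
}

#' Posterior mean stick orientations at a voxel
#'
#' Fiber orientations are axial (v and -v are the same fiber), so the
#' posterior mean direction of each stick is taken as the principal
#' eigenvector of the mean dyadic tensor \eqn{\langle v v^T \rangle} over
#' the retained samples, with the corresponding eigenvalue as a
#' concentration measure (1 = all samples aligned, 1/3 = isotropic).
#'
#' @param model a `fiber_model`.
#' @param voxel voxel index (length-3 integer, 1-based) or linear index.
#' @return List of one entry per supported stick: `direction` (unit vector),
#'   `concentration`, `mean_f`.
#' @export
stick_directions <- function(model, voxel) {
  stopifnot(inherits(model, "fiber_model"))
  v <- if (length(voxel) == 3)
    voxel[1] + model$dims[1] * ((voxel[2] - 1) + model$dims[2] * (voxel[3] - 1))
  else voxel
  sup <- as.vector(model$support)[v]
  out <- list()
  for (s in seq_len(max(sup, 0))) {
    th <- model[[paste0("th", s)]][, v]
    ph <- model[[paste0("ph", s)]][, v]
    dirs <- sph_to_cart(th, ph)
    dy <- crossprod(dirs) / nrow(dirs)
    e <- eigen(dy, symmetric = TRUE)
    out[[s]] <- list(direction = e$vectors[, 1], concentration = e$values[1],
                     mean_f = mean(model[[paste0("f", s)]][, v]))
  }
  out
}

#' Deterministic fiber model from a phantom's ground-truth orientations
#'
#' Builds a single-sample (K = 1) `fiber_model` directly from the phantom's
#' orientation field, bypassing the MCMC fit. Useful as a noise-free oracle
#' for the tracking stage.
#'
#' @param phantom a [make_phantom()] result.
#' @return A `fiber_model` with one posterior sample per voxel.
#' @export
fiber_model_from_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "dwi_phantom"))
  nvox <- prod(phantom$dims)
  sph1 <- cart_to_sph(phantom$orient1 + rep(c(0, 0, 1e-12), each = nvox))
  sph2 <- cart_to_sph(phantom$orient2 + rep(c(0, 0, 1e-12), each = nvox))
  structure(list(f1 = matrix(phantom$f1, 1), f2 = matrix(phantom$f2, 1),
                 th1 = matrix(sph1[, 1], 1), ph1 = matrix(sph1[, 2], 1),
                 th2 = matrix(sph2[, 1], 1), ph2 = matrix(sph2[, 2], 1),
                 d = matrix(1e-3, 1, nvox),
                 s0 = matrix(1, 1, nvox),
                 support = phantom$nfib,
                 acceptance = array(1, phantom$dims),
                 flagged = array(FALSE, phantom$dims),
                 K = 1L, dims = phantom$dims, voxsize = phantom$voxsize,
                 session = "truth"), class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat(sprintf("Ball-and-stick fiber model (%s): %d voxels with support (%d two-fiber), K = %d samples/voxel\n",
              x$session %||% "?", sum(x$support > 0), sum(x$support == 2L),
              x$K))
  invisible(x)
}

#' Probabilistic streamline tracking with a classification target
#'
#' Launches `params$samples` streamline samples from every seed-mask voxel.
#' Each sample draws a posterior orientation realisation at every voxel it
#' enters (nearest-voxel lookup), picks a stick with probability
#' proportional to its volume fraction, sign-aligns with the previous step,
#' terminates on curvature violation, brain-mask exit, loop detection or the
#' step cap, and succeeds when it enters the target mask. Both directions
#' from the seed are propagated (two half-tracts per sample).
#'
#' @param model a `fiber_model`.
#' @param seed_mask,target_mask binary 3D masks on the model grid; they must
#'   not intersect, and the seed mask must be non-empty. An unreachable
#'   target is not an error (counts are 0).
#' @param params a [tracking_params()].
#' @param termination_mask binary mask outside which streamlines stop
#'   (default: everywhere allowed except the grid boundary). Typically the
#'   brain mask.
#' @param seed RNG seed.
#' @return A `tractography_result`: per-voxel `success` counts over the
#'   seed mask, the `visitation` map (count of successful streamlines
#'   crossing each voxel), `samples` per seed voxel and the masks.
#' @export
track <- function(model, seed_mask, target_mask, params = tracking_params(),
                  termination_mask = NULL, seed = NULL) {
  stopifnot(inherits(model, "fiber_model"), inherits(params, "tracking_params"))
  if (!is.null(seed)) set.seed(seed)
  sm <- as.integer(as.vector(seed_mask) > 0)
  tm <- as.integer(as.vector(target_mask) > 0)
  if (sum(sm) == 0) stop("seed mask is empty")
  if (any(sm & tm)) stop("seed and target masks must not intersect")
  bm <- if (is.null(termination_mask)) rep(1L, prod(model$dims))
        else as.integer(as.vector(termination_mask) > 0)
  res <- cpp_track(model$dims, model$voxsize, model$f1, model$f2, model$th1,
                   model$ph1, model$th2, model$ph2,
                   as.integer(as.vector(model$support)), sm, tm, bm,
                   params$samples, params$step, params$curvature,
                   params$loopcheck, params$max_steps)
  structure(list(success = array(res$success, model$dims),
                 visitation = array(res$visitation, model$dims),
                 samples = params$samples,
                 seed_mask = array(sm > 0, model$dims),
                 target_mask = array(tm > 0, model$dims),
                 params = params, session = model$session),
            class = "tractography_result")
}

#' @export
print.tractography_result <- function(x, ...) {
  ns <- sum(x$seed_mask)
  cat(sprintf("Tractography (%s): %d seed voxels x %d samples; index %.1f, density %.1f%%\n",
              x$session %||% "?", ns, x$samples,
              connection_probability_index(x), streamline_density(x)))
  invisible(x)
}
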