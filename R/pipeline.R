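#' Configure a pre/post phantom study
#'
#' Bundles everything [run_study()] needs: the phantom specification, the
#' acquisition scheme, per-session noise/motion settings, the artifact
#' attenuation applied to the post session, the tract definitions
#' (seed/target ROI names), tracking parameters, test levels and the master
#' RNG seed. Defaults emulate the study contrast the pipeline is built
#' around: an anesthetized high-SNR pre-operative session versus an awake,
#' implanted, low-SNR post-operative session.
#'
#' Default noise levels put the sessions in the reported SNR regimes
#' (roughly 320 pre and 8 post for an S0 of 1000); default motion scales
#' give mean per-volume translation magnitudes near 0.16 mm (pre) and
#' 0.56 mm (post), a 3.5-fold post/pre motion ratio.
#'
#' @param phantom a [phantom_spec()].
#' @param gtab a [gradient_table()].
#' @param sigma_pre,sigma_post Rician noise parameter per session.
#' @param motion_pre,motion_post per-axis standard deviation (mm and
#'   degrees) of the random per-volume rigid motion; 0 disables motion.
#' @param artifact_attenuation attenuation applied inside the phantom's
#'   artifact region in the post session (1 disables the artifact).
#' @param tracts named list of `list(seed = <roi name>, target = <roi name>)`;
#'   `NULL` derives one tract per seed/target ROI pair in specification
#'   order.
#' @param tracking a [tracking_params()]; the study default scales samples
#'   per voxel down to 500.
#' @param alpha significance level for all gates and branch tests.
#' @param master_seed integer master seed; every stochastic stage derives
#'   its own stream from it via [derive_seed()] (master seed plus a
#'   stage-name hash).
#' @param register run volume-to-b0 motion correction (can be disabled for
#'   speed when no motion is simulated).
#' @return A `study_config` list.
#' @export
study_config <- function(phantom = default_phantom_spec(),
                         gtab = default_gradient_table(),
                         sigma_pre = 2.4, sigma_post = 93,
                         motion_pre = 0.1, motion_post = 0.35,
                         artifact_attenuation = NULL,
                         tracts = NULL, tracking = tracking_params(samples = 500),
                         alpha = 0.05, master_seed = 42, register = TRUE) {
  if (is.null(artifact_attenuation))
    artifact_attenuation <- if (!is.null(phantom$artifact))
      phantom$artifact$attenuation else 1
  if (is.null(tracts) && !is.null(phantom$rois)) {
    seeds <- which(phantom$rois$role == "seed")
    targets <- which(phantom$rois$role == "target")
    n <- min(length(seeds), length(targets))
    if (n > 0)
      tracts <- stats::setNames(lapply(seq_len(n), function(i)
        list(seed = phantom$rois$name[seeds[i]],
             target = phantom$rois$name[targets[i]])),
        paste0("tract", seq_len(n)))
  }
  if (!is.null(tracts) && !is.null(phantom$rois))
    for (nm in names(tracts)) {
      tr <- tracts[[nm]]
      if (!all(c(tr$seed, tr$target) %in% phantom$rois$name))
        stop("tract '", nm, "' references ROI names absent from the phantom")
    }
  structure(list(phantom = phantom, gtab = gtab, sigma_pre = sigma_pre,
                 sigma_post = sigma_post, motion_pre = motion_pre,
                 motion_post = motion_post,
                 artifact_attenuation = artifact_attenuation,
                 tracts = tracts, tracking = tracking, alpha = alpha,
                 master_seed = as.integer(master_seed), register = register),
            class = "study_config")
}

roi_mask <- function(phantom, name) {
  lab <- phantom$roi_table$label[phantom$roi_table$name == name]
  phantom$labels == lab
}

#' Run the full pre/post phantom study
#'
#' Deterministically (under the master seed) generates both sessions,
#' applies the post-session artifact and motion, runs motion correction,
#' fits tensors and FA/MD/RD maps, computes SNR/CNR, runs the per-ROI
#' statistical decision tree with artifact-affected stratification, fits the
#' ball-and-stick model per session, tracks every configured tract, and
#' assembles the connectivity table (index of connection probability,
#' streamline density, percent change, voxel-wise Welch similarity).
#'
#' @param config a [study_config()].
#' @param outdir optional output directory; when given, CSV/JSON/NIfTI
#'   reports and a manifest are written there.
#' @param verbose print stage progress.
#' @return A `study_result` list with all stage outputs.
#' @export
run_study <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(...)
  ms <- config$master_seed
  warnings_log <- character()
  log_warn <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  say("phantom")
  phantom <- make_phantom(config$phantom)

  say("simulate")
  pre <- simulate_dwi(phantom, config$gtab, config$sigma_pre,
                      seed = derive_seed(ms, "simulate-pre"), session = "pre")
  # dropout dephases the signal before receiver noise enters, so the
  # artifact attenuates the noiseless signal and noise is added last
  post <- simulate_dwi(phantom, config$gtab, sigma = 0, session = "post")
  if (config$artifact_attenuation < 1 && any(phantom$artifact))
    post <- apply_artifact(post, phantom$artifact, config$artifact_attenuation)
  post <- add_rician_noise(post, config$sigma_post,
                           seed = derive_seed(ms, "simulate-post"))
  motion_truth <- list()
  if (config$motion_pre > 0) {
    m <- random_rigid_motion(config$gtab, config$motion_pre, config$motion_pre,
                             seed = derive_seed(ms, "motion-pre"))
    pre <- apply_motion(pre, m); motion_truth$pre <- m
  }
  if (config$motion_post > 0) {
    m <- random_rigid_motion(config$gtab, config$motion_post,
                             config$motion_post,
                             seed = derive_seed(ms, "motion-post"))
    post <- apply_motion(post, m); motion_truth$post <- m
  }

  motion <- NULL
  if (config$register) {
    say("register")
    rp <- log_warn("register-pre", register_to_b0(pre))
    ro <- log_warn("register-post", register_to_b0(post))
    pre <- rp$dwi; post <- ro$dwi
    motion <- list(pre = rp$report, post = ro$report,
                   summary = summarize_motion(ro$report, rp$report))
  }

  say("tensor")
  tf_pre <- fit_tensor(pre)
  tf_post <- fit_tensor(post)
  maps <- list()
  for (k in c("fa", "md", "rd"))
    maps[[k]] <- list(pre = scalar_map(tf_pre, k), post = scalar_map(tf_post, k))

  say("quality")
  quality <- list(
    snr = list(pre = compute_snr(pre), post = compute_snr(post)),
    cnr = list(pre = compute_cnr(pre), post = compute_cnr(post)))

  say("roistats")
  roi_results <- do.call(rbind, lapply(c("fa", "md", "rd"), function(k)
    log_warn(paste0("roistats-", k),
             compare_rois(maps[[k]]$pre, maps[[k]]$post, phantom$labels,
                          phantom$artifact, phantom$roi_table,
                          alpha = config$alpha))))
  attr(roi_results, "alpha") <- config$alpha
  cohort <- cohort_summary(roi_results, config$alpha)
  affected <- classify_affected(phantom$labels, phantom$artifact,
                                phantom$roi_table)

  fm_pre <- fm_post <- NULL
  if (length(config$tracts)) {
    say("fiber model")
    fm_pre <- log_warn("bedpost-pre",
      fit_ball_and_stick(pre, seed = derive_seed(ms, "bedpost-pre")))
    fm_post <- log_warn("bedpost-post",
      fit_ball_and_stick(post, seed = derive_seed(ms, "bedpost-post")))
  }

  say("tractography")
  tract_runs <- list()
  for (nm in names(config$tracts)) {
    tr <- config$tracts[[nm]]
    sm <- roi_mask(phantom, tr$seed)
    tm <- roi_mask(phantom, tr$target)
    tract_runs[[nm]] <- list(
      pre = track(fm_pre, sm, tm, config$tracking, phantom$masks$brain,
                  seed = derive_seed(ms, paste0("track-pre-", nm))),
      post = track(fm_post, sm, tm, config$tracking, phantom$masks$brain,
                   seed = derive_seed(ms, paste0("track-post-", nm))),
      target_mask = tm)
  }
  conn <- if (length(tract_runs)) connectivity_table(tract_runs, config$alpha)
          else NULL

  result <- structure(list(
    phantom = phantom, pre = pre, post = post, motion = motion,
    motion_truth = motion_truth, tensors = list(pre = tf_pre, post = tf_post),
    maps = maps, quality = quality, roi_results = roi_results,
    cohort = cohort, affected = affected,
    fiber_models = list(pre = fm_pre, post = fm_post), tracts = tract_runs,
    connectivity = conn, config = config, warnings = warnings_log),
    class = "study_result")

  if (!is.null(outdir)) write_study(result, outdir)
  result
}

#' Read and write a study configuration as YAML
#'
#' A single structured text file fully determines a study: phantom geometry
#' (grid, voxel size, brain radii, bundles, ROIs, artifact, signal-model
#' constants), per-session noise/motion, tract definitions, tracking
#' parameters, alpha and the master seed.
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `read_study_yaml()` returns a [study_config()].
#' @export
write_study_yaml <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  ph <- config$phantom
  y <- list(
    phantom = list(
      dims = ph$dims, voxsize = ph$voxsize, brain_radius = ph$brain_radius,
      S0 = ph$S0, d_wm = ph$d_wm, d_gm = ph$d_gm, d_csf = ph$d_csf,
      bundles = lapply(ph$bundles, function(b)
        list(name = b$name, radius = b$radius, f = b$f,
             waypoints = as.vector(t(b$waypoints)))),
      rois = if (is.null(ph$rois)) NULL else as.list(ph$rois),
      artifact = ph$artifact),
    sessions = list(sigma_pre = config$sigma_pre,
                    sigma_post = config$sigma_post,
                    motion_pre = config$motion_pre,
                    motion_post = config$motion_post,
                    artifact_attenuation = config$artifact_attenuation),
    gradients = list(ndir = sum(config$gtab$bvals > 0),
                     bval = max(config$gtab$bvals),
                     nb0 = sum(config$gtab$bvals == 0)),
    tracts = config$tracts,
    tracking = unclass(config$tracking),
    alpha = config$alpha,
    master_seed = config$master_seed,
    register = config$register)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_study_yaml
#' @export
read_study_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$phantom
  bundles <- lapply(p$bundles, function(b)
    fiber_bundle(matrix(unlist(b$waypoints), ncol = 3, byrow = TRUE),
                 radius = b$radius, f = b$f, name = b$name))
  rois <- if (is.null(p$rois)) NULL else as.data.frame(p$rois)
  spec <- phantom_spec(dims = unlist(p$dims), voxsize = unlist(p$voxsize),
                       bundles = bundles, brain_radius = unlist(p$brain_radius),
                       rois = rois, artifact = p$artifact, S0 = p$S0,
                       d_wm = p$d_wm, d_gm = p$d_gm, d_csf = p$d_csf)
  tk <- y$tracking
  study_config(phantom = spec,
               gtab = default_gradient_table(y$gradients$ndir,
                                             y$gradients$bval,
                                             y$gradients$nb0),
               sigma_pre = y$sessions$sigma_pre,
               sigma_post = y$sessions$sigma_post,
               motion_pre = y$sessions$motion_pre,
               motion_post = y$sessions$motion_post,
               artifact_attenuation = y$sessions$artifact_attenuation,
               tracts = y$tracts,
               tracking = tracking_params(tk$samples, tk$step, tk$curvature,
                                          tk$loopcheck, tk$max_steps),
               alpha = y$alpha, master_seed = y$master_seed,
               register = y$register)
}

#' Artifact dose-response experiment
#'
#' Quantifies how progressively severe signal dropout on a bundle-bisecting
#' artifact region degrades tract reconstruction. A high-SNR pre session is
#' tracked once as the reference; then, for each attenuation factor in
#' `attenuations`, a post session is simulated (noiseless signal, artifact
#' attenuation, Rician noise last), the ball-and-stick model refitted and
#' the tract retracked, and the index of connection probability, streamline
#' density and their percent changes against the pre session recorded. The
#' same derived seeds are reused across attenuations so runs differ only in
#' the attenuation factor.
#'
#' Session noise defaults to the study conditions (pre sigma 2.4, post
#' sigma 93): at the post-operative noise level every attenuation step
#' materially lowers the artifact-region contrast-to-noise, which is what
#' makes dropout severity visible to tracking.
#'
#' @param attenuations attenuation grid (decreasing severity order is not
#'   required; rows come back in the given order).
#' @param spec phantom specification; the default phantom's artifact sphere
#'   bisects the first bundle.
#' @param tract_seed,tract_target ROI names of the tracked pathway.
#' @param sigma_pre,sigma_post session noise parameters.
#' @param samples streamline samples per seed voxel.
#' @param fit_mask optional mask restricting the ball-and-stick fit (the
#'   default boxes in the first bundle and its ROIs to keep runtime small).
#' @param master_seed master RNG seed.
#' @return Data frame: one reference row (`session = "pre"`) then one row
#'   per attenuation with index, density and percent changes.
#' @export
dose_response <- function(attenuations = c(1.0, 0.5, 0.1, 0.0),
                          spec = default_phantom_spec(),
                          tract_seed = "STR", tract_target = "SN",
                          sigma_pre = 2.4, sigma_post = 93, samples = 500,
                          fit_mask = NULL, master_seed = 42) {
  phantom <- make_phantom(spec)
  gtab <- default_gradient_table()
  if (is.null(fit_mask)) {
    fit_mask <- array(FALSE, phantom$dims)
    fit_mask[3:22, 9:15, 9:15] <- TRUE
  }
  fit_mask <- fit_mask & phantom$masks$brain
  seedm <- roi_mask(phantom, tract_seed)
  targm <- roi_mask(phantom, tract_target)
  tp <- tracking_params(samples = samples)
  ms <- master_seed

  pre <- simulate_dwi(phantom, gtab, sigma_pre,
                      seed = derive_seed(ms, "dose-pre"), session = "pre")
  fm_pre <- suppressWarnings(
    fit_ball_and_stick(pre, mask = fit_mask,
                       seed = derive_seed(ms, "dose-fit-pre")))
  r_pre <- track(fm_pre, seedm, targm, tp, phantom$masks$brain,
                 seed = derive_seed(ms, "dose-track-pre"))
  ipre <- connection_probability_index(r_pre)
  dpre <- streamline_density(r_pre)

  rows <- lapply(attenuations, function(att) {
    post <- simulate_dwi(phantom, gtab, sigma = 0, session = "post")
    post <- apply_artifact(post, phantom$artifact, att)
    post <- add_rician_noise(post, sigma_post,
                             seed = derive_seed(ms, "dose-post"))
    fm <- suppressWarnings(
      fit_ball_and_stick(post, mask = fit_mask,
                         seed = derive_seed(ms, "dose-fit-post")))
    r <- track(fm, seedm, targm, tp, phantom$masks$brain,
               seed = derive_seed(ms, "dose-track-post"))
    idx <- connection_probability_index(r)
    den <- streamline_density(r)
    data.frame(session = "post", attenuation = att, index = idx,
               density = den,
               index_pct_change = if (ipre > 0) percent_change(ipre, idx) else NaN,
               density_pct_change = if (dpre > 0) percent_change(dpre, den) else NaN)
  })
  rbind(data.frame(session = "pre", attenuation = NA_real_, index = ipre,
                   density = dpre, index_pct_change = 0,
                   density_pct_change = 0),
        do.call(rbind, rows))
}

#' @export
print.study_result <- function(x, ...) {
  cat("Pre/post phantom study\n")
  cat(sprintf("  SNR: pre %.2f, post %.2f;  CNR: pre %.2f, post %.2f\n",
              x$quality$snr$pre$mean, x$quality$snr$post$mean,
              x$quality$cnr$pre$mean, x$quality$cnr$post$mean))
  if (!is.null(x$motion))
    cat(sprintf("  motion: pre %.2f mm, post %.2f mm (ratio %.2f)\n",
                summarize_motion(x$motion$pre)$mean_translation,
                summarize_motion(x$motion$post)$mean_translation,
                x$motion$summary$translation_ratio))
  cat(sprintf("  ROIs affected by artifact: %.1f%%\n",
              100 * attr(x$affected, "fraction_affected")))
  if (!is.null(x$connectivity)) {
    cat("  connectivity:\n")
    print(x$connectivity, row.names = FALSE)
  }
  invisible(x)
}

# Write the study report bundle: tidy CSVs, JSON summaries, scalar maps and
# a manifest echoing seeds and parameters.
write_study <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  write.csv(result$roi_results, file.path(outdir, "roi_comparisons.csv"),
            row.names = FALSE)
  write.csv(result$cohort, file.path(outdir, "cohort_summary.csv"),
            row.names = FALSE)
  write.csv(result$affected, file.path(outdir, "affected_rois.csv"),
            row.names = FALSE)
  if (!is.null(result$connectivity))
    write.csv(result$connectivity, file.path(outdir, "connectivity.csv"),
              row.names = FALSE)
  for (m in c("snr", "cnr")) for (s in c("pre", "post"))
    write_quality_report(result$quality[[m]][[s]],
                         json_path = file.path(outdir,
                                               sprintf("%s_%s.json", m, s)))
  if (!is.null(result$motion)) {
    write_motion_report(result$motion$pre, file.path(outdir, "motion_pre.csv"))
    write_motion_report(result$motion$post, file.path(outdir, "motion_post.csv"))
    jsonlite::write_json(result$motion$summary,
                         file.path(outdir, "motion_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (k in names(result$maps)) for (s in c("pre", "post"))
    write_scalar_map(result$maps[[k]][[s]], file.path(outdir, "maps"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dbsdti")),
    master_seed = cfg$master_seed,
    sigma = list(pre = cfg$sigma_pre, post = cfg$sigma_post),
    motion_sd = list(pre = cfg$motion_pre, post = cfg$motion_post),
    artifact_attenuation = cfg$artifact_attenuation,
    tracking = unclass(cfg$tracking), alpha = cfg$alpha,
    grid = cfg$phantom$dims, voxel_mm = cfg$phantom$voxsize,
    n_volumes = length(cfg$gtab$bvals),
    warnings = result$warnings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
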