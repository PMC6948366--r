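#' Mask-based SNR of a DWI session
#'
#' Per volume, SNR is the mean gray-matter signal over the sample standard
#' deviation of the air (background) signal:
#' \deqn{SNR_v = \mathrm{Mean}_{GM,v} / \mathrm{SD}_{AIR,v}}
#' The session value averages across volumes (b0 included by default, as the
#' measurement is taken over all volumes of the corrected series).
#'
#' @param dwi a [dwi_volume()] with `gm` and `air` masks of at least 30
#'   voxels each.
#' @param exclude_b0 drop b0 volumes from the average.
#' @return A `quality_report` with `per_volume`, `mean`, `session` and the
#'   mask voxel counts used.
#' @export
compute_snr <- function(dwi, exclude_b0 = FALSE) {
  qc_masked_ratio(dwi, exclude_b0, metric = "snr")
}

#' Mask-based CNR of a DWI session
#'
#' Per volume, CNR is the gray-white mean difference over the air standard
#' deviation:
#' \deqn{CNR_v = (\mathrm{Mean}_{GM,v} - \mathrm{Mean}_{WM,v}) / \mathrm{SD}_{AIR,v}}
#' averaged across volumes. CNR may be negative when white matter is
#' brighter than gray matter on average.
#'
#' @inheritParams compute_snr
#' @return A `quality_report`.
#' @export
compute_cnr <- function(dwi, exclude_b0 = FALSE) {
  qc_masked_ratio(dwi, exclude_b0, metric = "cnr")
}

qc_masked_ratio <- function(dwi, exclude_b0, metric) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gm <- which(as.vector(dwi$masks$gm) > 0)
  wm <- which(as.vector(dwi$masks$wm) > 0)
  air <- which(as.vector(dwi$masks$air) > 0)
  if (length(gm) < 30 || length(air) < 30)
    stop("GM and air masks must each contain at least 30 voxels")
  if (metric == "cnr" && length(wm) == 0) stop("WM mask is empty")
  d <- dim(dwi$signal)
  nvox <- prod(d[1:3])
  S <- matrix(dwi$signal, nvox, d[4])
  keep <- if (exclude_b0) which(dwi$gtab$bvals > 0) else seq_len(d[4])
  vals <- vapply(keep, function(v) {
    sd_air <- sd(S[air, v])
    if (sd_air == 0)
      stop("air standard deviation is zero (noiseless input); simulate ",
           "with sigma > 0 to obtain a finite ", toupper(metric))
    if (metric == "snr") mean(S[gm, v]) / sd_air
    else (mean(S[gm, v]) - mean(S[wm, v])) / sd_air
  }, numeric(1))
  structure(list(metric = toupper(metric),
                 per_volume = data.frame(volume = keep, value = vals),
                 mean = mean(vals), session = dwi$session,
                 n_gm = length(gm), n_wm = length(wm), n_air = length(air)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("%s (%s): %.3f (mean over %d volumes; sd %.3f)\n", x$metric,
              x$session %||% "?", x$mean, nrow(x$per_volume),
              sd(x$per_volume$value)))
  invisible(x)
}

#' Write a quality report as CSV + JSON
#'
#' @param report a `quality_report`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_quality_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(report$per_volume, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(metric = report$metric, session = report$session,
                              mean = report$mean,
                              sd = sd(report$per_volume$value),
                              n_volumes = nrow(report$per_volume)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
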