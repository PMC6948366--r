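#' Index of connection probability
#'
#' The mean number of successful samples per seed voxel: the sum over seed
#' voxels of per-voxel success counts, divided by the number of seed voxels.
#' Ranges from 0 to the samples-per-voxel setting.
#'
#' @param result a `tractography_result` from [track()].
#' @return A single number.
#' @export
connection_probability_index <- function(result) {
  stopifnot(inherits(result, "tractography_result"))
  ns <- sum(result$seed_mask)
  if (ns == 0) stop("seed mask is empty")
  sum(result$success[result$seed_mask]) / ns
}

#' Streamline density
#'
#' The percentage of seed voxels generating at least one streamline that
#' reaches the classification target.
#'
#' @inheritParams connection_probability_index
#' @return A percentage in `[0, 100]`.
#' @export
streamline_density <- function(result) {
  stopifnot(inherits(result, "tractography_result"))
  ns <- sum(result$seed_mask)
  if (ns == 0) stop("seed mask is empty")
  100 * sum(result$success[result$seed_mask] >= 1) / ns
}

#' Percent change between a pre and a post metric
#'
#' `100 * (pre - post) / pre`. Reports round this to one decimal, half away
#' from zero. A zero pre value is undefined and returns NaN with a warning.
#'
#' @param pre,post metric values.
#' @return Percent change (unrounded; see [round_half_away] semantics used
#'   in report tables).
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) {
    warning("percent change undefined for pre = 0; returning NaN")
    return(ifelse(pre == 0, NaN, 100 * (pre - post) / pre))
  }
  100 * (pre - post) / pre
}

#' Voxel-wise pre/post comparison of connection probability
#'
#' Welch's two-sample two-tailed t-test (heteroscedastic) on the two
#' sessions' connection-probability values (the visitation-map counts)
#' within the target ROI, treating voxels as independent observations.
#' p > 0.05 is reported as "similar" (similarity-by-nonrejection).
#'
#' @param pre,post `tractography_result`s (or 3D numeric maps) on the same
#'   grid.
#' @param target_mask binary mask with at least 2 voxels.
#' @param alpha similarity level.
#' @return List with `p_value`, `similar`, `t`, and the two voxel-value
#'   vectors' means.
#' @export
compare_connection_maps <- function(pre, post, target_mask, alpha = 0.05) {
  getmap <- function(x) if (inherits(x, "tractography_result")) x$visitation
                        else x
  a <- getmap(pre); b <- getmap(post)
  if (!identical(dim(a), dim(b))) stop("maps must share a grid")
  sel <- as.vector(target_mask) > 0
  if (sum(sel) < 2) stop("target mask must contain at least 2 voxels")
  x <- as.vector(a)[sel]; y <- as.vector(b)[sel]
  if (sd(x) == 0 && sd(y) == 0) {
    # identical-constant maps: no evidence of difference
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
  }
  list(p_value = tt$p.value, similar = tt$p.value > alpha,
       t = unname(tt$statistic), mean_pre = mean(x), mean_post = mean(y),
       n_voxels = sum(sel))
}

#' Tract-retention summary table
#'
#' One row per tract: pre/post index of connection probability and
#' streamline density, their percent changes (rounded to one decimal, half
#' away from zero) and the voxel-wise Welch similarity verdict, shaped like
#' a per-tract connectivity report.
#'
#' @param tracts named list; each element a list with `pre` and `post`
#'   `tractography_result`s and the tract's `target_mask`.
#' @param alpha similarity level for the Welch test.
#' @return Data frame.
#' @export
connectivity_table <- function(tracts, alpha = 0.05) {
  do.call(rbind, lapply(names(tracts), function(nm) {
    tr <- tracts[[nm]]
    ipre <- connection_probability_index(tr$pre)
    ipost <- connection_probability_index(tr$post)
    dpre <- streamline_density(tr$pre)
    dpost <- streamline_density(tr$post)
    welch <- compare_connection_maps(tr$pre, tr$post, tr$target_mask, alpha)
    data.frame(tract = nm, index_pre = ipre, index_post = ipost,
               index_pct_change = if (ipre > 0)
                 round_half_away(percent_change(ipre, ipost), 1) else NaN,
               density_pre = dpre, density_post = dpost,
               density_pct_change = if (dpre > 0)
                 round_half_away(percent_change(dpre, dpost), 1) else NaN,
               welch_p = welch$p_value, similar = welch$similar)
  }))
}
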