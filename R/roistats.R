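#' Classify ROIs as artifact-affected
#'
#' An ROI counts as affected when it shares at least one voxel with the
#' artifact (signal-dropout) mask; all remaining ROIs are unaffected.
#'
#' @param labels integer 3D label volume.
#' @param artifact binary 3D artifact mask on the same grid.
#' @param roi_table optional data frame with `label` (and `name`) columns;
#'   defaults to every nonzero label present. An explicitly requested label
#'   absent from the volume is an error.
#' @return Data frame `label`, `name`, `affected`, `overlap_voxels`, with
#'   attribute `fraction_affected`.
#' @export
classify_affected <- function(labels, artifact, roi_table = NULL) {
  if (!identical(dim(labels), dim(artifact)))
    stop("labels and artifact mask must share a grid")
  lab_vec <- as.vector(labels)
  art <- as.vector(artifact) > 0
  if (is.null(roi_table)) {
    labs <- sort(setdiff(unique(lab_vec), 0L))
    roi_table <- data.frame(label = labs, name = as.character(labs))
  }
  missing <- setdiff(roi_table$label, unique(lab_vec))
  if (length(missing))
    stop("label(s) absent from the volume: ", paste(missing, collapse = ", "))
  overlap <- vapply(roi_table$label, function(l) sum(lab_vec == l & art),
                    numeric(1))
  out <- data.frame(label = roi_table$label,
                    name = roi_table$name %||% as.character(roi_table$label),
                    affected = overlap >= 1, overlap_voxels = overlap)
  attr(out, "fraction_affected") <- mean(out$affected)
  out
}

#' Extract paired pre/post scalar values for one ROI
#'
#' Values come from voxels inside the ROI that are valid in both sessions'
#' maps; pre and post pair by voxel index (both maps live on the same
#' phantom grid).
#'
#' @param pre_map,post_map `scalar_map`s on the same grid.
#' @param labels integer label volume.
#' @param label ROI label to extract.
#' @return List with `pre`, `post` value vectors and their means.
#' @export
roi_values <- function(pre_map, post_map, labels, label) {
  stopifnot(inherits(pre_map, "scalar_map"), inherits(post_map, "scalar_map"))
  sel <- as.vector(labels) == label & as.vector(pre_map$valid) &
    as.vector(post_map$valid)
  list(pre = as.vector(pre_map$values)[sel],
       post = as.vector(post_map$values)[sel],
       mean_pre = mean(as.vector(pre_map$values)[sel]),
       mean_post = mean(as.vector(post_map$values)[sel]))
}

#' Pre vs post comparison of one ROI's scalar values
#'
#' The decision tree used per region: a two-sample Kolmogorov-Smirnov test
#' gates the branch choice. If KS rejects at `alpha` the samples are treated
#' as differently distributed and a paired Wilcoxon signed-rank test is run
#' on the voxelwise differences (zero differences dropped, per the
#' signed-rank convention); otherwise a paired t-test is run and a 95%
#' confidence interval for the mean difference is reported. Exactly one of
#' the two branch p-values is populated. A degenerate branch (all paired
#' differences zero) reports p = 1 and is flagged.
#'
#' Note the similarity convention inherited from the study design:
#' p > alpha on the chosen branch is reported as "similar"
#' (similarity-by-nonrejection; this is not an equivalence test).
#'
#' @param pre,post paired numeric vectors of equal length `>= 10`.
#' @param alpha significance level for both the KS gate and the branch test.
#' @return A `roi_comparison` list: `ks_p`, `branch`
#'   (`"signed-rank"`/`"paired-t"`), `branch_p`, `conf_int` (paired-t branch
#'   only), `mean_pre`, `mean_post`, `percent_change`, `degenerate`,
#'   `alpha`.
#' @export
compare_roi <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post))
    stop("pre and post vectors must pair voxelwise (equal length)")
  if (length(pre) < 10) stop("need at least 10 paired voxels")
  ks_p <- suppressWarnings(ks.test(pre, post, exact = FALSE)$p.value)
  diffs <- post - pre
  degenerate <- FALSE
  if (ks_p < alpha) {
    branch <- "signed-rank"
    nz <- diffs[diffs != 0]
    if (length(nz) == 0) {
      branch_p <- 1; degenerate <- TRUE
    } else {
      branch_p <- suppressWarnings(
        wilcox.test(nz, exact = FALSE)$p.value)
    }
    ci <- NULL
  } else {
    branch <- "paired-t"
    if (sd(diffs) == 0) {
      branch_p <- 1; degenerate <- TRUE
      ci <- c(0, 0) + mean(diffs)
    } else {
      tt <- t.test(post, pre, paired = TRUE, conf.level = 0.95)
      branch_p <- tt$p.value
      ci <- as.numeric(tt$conf.int)
    }
  }
  structure(list(ks_p = ks_p, branch = branch, branch_p = branch_p,
                 conf_int = ci, mean_pre = mean(pre), mean_post = mean(post),
                 percent_change = if (mean(pre) != 0)
                   100 * (mean(pre) - mean(post)) / mean(pre) else NaN,
                 degenerate = degenerate, alpha = alpha),
            class = "roi_comparison")
}

#' @export
print.roi_comparison <- function(x, ...) {
  cat(sprintf("ROI comparison: KS p = %.3g -> %s branch, p = %.3g%s\n",
              x$ks_p, x$branch, x$branch_p,
              if (!is.null(x$conf_int))
                sprintf(" [%.3g, %.3g]", x$conf_int[1], x$conf_int[2]) else ""))
  invisible(x)
}

#' Compare every ROI of a scalar map pair
#'
#' Runs [compare_roi()] for each label and attaches the artifact-affected
#' flag. ROIs with fewer than 10 valid paired voxels are skipped with a
#' warning.
#'
#' @param pre_map,post_map `scalar_map`s on the same grid.
#' @param labels integer label volume.
#' @param artifact binary artifact mask (used for the affected flag).
#' @param roi_table optional data frame with `label`/`name`.
#' @param alpha significance level.
#' @return Data frame, one row per ROI: label, name, scalar kind, KS p,
#'   branch, branch p, CI bounds, means, percent change, affected flag.
#' @export
compare_rois <- function(pre_map, post_map, labels, artifact,
                         roi_table = NULL, alpha = 0.05) {
  aff <- classify_affected(labels, artifact, roi_table)
  rows <- lapply(seq_len(nrow(aff)), function(i) {
    rv <- roi_values(pre_map, post_map, labels, aff$label[i])
    if (length(rv$pre) < 10) {
      warning("ROI ", aff$name[i], " has fewer than 10 valid paired voxels; skipped")
      return(NULL)
    }
    cmp <- compare_roi(rv$pre, rv$post, alpha)
    data.frame(label = aff$label[i], name = aff$name[i],
               kind = pre_map$kind, n_voxels = length(rv$pre),
               ks_p = cmp$ks_p, branch = cmp$branch, branch_p = cmp$branch_p,
               ci_lower = if (is.null(cmp$conf_int)) NA_real_ else cmp$conf_int[1],
               ci_upper = if (is.null(cmp$conf_int)) NA_real_ else cmp$conf_int[2],
               mean_pre = cmp$mean_pre, mean_post = cmp$mean_post,
               percent_change = cmp$percent_change,
               degenerate = cmp$degenerate, affected = aff$affected[i])
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "fraction_affected") <- attr(aff, "fraction_affected")
  out
}

#' Cohort summary of ROI comparisons
#'
#' Per scalar kind and per affected/unaffected stratum (plus the pooled
#' cohort), summarises: the percent of ROIs whose KS test found different
#' distributions; of those, the percent whose signed-rank p exceeds alpha
#' ("equal medians"); of the KS-similar ROIs, the percent whose paired-t p
#' exceeds alpha ("equal means"); and the percent of ROIs with lower post
#' than pre means. Empty strata report NA (not 0).
#'
#' @param results data frame from [compare_rois()] (rows of several scalar
#'   kinds may be concatenated).
#' @param alpha significance level used in the comparisons.
#' @return Data frame, one row per (kind, stratum).
#' @export
cohort_summary <- function(results, alpha = attr(results, "alpha") %||% 0.05) {
  if (is.null(results) || nrow(results) == 0) stop("no comparison results")
  strata <- list(all = rep(TRUE, nrow(results)),
                 affected = results$affected,
                 unaffected = !results$affected)
  out <- do.call(rbind, lapply(unique(results$kind), function(k) {
    do.call(rbind, lapply(names(strata), function(sname) {
      r <- results[results$kind == k & strata[[sname]], , drop = FALSE]
      if (nrow(r) == 0)
        return(data.frame(kind = k, stratum = sname, n = 0,
                          pct_different = NA_real_, pct_equal_medians = NA_real_,
                          pct_equal_means = NA_real_, pct_lower_post = NA_real_))
      diff <- r$ks_p < alpha
      eq_med <- if (any(diff))
        100 * mean(r$branch_p[diff] > alpha) else NA_real_
      eq_mean <- if (any(!diff))
        100 * mean(r$branch_p[!diff] > alpha) else NA_real_
      data.frame(kind = k, stratum = sname, n = nrow(r),
                 pct_different = 100 * mean(diff),
                 pct_equal_medians = eq_med, pct_equal_means = eq_mean,
                 pct_lower_post = 100 * mean(r$mean_post < r$mean_pre))
    }))
  }))
  rownames(out) <- NULL
  out
}
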