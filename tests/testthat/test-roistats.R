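mk_map <- function(values, valid = NULL, kind = "FA", dims = dim(values)) {
  structure(list(values = values, kind = kind, units = "dimensionless",
                 valid = valid %||% array(TRUE, dims), voxsize = c(2, 2, 2),
                 session = "pre"), class = "scalar_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("artifact-affected classification uses the >= 1 voxel rule", {
  dims <- c(10, 10, 10)
  labels <- array(0L, dims)
  labels[1:3, 1:3, 1] <- 1L      # fully inside artifact
  labels[5:6, 5, 1] <- 2L        # one overlapping voxel
  labels[8:9, 8:9, 8] <- 3L      # disjoint
  artifact <- array(FALSE, dims)
  artifact[1:5, 1:5, 1] <- TRUE
  aff <- classify_affected(labels, artifact)
  expect_equal(aff$affected, c(TRUE, TRUE, FALSE))
  expect_equal(aff$overlap_voxels, c(9, 1, 0))
  expect_equal(attr(aff, "fraction_affected"), 2 / 3)

  # idempotent and order independent
  tab <- data.frame(label = c(3L, 1L, 2L), name = c("c", "a", "b"))
  aff2 <- classify_affected(labels, artifact, tab)
  expect_equal(aff2$affected[aff2$label == 1], TRUE)
  expect_equal(aff2$affected[aff2$label == 3], FALSE)
  expect_identical(classify_affected(labels, artifact), aff)

  expect_error(classify_affected(labels, artifact,
                                 data.frame(label = 9L, name = "x")), "9")
})

test_that("identical paired samples take the paired-t branch with p = 1", {
  x <- rnorm(50, 0.5, 0.1)
  cmp <- compare_roi(x, x)
  expect_equal(cmp$ks_p, 1)
  expect_equal(cmp$branch, "paired-t")
  expect_equal(cmp$branch_p, 1)
  expect_true(cmp$degenerate)
  expect_equal(cmp$mean_post - cmp$mean_pre, 0)
  expect_true(cmp$conf_int[1] <= 0 && cmp$conf_int[2] >= 0)
})

test_that("a constant shift routes to the signed-rank branch and matches the direct tests", {
  set.seed(42)
  pre <- rnorm(200)
  post <- pre + 10
  cmp <- compare_roi(pre, post)
  expect_equal(cmp$branch, "signed-rank")
  expect_lt(cmp$branch_p, 1e-6)
  expect_null(cmp$conf_int)
  # oracle: the branch p-values equal direct calls to the reference tests
  expect_equal(cmp$ks_p,
               suppressWarnings(ks.test(pre, post, exact = FALSE)$p.value))
  expect_equal(cmp$branch_p,
               suppressWarnings(wilcox.test(post, pre, paired = TRUE,
                                            exact = FALSE)$p.value))

  # mild mean shift that KS cannot see routes to paired-t with a CI
  set.seed(43)
  pre2 <- rnorm(200)
  post2 <- pre2 + rnorm(200, 0.01, 0.05)
  cmp2 <- compare_roi(pre2, post2)
  if (cmp2$branch == "paired-t") {
    tt <- t.test(post2, pre2, paired = TRUE)
    expect_equal(cmp2$branch_p, tt$p.value)
    expect_equal(cmp2$conf_int, as.numeric(tt$conf.int))
  }
  expect_error(compare_roi(1:20, 1:10), "equal length")
  expect_error(compare_roi(1:5, 1:5), "at least 10")
})

test_that("exactly one branch p-value is populated per comparison", {
  set.seed(7)
  for (r in 1:20) {
    pre <- rnorm(60)
    post <- pre + sample(c(0, 5), 1) + rnorm(60, 0, 0.2)
    cmp <- compare_roi(pre, post)
    expect_true(cmp$branch %in% c("signed-rank", "paired-t"))
    expect_identical(is.null(cmp$conf_int), cmp$branch == "signed-rank")
  }
})

test_that("KS gate type-I error sits near alpha under the null", {
  set.seed(11)
  n_rep <- 500
  taken_t <- 0
  for (r in seq_len(n_rep)) {
    pre <- rnorm(200); post <- rnorm(200)
    if (compare_roi(pre, post)$branch == "paired-t") taken_t <- taken_t + 1
  }
  # asymptotic two-sample KS is slightly conservative: accept 91-99%
  expect_gt(taken_t / n_rep, 0.91)
  expect_lt(taken_t / n_rep, 0.995)
})

test_that("cohort summaries stratify by artifact overlap and handle empty strata", {
  mkrow <- function(kind, ks_p, branch_p, affected, pre = 1, post = 0.9)
    data.frame(label = 1, name = "r", kind = kind, n_voxels = 50, ks_p = ks_p,
               branch = ifelse(ks_p < 0.05, "signed-rank", "paired-t"),
               branch_p = branch_p, ci_lower = NA, ci_upper = NA,
               mean_pre = pre, mean_post = post, percent_change = 10,
               degenerate = FALSE, affected = affected)
  # all 10 ROIs KS-rejecting: percent different = 100
  res <- do.call(rbind, lapply(1:10, function(i)
    mkrow("FA", 0.001, 0.5, i <= 3)))
  cs <- cohort_summary(res, alpha = 0.05)
  all_row <- cs[cs$kind == "FA" & cs$stratum == "all", ]
  expect_equal(all_row$pct_different, 100)
  expect_equal(all_row$pct_equal_medians, 100)  # branch p 0.5 > alpha
  expect_true(is.na(all_row$pct_equal_means))   # no KS-similar ROIs
  expect_equal(all_row$pct_lower_post, 100)

  # empty affected stratum reports NA, not zero
  res2 <- do.call(rbind, lapply(1:5, function(i) mkrow("MD", 0.5, 0.01, FALSE)))
  cs2 <- cohort_summary(res2, alpha = 0.05)
  aff_row <- cs2[cs2$kind == "MD" & cs2$stratum == "affected", ]
  expect_equal(aff_row$n, 0)
  expect_true(is.na(aff_row$pct_different))
  expect_error(cohort_summary(res2[0, ]), "no comparison")
})

test_that("artifact dropout separates affected from unaffected ROI statistics", {
  # end-to-end: post session gets severe dropout in the artifact region;
  # affected ROIs must show a higher rate of FA distribution differences
  ph <- make_phantom(default_phantom_spec())
  gt <- default_gradient_table()
  sigma <- 30
  pre <- simulate_dwi(ph, gt, sigma = sigma, seed = 51, session = "pre")
  post <- simulate_dwi(ph, gt, sigma = 0, session = "post")
  post <- apply_artifact(post, ph$artifact, 0.1)
  post <- add_rician_noise(post, sigma, seed = 52)
  fa_pre <- scalar_map(fit_tensor(pre), "fa")
  fa_post <- scalar_map(fit_tensor(post), "fa")
  res <- suppressWarnings(
    compare_rois(fa_pre, fa_post, ph$labels, ph$artifact, ph$roi_table))
  cs <- cohort_summary(res, 0.05)
  aff <- cs[cs$stratum == "affected", ]
  una <- cs[cs$stratum == "unaffected", ]
  expect_gt(aff$pct_different, una$pct_different)
  expect_gte(aff$pct_different, 50)
})
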