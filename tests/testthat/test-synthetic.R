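test_that("generation is seed-deterministic and respects feasibility", {
  s1 <- generate_microarray(n_per_group = 4L, d = 80L, n_up = 3L,
                            n_down = 3L, n_exclusive_each = 1L, seed = 5L)
  s2 <- generate_microarray(n_per_group = 4L, d = 80L, n_up = 3L,
                            n_down = 3L, n_exclusive_each = 1L, seed = 5L)
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$truth$up, s2$truth$up)
  s3 <- generate_microarray(n_per_group = 4L, d = 80L, n_up = 3L,
                            n_down = 3L, n_exclusive_each = 1L, seed = 6L)
  expect_false(identical(unclass(s1$matrix), unclass(s3$matrix)))
  expect_error(generate_microarray(d = 10L, n_up = 6L, n_down = 6L),
               "exceed")
  # shape and annotations of the default design
  sim <- generate_microarray(seed = 1L)
  expect_equal(dim(sim$matrix), c(2000L, 20L))
  expect_identical(expr_scale(sim$matrix), "linear")
  expect_equal(sort(table(sim$metadata$group), decreasing = TRUE),
               sort(table(c(rep("bright", 10), rep("dim", 10))),
                    decreasing = TRUE))
  # paired donors: each donor appears once per group
  tab <- table(sim$metadata$donor_id, sim$metadata$group)
  expect_true(all(tab == 1))
  # both groups present in both batches (unconfounded two-batch design)
  bt <- table(sim$metadata$batch_id, sim$metadata$group)
  expect_true(all(bt > 0))
})

test_that("planted truth is disjoint and detectable in the right group", {
  sim <- generate_microarray(seed = 3L)
  t <- sim$truth
  groups <- list(t$up, t$down, t$exclusive_bright, t$exclusive_dim)
  expect_equal(length(unique(unlist(groups))), sum(lengths(groups)))
  norm <- preprocess_chain(sim$matrix, sim$metadata)
  md <- sim$metadata
  bright <- unclass(norm)[, md$group == "bright"]
  dimm <- unclass(norm)[, md$group == "dim"]
  # exclusive-bright features sit below 1 LU in dim and above in bright
  expect_true(all(apply(bright[t$exclusive_bright, , drop = FALSE], 1,
                        median) > 1))
  expect_true(all(apply(dimm[t$exclusive_bright, , drop = FALSE], 1,
                        median) < 1))
  # planted medians differ by about the effect size
  deltas <- apply(dimm[t$up, ], 1, median) - apply(bright[t$up, ], 1,
                                                   median)
  # quantile normalization compresses the planted 1.5 log2 shift a little
  expect_gt(min(deltas), 0.75)
  expect_equal(mean(deltas), 1.5, tolerance = 0.15)
})

test_that("null generation produces no signature calls", {
  sim <- generate_microarray(n_up = 0L, n_down = 0L,
                             n_exclusive_each = 0L, seed = 12L)
  norm <- preprocess_chain(sim$matrix, sim$metadata)
  de <- differential_expression(norm, sim$metadata)
  expect_true(all(de$status == "unchanged"))
  frac <- mean(de$p <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(de)))
})

test_that("batch aligned with group trips the confounding canary", {
  sim <- generate_microarray(n_per_group = 4L, d = 50L, n_up = 2L,
                             n_down = 2L, n_exclusive_each = 0L, seed = 2L)
  md <- sim$metadata
  md$batch_id <- ifelse(md$group == "bright", "batch1", "batch2")
  lg <- log2_transform(floor_threshold(sim$matrix))
  expect_error(batch_adjust(quantile_normalize(lg), md), "confounded")
})

test_that("intermediate group lands halfway between the parents", {
  sim <- generate_microarray(n_per_group = 6L, d = 100L, n_up = 4L,
                             n_down = 4L, n_exclusive_each = 1L,
                             sigma = 0.05, batch_offset = 0, seed = 4L)
  aug0 <- generate_intermediate_group(sim, n_samples = 6L, mixing = 0,
                                      seed = 9L)
  aug5 <- generate_intermediate_group(sim, n_samples = 6L, mixing = 0.5,
                                      seed = 9L)
  expect_error(generate_intermediate_group(sim, mixing = 1.5), "mixing")
  md <- aug5$metadata
  expect_equal(sum(md$group == "bright_cd16dim"), 6L)
  lg <- function(aug) unclass(log2_transform(floor_threshold(aug$matrix)))
  t <- sim$truth
  up <- t$up[1]
  bright_m <- mean(lg(aug5)[up, aug5$metadata$group == "bright"])
  dim_m <- mean(lg(aug5)[up, aug5$metadata$group == "dim"])
  mid_m <- mean(lg(aug5)[up, aug5$metadata$group == "bright_cd16dim"])
  expect_lt(abs(mid_m - (bright_m + dim_m) / 2), 0.15)
  # mixing = 0 reproduces the bright mean
  mid0 <- mean(lg(aug0)[up, aug0$metadata$group == "bright_cd16dim"])
  expect_lt(abs(mid0 - bright_m), 0.15)
  # the three-group ANOVA trend is detectable per planted feature
  vals <- lg(aug5)[t$up[2], ]
  g <- aug5$metadata$group[match(names(vals), aug5$metadata$sample_id)]
  trend <- group_compare(vals, g, design = "anova_bonferroni")
  expect_lt(trend$p, 0.01)
})

test_that("synthetic qPCR reproduces planted fold changes via ddCt", {
  sim <- generate_microarray(n_per_group = 4L, d = 60L, n_up = 2L,
                             n_down = 2L, n_exclusive_each = 0L,
                             effect_log2 = 1, sigma = 0.3, seed = 6L)
  t <- sim$truth
  q <- generate_qpcr(t, targets = c(t$up[1], t$down[1]), n_per_group = 4L,
                     sigma_ct = 0.02, seed = 3L)
  # triplicates for every (sample, target) incl. the reference gene
  expect_true(all(table(q$sample_id, q$target) == 3))
  rq <- delta_delta_ct(q, calibrator = "bright")
  dim_rq <- rq[rq$group == "dim", ]
  # planted 2-fold up: RQ about 2; planted down: RQ about 1/2
  expect_equal(mean(dim_rq$rq[dim_rq$target == t$up[1]]), 2,
               tolerance = 0.1)
  expect_equal(mean(dim_rq$rq[dim_rq$target == t$down[1]]), 0.5,
               tolerance = 0.05)
  # a null target stays near RQ 1
  null_feat <- setdiff(rownames(sim$matrix), planted_features(t))[1]
  qn <- generate_qpcr(t, targets = null_feat, n_per_group = 4L,
                      sigma_ct = 0.02, seed = 4L)
  rqn <- delta_delta_ct(qn, calibrator = "bright")
  expect_equal(mean(rqn$rq[rqn$group == "dim"]), 1, tolerance = 0.05)
  expect_error(generate_qpcr(t, targets = "not-a-mir"), "unknown")
  expect_identical(generate_qpcr(t, targets = t$up[1], seed = 8L),
                   generate_qpcr(t, targets = t$up[1], seed = 8L))
})
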