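make_de_fixture <- function(n_per = 10, d = 60, n_up = 5, shift = 1.5,
                            sd = 0.3, seed = 21) {
  set.seed(seed)
  vals <- matrix(rnorm(d * 2 * n_per, mean = 5, sd = sd), d, 2 * n_per)
  groups <- rep(c("bright", "dim"), each = n_per)
  vals[seq_len(n_up), groups == "dim"] <-
    vals[seq_len(n_up), groups == "dim", drop = FALSE] + shift
  dimnames(vals) <- list(sprintf("mir%02d", seq_len(d)),
                         sprintf("s%02d", seq_len(2 * n_per)))
  list(mat = expr_matrix(vals, scale = "log2"),
       md = two_group_meta(colnames(vals), groups),
       planted = sprintf("mir%02d", seq_len(n_up)))
}

test_that("identical groups give zero deltas and no calls", {
  set.seed(1)
  half <- matrix(rnorm(50, 5), 10, 5)
  vals <- cbind(half, half)
  dimnames(vals) <- list(paste0("m", 1:10), paste0("s", 1:10))
  m <- expr_matrix(vals, scale = "log2")
  md <- two_group_meta(colnames(m), rep(c("bright", "dim"), each = 5))
  de <- differential_expression(m, md)
  expect_true(all(de$delta_log2 == 0))
  expect_true(all(de$status == "unchanged"))
})

test_that("planted shifts are recovered as induced with correct sign", {
  fx <- make_de_fixture()
  de <- differential_expression(fx$mat, fx$md)
  got <- de$status[match(fx$planted, de$feature)]
  expect_true(all(got == "induced"))  # shifted up in dim
  expect_true(all(de$status[!de$feature %in% fx$planted] == "unchanged"))
  # fold change is the signed linear fold of the median difference
  i <- match(fx$planted[1], de$feature)
  expect_equal(de$fold_change[i],
               sign(de$delta_log2[i]) * 2^abs(de$delta_log2[i]))
})

test_that("status needs both significance and the two-fold margin", {
  # construct exact medians: delta +1.2 (passes), delta +0.8 (fails fold)
  n <- 6
  mk_row <- function(delta) c(rep(5, n), rep(5 + delta, n)) +
    rep(c(-0.01, 0, 0.01), 4)
  vals <- rbind(big = mk_row(1.2), small = mk_row(0.8))
  colnames(vals) <- paste0("s", 1:12)
  m <- expr_matrix(vals, scale = "log2")
  md <- two_group_meta(colnames(m), rep(c("bright", "dim"), each = n))
  de <- differential_expression(m, md, detect_theta = NULL)
  expect_lt(max(de$p_adj), 0.05)
  expect_equal(de$status[de$feature == "big"], "induced")
  expect_equal(de$status[de$feature == "small"], "unchanged")
})

test_that("swapping group labels negates deltas and swaps calls", {
  fx <- make_de_fixture(seed = 33)
  de1 <- differential_expression(fx$mat, fx$md)
  md2 <- fx$md
  md2$group <- ifelse(md2$group == "bright", "dim", "bright")
  de2 <- differential_expression(fx$mat, md2)
  de2 <- de2[match(de1$feature, de2$feature), ]
  expect_equal(de2$delta_log2, -de1$delta_log2)
  swap <- c(induced = "repressed", repressed = "induced",
            unchanged = "unchanged")
  expect_equal(unname(swap[de1$status]), de2$status)
})

test_that("undetected features are excluded before testing", {
  fx <- make_de_fixture(d = 20)
  vals <- unclass(fx$mat)
  vals["mir20", ] <- 0.1            # below theta = 1 everywhere
  m <- expr_matrix(vals, scale = "log2")
  de <- differential_expression(m, fx$md, detect_theta = 1)
  expect_false("mir20" %in% de$feature)
  de_all <- differential_expression(m, fx$md, detect_theta = NULL)
  expect_true("mir20" %in% de_all$feature)
})

test_that("input contracts: group sizes, alpha range, scale tag", {
  fx <- make_de_fixture(n_per = 2, d = 10)
  md_bad <- fx$md
  md_bad$group <- c("bright", "bright", "bright", "dim")
  expect_error(differential_expression(fx$mat, md_bad), "2 samples")
  expect_error(differential_expression(fx$mat, fx$md, alpha = 1.2),
               "alpha")
  lin <- expr_matrix(unclass(fx$mat), scale = "linear")
  expect_error(differential_expression(lin, fx$md), "log2")
})

test_that("p-value adjustment matches hand-computed BH and Bonferroni", {
  expect_equal(adjust_pvalues(0.02), 0.02)
  # BH step-up by hand: all four tie at 0.04
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(rep(0.01, 4), "bonferroni"), rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # BH never decreases, Bonferroni dominates BH
  set.seed(4)
  p <- runif(50)
  expect_true(all(adjust_pvalues(p) >= p))
  expect_true(all(adjust_pvalues(p, "bonferroni") >= adjust_pvalues(p)))
})

test_that("type-I error is calibrated under the global null", {
  set.seed(99)
  d <- 2000; n <- 10
  vals <- matrix(rnorm(d * 2 * n, 5, 0.3), d, 2 * n,
                 dimnames = list(sprintf("m%04d", 1:d),
                                 sprintf("s%02d", 1:(2 * n))))
  m <- expr_matrix(vals, scale = "log2")
  md <- two_group_meta(colnames(m), rep(c("bright", "dim"), each = n))
  de <- differential_expression(m, md, detect_theta = NULL)
  frac <- mean(de$p <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / d))
})

test_that("bi-clustering recovers planted sample partition", {
  set.seed(12)
  # 4 samples in two well-separated groups, 6 features
  vals <- cbind(a1 = rnorm(6, 0, 0.1), a2 = rnorm(6, 0, 0.1),
                b1 = rnorm(6, 5, 0.1), b2 = rnorm(6, 5, 0.1))
  vals[1:3, c("b1", "b2")] <- -vals[1:3, c("b1", "b2")]  # shape contrast
  rownames(vals) <- paste0("m", 1:6)
  m <- expr_matrix(vals, scale = "log2")
  bc <- hierarchical_bicluster(m, distance = "euclidean")
  top <- cutree(bc$samples, k = 2)
  expect_equal(length(unique(top[c("a1", "a2")])), 1L)
  expect_equal(length(unique(top[c("b1", "b2")])), 1L)
  expect_false(top[["a1"]] == top[["b1"]])
  # leaves preserved on both axes
  expect_setequal(bc$samples$labels, colnames(m))
  expect_setequal(bc$features$labels, rownames(m))
  # identical samples merge at height zero
  vals2 <- cbind(vals, a1bis = vals[, "a1"])
  colnames(vals2)[5] <- "a3"
  bc2 <- hierarchical_bicluster(expr_matrix(vals2, scale = "log2"),
                                distance = "euclidean")
  expect_equal(min(bc2$samples$height), 0)
  # constant rows break correlation distance with advice
  cm <- expr_matrix(matrix(1, 3, 4, dimnames = list(paste0("m", 1:3),
                                                    paste0("s", 1:4))),
                    scale = "log2")
  expect_error(hierarchical_bicluster(cm, distance = "correlation"),
               "[Ee]uclidean")
})

test_that("group tests: identical samples, shifted samples, anova contract", {
  x <- c(1, 2, 3, 4)
  gm <- group_mean_test(c(x, x), rep(c("a", "b"), each = 4),
                        kind = "mann_whitney")
  expect_equal(gm$p, 1)
  # exhaustive permutation oracle for a tie-free tiny case
  a <- c(1.1, 2.3, 3.7); b <- c(5.2, 6.4, 7.9)
  gm2 <- group_mean_test(c(a, b), rep(c("a", "b"), each = 3),
                         kind = "mann_whitney")
  pool <- c(a, b)
  combs <- combn(6, 3)
  stat_u <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - 3 * 4 / 2
  }
  obs <- stat_u(1:3)
  null_u <- apply(combs, 2, stat_u)
  p_exact <- mean(abs(null_u - 4.5) >= abs(obs - 4.5))
  expect_equal(gm2$p, p_exact)

  set.seed(6)
  sh <- group_mean_test(c(rnorm(10), rnorm(10, 3)),
                        rep(c("a", "b"), each = 10), kind = "welch_t")
  expect_lt(sh$p, 0.05)

  expect_error(group_mean_test(rnorm(6), rep(c("a", "b"), 3),
                               kind = "anova_bonferroni"), "3 groups")
  set.seed(7)
  tri <- group_mean_test(c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 2)),
                         rep(c("a", "b", "c"), each = 5),
                         kind = "anova_bonferroni")
  expect_lt(tri$p, 0.01)
  expect_length(tri$pairwise, 3L)
  expect_true(all(tri$pairwise <= 1))
})
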