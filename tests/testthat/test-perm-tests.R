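# Exhaustive-enumeration oracle for the two-group permutation ANOVA on a
# tiny instance: every C(n, n1) relabelling, p = #{F* >= F_obs} / #labelings.
enumerate_two_group_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  n <- length(pooled)
  f_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    ssb <- n1 * (mean(a) - mean(pooled))^2 +
      (n - n1) * (mean(b) - mean(pooled))^2
    ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ssw < 1e-12) {
      if (ssb < 1e-12) 0 else Inf
    } else {
      (ssb / 1) / (ssw / (n - 2))
    }
  }
  f_obs <- f_of(seq_len(n1))
  combos <- utils::combn(n, n1)
  f_all <- apply(combos, 2, f_of)
  mean(f_all >= f_obs - 1e-12)
}

test_that("permutation ANOVA decomposition obeys its arithmetic identities", {
  set.seed(4)
  df <- data.frame(g = rep(letters[1:6], each = 8), y = rnorm(48))
  res <- perm_anova(df, y, g, iterations = 99, seed = 1)
  expect_equal(res$df_between, 5)
  expect_equal(res$ms_between, res$ss_between / res$df_between)
  expect_equal(res$df_within, 48 - 6)
  expect_gte(res$p_value, 1 / 100)
  # F is invariant to adding a constant to every value
  res2 <- perm_anova(dplyr::mutate(df, y = y + 100), y, g,
                     iterations = 99, seed = 1)
  expect_equal(res2$f_obs, res$f_obs, tolerance = 1e-8)
  expect_equal(res2$p_value, res$p_value)
})

test_that("degenerate inputs: identical values give F = 0 and p = 1", {
  df <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(3.3, 8))
  res <- perm_anova(df, y, g, iterations = 199, seed = 2)
  expect_equal(res$f_obs, 0)
  expect_equal(res$p_value, 1)
})

test_that("empty groups are rejected by name", {
  df <- data.frame(g = factor(rep("a", 4), levels = c("a", "b")),
                   y = rnorm(4))
  expect_error(perm_anova(df, y, g, iterations = 9, seed = 1), "'b'")
})

test_that("sampled permutation p matches the exhaustive enumeration oracle", {
  # two groups {0,0,0} vs {10,10,10}: the enumeration over C(6,3) = 20
  # relabelings puts F_obs at the maximum, attained by 2 of them
  p_exact <- enumerate_two_group_p(c(0, 0, 0), c(10, 10, 10))
  expect_equal(p_exact, 0.1)
  df <- data.frame(g = rep(c("a", "b"), each = 3), y = c(0, 0, 0, 10, 10, 10))
  res <- perm_anova(df, y, g, iterations = 999, seed = 3)
  expect_lt(abs(res$p_value - p_exact), 0.04)

  # a non-degenerate tiny instance converges to its enumeration p too
  x1 <- c(0.3, 1.2, 2.1)
  x2 <- c(1.9, 2.8, 3.5, 4.1)
  p_exact2 <- enumerate_two_group_p(x1, x2)
  df2 <- data.frame(g = rep(c("a", "b"), c(3, 4)), y = c(x1, x2))
  res2 <- perm_anova(df2, y, g, iterations = 4999, seed = 4)
  expect_lt(abs(res2$p_value - p_exact2), 0.03)
})

test_that("pairwise permutation tests separate groups and share letters", {
  df <- data.frame(
    g = rep(c("A", "B", "C"), each = 4),
    y = c(rep(0, 4), rep(0, 4), rep(9, 4))
  )
  # unadjusted letters match the exhaustive two-sample enumeration: only
  # 2 of the C(8,4) = 70 relabelings reproduce the A-C mean gap, so the
  # A-C and B-C contrasts are significant at 0.05 while A-B is not
  res <- pairwise_perm_test(df, y, g, iterations = 999, seed = 5,
                            adjust = "none")
  lt <- res$letters
  expect_equal(lt$letters[lt$group == "A"], lt$letters[lt$group == "B"])
  expect_false(lt$letters[lt$group == "C"] %in%
                 lt$letters[lt$group %in% c("A", "B")])
  ac <- res$pairs[res$pairs$group1 == "A" & res$pairs$group2 == "C", ]
  expect_lt(abs(ac$p.value - 2 / 70), 0.02)
  ab <- res$pairs[res$pairs$group1 == "A" & res$pairs$group2 == "B", ]
  expect_gt(ab$p.adjusted, 0.05)
  # adjustment monotonicity under holm
  res_h <- pairwise_perm_test(df, y, g, iterations = 199, seed = 5,
                              adjust = "holm")
  expect_true(all(res_h$pairs$p.adjusted >= res_h$pairs$p.value))
})

test_that("identical groups share one letter with adjusted p of 1", {
  df <- data.frame(g = rep(c("A", "B", "C"), each = 4), y = rep(2, 12))
  res <- pairwise_perm_test(df, y, g, iterations = 199, seed = 6)
  expect_true(all(res$pairs$p.adjusted == 1))
  expect_equal(length(unique(res$letters$letters)), 1)
})

test_that("letters never join a significantly different pair", {
  set.seed(9)
  df <- data.frame(
    g = rep(letters[1:4], each = 10),
    y = c(rnorm(10, 0), rnorm(10, 0.2), rnorm(10, 3), rnorm(10, 6))
  )
  res <- pairwise_perm_test(df, y, g, iterations = 999, seed = 9)
  lt <- res$letters
  for (i in seq_len(nrow(res$pairs))) {
    pr <- res$pairs[i, ]
    shared <- intersect(
      strsplit(lt$letters[lt$group == pr$group1], "")[[1]],
      strsplit(lt$letters[lt$group == pr$group2], "")[[1]]
    )
    if (pr$p.adjusted <= 0.05) expect_length(shared, 0)
    else expect_gt(length(shared), 0)
  }
})

test_that("permutation p is reproducible given a seed", {
  set.seed(11)
  df <- data.frame(g = rep(c("a", "b", "c"), each = 6), y = rnorm(18))
  r1 <- perm_anova(df, y, g, iterations = 299, seed = 42)
  r2 <- perm_anova(df, y, g, iterations = 299, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
})
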