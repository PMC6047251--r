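long_table <- function(m) {
  # m: subjects x levels response matrix
  data.frame(subject = rep(rownames(m), ncol(m)),
             level = rep(colnames(m), each = nrow(m)),
             value = as.vector(m))
}

rand_table <- function(n, k, effect = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(paste0("s", 1:n), paste0("l", 1:k)))
  m <- m + matrix(stats::rnorm(n), n, k)       # subject effect
  m <- m + rep(effect * (1:k), each = n)
  long_table(m)
}

test_that("a two-level within-subject ANOVA equals the squared paired t", {
  tab <- rand_table(8, 2, effect = 0.5, seed = 3)
  a <- rm_anova(tab)
  m <- tapply(tab$value, list(tab$subject, tab$level), mean)
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
  expect_equal(a$df_num, 1L)
  expect_equal(a$df_den, 7L)
})

test_that("a constant response gives F = 0 and p = 1", {
  m <- matrix(2.5, 5, 3, dimnames = list(paste0("s", 1:5), c("a", "b", "c")))
  a <- rm_anova(long_table(m))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
})

test_that("rm_anova matches hand-computed sums of squares", {
  # small 3-level, 5-subject dataset; oracle computed from the definition
  m <- matrix(c(4, 5, 6, 7, 8,
                5, 7, 8, 9, 10,
                6, 6, 9, 11, 11), 5, 3,
              dimnames = list(paste0("s", 1:5), c("a", "b", "c")))
  n <- 5; k <- 3
  grand <- mean(m)
  ss_factor <- n * sum((colMeans(m) - grand)^2)
  ss_subject <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_factor - ss_subject
  F_oracle <- (ss_factor / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  p_oracle <- stats::pf(F_oracle, k - 1, (k - 1) * (n - 1),
                        lower.tail = FALSE)
  a <- rm_anova(long_table(m))
  expect_equal(a$F, F_oracle, tolerance = 1e-9)
  expect_equal(a$p, p_oracle, tolerance = 1e-9)
  expect_equal(a$ms_error, ss_err / ((k - 1) * (n - 1)), tolerance = 1e-9)
})

test_that("unbalanced tables are rejected with the missing cells named", {
  tab <- rand_table(5, 3)
  tab <- tab[-2, ]
  err <- expect_error(rm_anova(tab), "unbalanced")
  expect_match(conditionMessage(err), "s2")
})

test_that("F and p are invariant under response rescaling", {
  tab <- rand_table(8, 3, effect = 0.3, seed = 9)
  a1 <- rm_anova(tab)
  tab$value <- tab$value * 1234.5
  a2 <- rm_anova(tab)
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  expect_equal(a1$p, a2$p, tolerance = 1e-9)
})

test_that("Tukey with two levels equals the unadjusted paired comparison", {
  tab <- rand_table(8, 2, effect = 0.4, seed = 5)
  tk <- tukey_posthoc(tab)
  expect_equal(nrow(tk), 1L)
  expect_equal(tk$p_adj, rm_anova(tab)$p, tolerance = 1e-6)
})

test_that("identical levels give all adjusted p = 1", {
  m <- matrix(stats::rnorm(6), 6, 3,
              dimnames = list(paste0("s", 1:6), c("a", "b", "c")))
  # identical responses across levels, subject-specific values
  tk <- tukey_posthoc(long_table(m))
  expect_equal(tk$p_adj, rep(1, 3), tolerance = 1e-9)
})

test_that("a strong anterior-posterior effect has its pair as the smallest p", {
  set.seed(11)
  m <- matrix(stats::rnorm(24, sd = 0.02), 8, 3,
              dimnames = list(paste0("s", 1:8),
                              c("anterior", "central", "posterior")))
  m[, "anterior"] <- m[, "anterior"] + 0.19
  m[, "central"] <- m[, "central"] + 0.15
  m[, "posterior"] <- m[, "posterior"] + 0.12
  tk <- tukey_posthoc(long_table(m))
  key <- paste(tk$level_1, tk$level_2)
  expect_equal(key[which.min(tk$p_adj)], "anterior posterior")
  expect_lt(min(tk$p_adj), 0.05)
})

test_that("pearson correlations match the t-distribution formula", {
  x <- 1:8
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_lt(pearson_corr(x, 2 * x + 1)$p, 1e-12)

  # orthogonalized response: r = 0 exactly
  set.seed(2)
  y <- stats::rnorm(8)
  y <- y - mean(y)
  xc <- x - mean(x)
  y_orth <- y - sum(y * xc) / sum(xc^2) * xc
  expect_lt(abs(pearson_corr(x, y_orth)$r), 1e-12)

  # construct data with sample correlation exactly 0.3, n = 8
  set.seed(3)
  e <- stats::rnorm(8)
  e <- e - mean(e)
  e_orth <- e - sum(e * xc) / sum(xc^2) * xc
  y3 <- 0.3 * xc / stats::sd(xc) +
    sqrt(1 - 0.09) * e_orth / stats::sd(e_orth)
  res <- pearson_corr(x, y3)
  expect_equal(res$r, 0.3, tolerance = 1e-12)
  t_or <- 0.3 * sqrt(6 / (1 - 0.09))
  expect_equal(res$p, 2 * stats::pt(t_or, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(round(res$p, 2), 0.47)

  expect_error(pearson_corr(rep(1, 8), 1:8), "zero variance")
  expect_error(pearson_corr(1:2, 2:3), "n >= 3")
})

test_that("greenhouse-geisser epsilon is 1 under compound symmetry and bounded", {
  tab <- rand_table(30, 3, seed = 21)
  a <- rm_anova(tab)
  expect_gte(a$gg_epsilon, 0.5)
  expect_lte(a$gg_epsilon, 1)
  expect_gte(a$p_gg, a$p - 1e-12)  # correction never anti-conservative
})
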