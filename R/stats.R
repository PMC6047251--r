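#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA for a single factor: `F = MS_factor /
#' MS_(factor x subject)` with `(k - 1)` and `(k - 1)(n - 1)` degrees of
#' freedom, fitted via `stats::aov` with an `Error(subject/level)` stratum.
#' The uncorrected p value is reported (as is conventional when following
#' up with Tukey tests); a Greenhouse-Geisser-corrected p value is also
#' returned, labeled, for sphericity-sensitive use.
#'
#' @param table data frame with columns `subject`, `level`, `value` —
#'   balanced: every subject must have every level exactly once (average
#'   regions sharing a level first, e.g. with [strain_long_table()]).
#' @return object of class `rm_anova`: list with `effect`, `F`, `df_num`,
#'   `df_den`, `p`, `p_gg`, `gg_epsilon`, `ms_error`, `n_subjects`,
#'   `levels`, `means`.
#' @export
rm_anova <- function(table) {
  table <- check_balanced(table)
  k <- length(unique(table$level))
  n <- length(unique(table$subject))
  if (k < 2) stop("need >= 2 factor levels")
  if (n < 3) stop("need >= 3 subjects")
  table$subject <- factor(table$subject)
  table$level <- factor(table$level)
  fit <- stats::aov(value ~ level + Error(subject / level), data = table)
  tab <- summary(fit)[["Error: subject:level"]][[1]]
  Fv <- tab["level", "F value"]
  p <- tab["level", "Pr(>F)"]
  ms_err <- tab["Residuals", "Mean Sq"]
  # constant response across levels: define F = 0, p = 1 (0/0 ratio)
  lm_ <- tapply(table$value, table$level, mean)
  if (!is.finite(Fv) ||
      diff(range(lm_)) < 1e-12 * (1 + max(abs(table$value)))) {
    Fv <- 0
    p <- 1
  }
  eps <- gg_epsilon(table)
  p_gg <- stats::pf(Fv, eps * (k - 1), eps * (k - 1) * (n - 1),
                    lower.tail = FALSE)
  structure(list(effect = "level", F = Fv, df_num = k - 1,
                 df_den = (k - 1) * (n - 1), p = p, p_gg = p_gg,
                 gg_epsilon = eps, ms_error = ms_err, n_subjects = n,
                 levels = levels(table$level),
                 means = tapply(table$value, table$level, mean)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p))
  cat(sprintf("  Greenhouse-Geisser: epsilon = %.3f, p = %.4g\n",
              x$gg_epsilon, x$p_gg))
  invisible(x)
}

check_balanced <- function(table) {
  stopifnot(all(c("subject", "level", "value") %in% names(table)))
  table <- table[!is.na(table$value), ]
  cells <- table(table$subject, table$level)
  if (any(cells != 1)) {
    bad <- which(cells != 1, arr.ind = TRUE)
    stop("unbalanced table; missing or duplicated cells: ",
         paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  table
}

# Greenhouse-Geisser epsilon: trace(Sc)^2 / ((k-1) * sum(Sc^2)) with Sc the
# double-centered covariance of the subject x level response matrix.
gg_epsilon <- function(table) {
  m <- tapply(table$value, list(table$subject, table$level), mean)
  S <- stats::cov(m)
  k <- ncol(S)
  C <- diag(k) - matrix(1 / k, k, k)
  Sc <- C %*% S %*% C
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  if (!is.finite(num / den) || den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}

#' Tukey post hoc tests after a repeated-measures ANOVA
#'
#' All pairwise level comparisons using the studentized range distribution
#' with the ANOVA's within-subject error term (`MS_(factor x subject)`, its
#' degrees of freedom).
#'
#' @param table balanced long table as for [rm_anova()].
#' @return data frame `level_1`, `level_2`, `diff`, `q`, `p_adj`.
#' @export
tukey_posthoc <- function(table) {
  a <- rm_anova(table)
  k <- length(a$levels)
  n <- a$n_subjects
  se <- sqrt(a$ms_error / n)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- a$means[[a$levels[j]]] - a$means[[a$levels[i]]]
      q <- if (se == 0) ifelse(abs(d) > 1e-15, Inf, 0) else abs(d) / se
      p <- if (is.infinite(q)) 0 else
        stats::ptukey(q, k, a$df_den, lower.tail = FALSE)
      out[[length(out) + 1]] <- data.frame(
        level_1 = a$levels[i], level_2 = a$levels[j], diff = d, q = q,
        p_adj = p)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation between a per-subject covariate and strain
#'
#' Product-moment correlation with the two-sided p value from
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x per-subject covariate (e.g. BMI or body weight).
#' @param y per-subject strain.
#' @return list `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in correlation input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
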