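#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness statistic (D'Agostino) and transformed
#' kurtosis statistic (Anscombe-Glynn) into K2 = Zs^2 + Zk^2, referred to a
#' chi-squared distribution with 2 df. Requires n >= 8; smaller samples (and
#' constant vectors) are flagged "assume non-normal" without a statistic.
#'
#' @param x Numeric vector.
#' @param alpha Gate level used for the `normal` decision (default 0.05).
#' @return List `statistic` (K2), `p_value`, `n`, `normal` (logical decision),
#'   `assumed` (TRUE when the decision was a flag, not a test).
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L || stats::sd(x) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                normal = FALSE, assumed = TRUE))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970) transformation to approximate normality
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / a + sqrt((Y / a)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqB1 * (2 / sqB1 + sqrt(1 + 4 / sqB1^2))
  Zk <- ((1 - 2 / (9 * A)) -
         ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  p <- stats::pchisq(K2, df = 2, lower.tail = FALSE)
  list(statistic = K2, p_value = p, n = n, normal = p >= alpha,
       assumed = FALSE)
}

#' Paired two-condition comparison with normality-gated test selection
#'
#' The paired differences are tested for normality; if normal, a paired
#' t-test is used, otherwise the Wilcoxon signed-rank test (exact p for
#' n <= 25 without ties/zeros, normal approximation with continuity
#' correction otherwise).
#'
#' @param a,b Numeric vectors of matched values (same units in the same
#'   order), or a long data.frame with `unit_id`, `condition`, `value` and
#'   exactly two conditions.
#' @param alpha Normality gate level (default 0.05).
#' @return List of class `test_report`: `test_name`, `statistic`, `dof_or_n`,
#'   `p_value`, `normality_p`, `n`.
#' @export
paired_compare <- function(a, b = NULL, alpha = 0.05) {
  if (is.data.frame(a)) {
    w <- long_to_wide(a)
    if (ncol(w) != 2L) stop("paired_compare needs exactly two conditions")
    b <- w[[2L]]; a <- w[[1L]]
  }
  if (length(a) != length(b)) stop("unmatched pair lengths")
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- a - b
  nc <- normality_check(d, alpha)
  if (all(d == 0))
    return(report("paired t-test", 0, length(d) - 1L, 1, nc$p_value,
                  length(d)))
  if (isTRUE(nc$normal)) {
    tt <- stats::t.test(a, b, paired = TRUE)
    report("paired t-test", unname(tt$statistic), unname(tt$parameter),
           tt$p.value, nc$p_value, length(a))
  } else {
    n_eff <- sum(d != 0)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = n_eff <= 25,
                         correct = TRUE))
    report("Wilcoxon signed-rank", unname(wt$statistic), n_eff, wt$p.value,
           nc$p_value, length(a))
  }
}

#' Unpaired two-group comparison with normality-gated test selection
#'
#' Both groups normal: unpaired t-test (equal variances). Otherwise:
#' Mann-Whitney U test.
#'
#' @param a,b Numeric vectors (independent groups).
#' @param alpha Normality gate level.
#' @return A `test_report` list (see [paired_compare()]).
#' @export
unpaired_compare <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) stop("need at least 3 per group")
  na <- normality_check(a, alpha); nb <- normality_check(b, alpha)
  np <- suppressWarnings(min(na$p_value, nb$p_value, na.rm = TRUE))
  if (isTRUE(na$normal) && isTRUE(nb$normal)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    report("unpaired t-test", unname(tt$statistic), unname(tt$parameter),
           tt$p.value, np, length(a) + length(b))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    report("Mann-Whitney U", unname(wt$statistic), length(a) + length(b),
           wt$p.value, np, length(a) + length(b))
  }
}

#' Three-condition repeated-measures comparison
#'
#' Complete blocks (every unit measured in every condition) are required.
#' Normal residuals: repeated-measures ANOVA with Tukey HSD pairwise
#' comparisons (both sphericity-uncorrected and Greenhouse-Geisser-corrected
#' p-values are reported). Non-normal: Friedman test with Dunn's post-test,
#' Bonferroni-adjusted over the pairwise comparisons.
#'
#' @param df Long data.frame with columns `unit_id`, `condition`, `value`.
#' @param alpha Normality gate level.
#' @return A `test_report` list with additional fields `post_hoc` (data.frame
#'   of pairwise comparisons) and, for the ANOVA branch, `p_value_gg`.
#' @export
repeated_compare <- function(df, alpha = 0.05) {
  stopifnot(all(c("unit_id", "condition", "value") %in% names(df)))
  w <- long_to_wide(df)
  if (anyNA(w)) {
    miss <- which(is.na(w), arr.ind = TRUE)
    stop("incomplete blocks; missing cells: ",
         paste(sprintf("(%s, %s)", rownames(w)[miss[, 1]],
                       colnames(w)[miss[, 2]]), collapse = ", "))
  }
  n <- nrow(w); k <- ncol(w)
  if (n < 3L || k < 2L) stop("need >= 3 units and >= 2 conditions")
  m <- as.matrix(w)
  grand <- mean(m)
  cond_means <- colMeans(m); unit_means <- rowMeans(m)
  resid <- m - outer(unit_means, cond_means, "+") + grand
  nc <- normality_check(as.vector(resid), alpha)
  if (isTRUE(nc$normal)) rm_anova(m, nc) else friedman_dunn(m, nc)
}

rm_anova <- function(m, nc) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_unit <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_unit
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  F <- if (ms_err > 0) ms_cond / ms_err else 0
  p <- if (ms_err > 0) stats::pf(F, df1, df2, lower.tail = FALSE) else 1
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- stats::cov(m)
  Sc <- S - outer(rowMeans(S), colMeans(S), "+") + mean(S)
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  p_gg <- if (ms_err > 0)
    stats::pf(F, df1 * eps, df2 * eps, lower.tail = FALSE) else 1
  # Tukey HSD on condition means with the within-subjects error term
  cm <- colMeans(m)
  pairs <- utils::combn(k, 2)
  post <- data.frame(
    a = colnames(m)[pairs[1, ]], b = colnames(m)[pairs[2, ]],
    diff = cm[pairs[1, ]] - cm[pairs[2, ]])
  post$p_adj <- if (ms_err > 0)
    stats::ptukey(abs(post$diff) / sqrt(ms_err / n), k, df2,
                  lower.tail = FALSE) else 1
  rep <- report("repeated-measures ANOVA", F, c(df1, df2), p, nc$p_value, n)
  rep$p_value_gg <- p_gg
  rep$gg_epsilon <- eps
  rep$post_hoc <- post
  rep
}

friedman_dunn <- function(m, nc) {
  n <- nrow(m); k <- ncol(m)
  ft <- stats::friedman.test(m)
  if (!is.finite(ft$statistic)) {  # fully tied blocks (e.g. constant data)
    ft$statistic <- 0; ft$p.value <- 1
  }
  R <- t(apply(m, 1L, rank))  # mid-ranks within blocks
  rs <- colMeans(R)
  pairs <- utils::combn(k, 2)
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (rs[pairs[1, ]] - rs[pairs[2, ]]) / se
  post <- data.frame(a = colnames(m)[pairs[1, ]], b = colnames(m)[pairs[2, ]],
                     z = z,
                     p_adj = pmin(1, 2 * stats::pnorm(-abs(z)) * ncol(pairs)))
  rep <- report("Friedman", unname(ft$statistic), unname(ft$parameter),
                ft$p.value, nc$p_value, n)
  rep$post_hoc <- post
  rep
}

report <- function(test_name, statistic, dof_or_n, p_value, normality_p, n) {
  structure(list(test_name = test_name, statistic = statistic,
                 dof_or_n = dof_or_n, p_value = p_value,
                 normality_p = normality_p, n = n),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, normality p = %.3g)\n",
              x$test_name, x$statistic[1L], x$p_value, x$n,
              if (is.na(x$normality_p)) NA else x$normality_p))
  if (!is.null(x$post_hoc)) {
    cat("post hoc:\n"); print(x$post_hoc, row.names = FALSE)
  }
  invisible(x)
}

long_to_wide <- function(df) {
  stopifnot(all(c("unit_id", "condition", "value") %in% names(df)))
  conds <- unique(df$condition)
  units <- unique(df$unit_id)
  if (anyDuplicated(df[c("unit_id", "condition")]))
    stop("each unit must appear once per condition")
  w <- matrix(NA_real_, length(units), length(conds),
              dimnames = list(units, conds))
  w[cbind(match(df$unit_id, units), match(df$condition, conds))] <- df$value
  as.data.frame(w)
}

#' Percent deletion from synapse counts
#'
#' Worked-example arithmetic for ablation efficiency from pooled per-group
#' synapse totals: `100 * (1 - n_ablated / n_control)`.
#'
#' @param n_control Synapse count in control tissue.
#' @param n_ablated Synapse count in ablated tissue.
#' @return Percent deletion.
#' @export
synapse_deletion_pct <- function(n_control, n_ablated) {
  stopifnot(n_control > 0, n_ablated >= 0)
  100 * (1 - n_ablated / n_control)
}
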