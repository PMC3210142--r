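# One- and two-factor fixed-effects ANOVA built from sums of squares, with
# Tukey's HSD on the studentized range and the pooled-variance Student
# t-test. Built directly from the sums-of-squares identities so every term
# is auditable; base R's aov/TukeyHSD/t.test serve as independent
# cross-checks in the test suite, never as the implementation.

# Residual sum of squares of a least-squares fit on design matrix X.
rss_of <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

rank_of <- function(X) qr(X)$rank

# Treatment-contrast columns for a factor (first level as reference).
contrast_cols <- function(f) {
  f <- factor(f)
  L <- levels(f)
  if (length(L) < 2L) stop("factor needs >= 2 levels", call. = FALSE)
  cols <- vapply(L[-1], function(l) as.numeric(f == l),
                 numeric(length(f)))
  matrix(cols, nrow = length(f))
}

#' One- or two-factor analysis of variance
#'
#' One-factor ANOVA uses the classical between/within decomposition; the
#' two-factor analysis fits the cell-means model with interaction (optional)
#' and reports type-II sums of squares (each main effect adjusted for the
#' other, the interaction adjusted for both), which reduce to the standard
#' decomposition for balanced designs and remain conventional for the
#' unbalanced field counts that image-based experiments produce. P-values
#' come from the F distribution. When every observation is identical the
#' F statistics are undefined and reported as `NA` with p = 1.
#'
#' @param values Numeric response.
#' @param factor1 First grouping factor.
#' @param factor2 Optional second grouping factor.
#' @param interaction Include the interaction term (two-factor only).
#' @return Object of class `np_anova`: `table` (term, df, sumsq, meansq,
#'   statistic, p_value; last row = residuals), plus the data and residual
#'   mean square for post-hoc tests.
#' @export
np_anova <- function(values, factor1, factor2 = NULL, interaction = TRUE) {
  y <- as.numeric(values)
  f1 <- factor(factor1)
  n <- length(y)
  if (length(f1) != n) stop("factor1 length mismatch", call. = FALSE)
  if (nlevels(f1) < 2L) stop("factor1 needs >= 2 groups", call. = FALSE)
  ss_total <- sum((y - mean(y))^2)

  if (is.null(factor2)) {
    means <- tapply(y, f1, mean)
    ns <- tapply(y, f1, length)
    ss_between <- sum(ns * (means - mean(y))^2)
    ss_within <- sum((y - means[f1])^2)
    df_b <- nlevels(f1) - 1L
    df_w <- n - nlevels(f1)
    if (df_w < 1L) stop("residual degrees of freedom = 0", call. = FALSE)
    ms_w <- ss_within / df_w
    if (ms_w > 0) {
      f_stat <- (ss_between / df_b) / ms_w
      p <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
    } else if (ss_between <= .Machine$double.eps * max(1, sum(y^2))) {
      f_stat <- NA_real_; p <- 1  # all observations identical
    } else {
      f_stat <- Inf; p <- 0
    }
    tab <- data.frame(
      term = c("factor1", "Residuals"),
      df = c(df_b, df_w),
      sumsq = c(ss_between, ss_within),
      meansq = c(ss_between / df_b, ms_w),
      statistic = c(f_stat, NA_real_),
      p_value = c(p, NA_real_),
      stringsAsFactors = FALSE)
    return(structure(
      list(table = tab, values = y, factors = list(factor1 = f1),
           mse = ms_w, df_residual = df_w, interaction_included = FALSE),
      class = "np_anova"))
  }

  f2 <- factor(factor2)
  if (length(f2) != n) stop("factor2 length mismatch", call. = FALSE)
  if (nlevels(f2) < 2L) stop("factor2 needs >= 2 groups", call. = FALSE)
  one <- matrix(1, n, 1)
  XA <- contrast_cols(f1)
  XB <- contrast_cols(f2)
  XAB <- NULL
  if (interaction) {
    XAB <- matrix(0, n, ncol(XA) * ncol(XB))
    k <- 0L
    for (i in seq_len(ncol(XA))) for (j in seq_len(ncol(XB))) {
      k <- k + 1L
      XAB[, k] <- XA[, i] * XB[, j]
    }
  }
  X_ab <- cbind(one, XA, XB)
  X_full <- if (interaction) cbind(X_ab, XAB) else X_ab
  rss_full <- rss_of(X_full, y)
  df_res <- n - rank_of(X_full)
  if (df_res < 1L) {
    stop("residual degrees of freedom = 0 (singleton cells with interaction)",
         call. = FALSE)
  }
  # type II: each term against the model containing the other terms at or
  # below its order
  ss_A <- rss_of(cbind(one, XB), y) - rss_of(X_ab, y)
  ss_B <- rss_of(cbind(one, XA), y) - rss_of(X_ab, y)
  terms <- c("factor1", "factor2")
  ss <- c(ss_A, ss_B)
  dfs <- c(ncol(XA), ncol(XB))
  if (interaction) {
    ss_AB <- rss_of(X_ab, y) - rss_full
    terms <- c(terms, "factor1:factor2")
    ss <- c(ss, ss_AB)
    dfs <- c(dfs, rank_of(X_full) - rank_of(X_ab))
  }
  ms_res <- rss_full / df_res
  ms <- ss / dfs
  if (ms_res > 0) {
    f_stat <- ms / ms_res
    p <- stats::pf(f_stat, dfs, df_res, lower.tail = FALSE)
  } else {
    zero <- ss <= .Machine$double.eps * max(1, sum(y^2))
    f_stat <- ifelse(zero, NA_real_, Inf)
    p <- ifelse(zero, 1, 0)
  }
  tab <- data.frame(
    term = c(terms, "Residuals"),
    df = c(dfs, df_res),
    sumsq = c(ss, rss_full),
    meansq = c(ms, ms_res),
    statistic = c(f_stat, NA_real_),
    p_value = c(p, NA_real_),
    stringsAsFactors = FALSE)
  structure(
    list(table = tab, values = y,
         factors = list(factor1 = f1, factor2 = f2),
         mse = ms_res, df_residual = df_res,
         interaction_included = interaction, ss_total = ss_total),
    class = "np_anova")
}

#' @export
print.np_anova <- function(x, ...) {
  cat(sprintf("%d-factor ANOVA%s (type II sums of squares)\n",
              length(x$factors),
              if (isTRUE(x$interaction_included)) " with interaction" else ""))
  tab <- x$table
  tab$sumsq <- signif(tab$sumsq, 6)
  tab$meansq <- signif(tab$meansq, 6)
  tab$statistic <- signif(tab$statistic, 5)
  tab$p_value <- signif(tab$p_value, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tukey's HSD all-pairs comparisons
#'
#' Studentized-range comparisons among the levels of one factor of a fitted
#' [np_anova()], using the Tukey-Kramer standard error for unequal group
#' sizes. Adjusted p-values come from the studentized range distribution
#' with the fit's residual degrees of freedom.
#'
#' @param fit An `np_anova` result.
#' @param which Factor to compare (`"factor1"` or `"factor2"`).
#' @param alpha Family-wise significance level for the `significant` flags.
#' @return Object of class `tukey_hsd`: data frame of pairs with
#'   `mean_diff`, `q_stat`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(fit, which = "factor1", alpha = 0.05) {
  if (!inherits(fit, "np_anova")) stop("fit must be an np_anova", call. = FALSE)
  f <- fit$factors[[which]]
  if (is.null(f)) stop(sprintf("no factor '%s' in fit", which), call. = FALSE)
  y <- fit$values
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  k <- length(means)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(names(means), 2)
  mse <- fit$mse
  df <- fit$df_residual
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[j] - means[i]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    if (se == 0) {
      q <- if (abs(diff) > 0) Inf else NA_real_
      p <- if (abs(diff) > 0) 0 else 1
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    c(unname(diff), unname(q), unname(p))
  })
  out <- data.frame(
    group_i = pairs[1, ], group_j = pairs[2, ],
    mean_diff = res[1, ], q_stat = res[2, ], p_adj = res[3, ],
    significant = res[3, ] < alpha,
    stringsAsFactors = FALSE)
  structure(list(pairs = out, alpha = alpha, nmeans = k, df = df),
            class = "tukey_hsd")
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("Tukey HSD (%d groups, df = %d, alpha = %g)\n",
              x$nmeans, x$df, x$alpha))
  tab <- x$pairs
  tab$mean_diff <- signif(tab$mean_diff, 5)
  tab$q_stat <- signif(tab$q_stat, 5)
  tab$p_adj <- signif(tab$p_adj, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Equal-variance two-sided Student's t-test. When the pooled variance is
#' zero the statistic is undefined: p = 1 is returned for equal means
#' (no evidence of a difference) and p = 0 for unequal means.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return List: `t`, `df`, `p_value`, `mean_diff`.
#' @export
t_test_student <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 per sample", call. = FALSE)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    return(list(t = if (d == 0) NA_real_ else Inf * sign(d), df = df,
                p_value = if (d == 0) 1 else 0, mean_diff = d))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df), mean_diff = d)
}
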