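# Statistical kernel: one-way repeated-measures ANOVA with Greenhouse-Geisser
# correction, Tukey HSD pairwise comparisons (studentized range), and Pearson
# correlation with a least-squares line fit.

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Computes the within-subject F test for a condition effect from a complete
#' subjects x conditions table, together with the Greenhouse-Geisser
#' sphericity correction factor epsilon (from the double-centered condition
#' covariance matrix) and both the uncorrected and epsilon-corrected p
#' values.  The headline `p` is the corrected one when epsilon < 0.75 and
#' the uncorrected one otherwise; both are always returned.
#'
#' @param table Numeric matrix or data frame, subjects in rows, conditions in
#'   columns; no missing cells.
#' @return List of class `rm_anova`: `F`, `df` (k-1, (k-1)(n-1)),
#'   `epsilon`, `p_uncorrected`, `p_gg`, `p`, `ms_error`, `df_error`, `k`,
#'   `n`, `means`.
#' @examples
#' x <- matrix(rnorm(36), 12, 3)
#' rm_anova_gg(x)
#' @export
rm_anova_gg <- function(table) {
  x <- as.matrix(table)
  if (anyNA(x)) stop("missing cells are not supported (no imputation)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(x)
  subj_means <- rowMeans(x)
  cond_means <- colMeans(x)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- x - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  # a zero condition effect is F = 0 even when the error term is degenerate
  F <- if (ms_cond == 0) 0 else ms_cond / ms_err
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(x)
  C <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  tr_c <- sum(diag(C))
  eps <- if (sum(C^2) == 0) 1 else tr_c^2 / (df1 * sum(C^2))
  eps <- min(1, max(1 / df1, eps))
  p_unc <- stats::pf(F, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE)
  structure(
    list(F = F, df = c(df1, df2), epsilon = eps,
         p_uncorrected = p_unc, p_gg = p_gg,
         p = if (eps < 0.75) p_gg else p_unc,
         ms_error = ms_err, df_error = df2, k = k, n = n,
         means = cond_means),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%g, %g) = %.3f, eps = %.3f, p = %.4g (GG p = %.4g)\n",
              x$df[1], x$df[2], x$F, x$epsilon, x$p_uncorrected, x$p_gg))
  invisible(x)
}

# Core Tukey HSD given group means, a common error mean square, its df, and
# the per-group sample sizes.  q = |m_i - m_j| / sqrt(ms_error / n); for
# unequal group sizes the Tukey-Kramer standard error
# sqrt(ms/2 (1/n_i + 1/n_j)) is used.  Adjusted p from the studentized-range
# distribution with k groups.
tukey_core <- function(means, ms_error, df_error, n_per_group, k = length(means)) {
  nm <- names(means)
  if (is.null(nm)) nm <- as.character(seq_along(means))
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, k)
  pairs <- utils::combn(seq_along(means), 2)
  diff <- means[pairs[1, ]] - means[pairs[2, ]]
  se <- sqrt(ms_error / 2 *
               (1 / n_per_group[pairs[1, ]] + 1 / n_per_group[pairs[2, ]]))
  q <- ifelse(diff == 0, 0, abs(diff) / se)
  p <- stats::ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
  data.frame(
    pair = paste(nm[pairs[1, ]], nm[pairs[2, ]], sep = "-"),
    diff = as.numeric(diff), q = as.numeric(q), p_adj = as.numeric(p),
    stringsAsFactors = FALSE)
}

#' Tukey HSD pairwise comparisons for a repeated-measures design
#'
#' Compares all condition pairs of a subjects x conditions table using the
#' within-subject error term from [rm_anova_gg()].
#'
#' @param table Subjects x conditions matrix.
#' @param ms_error Error mean square; defaults to the condition-by-subject
#'   interaction mean square from [rm_anova_gg()].
#' @param df_error Error degrees of freedom.
#' @return Object of class `tukey_result`: data frame `pair`, `diff`, `q`,
#'   `p_adj` with attributes `k` and `df_error`.
#' @export
tukey_hsd <- function(table, ms_error = NULL, df_error = NULL) {
  x <- as.matrix(table)
  if (is.null(ms_error) || is.null(df_error)) {
    a <- rm_anova_gg(x)
    ms_error <- a$ms_error
    df_error <- a$df_error
  }
  res <- tukey_core(colMeans(x), ms_error, df_error, n_per_group = nrow(x))
  structure(res, k = ncol(x), df_error = df_error,
            class = c("tukey_result", "data.frame"))
}

#' Tukey HSD for independent groups (one-way layout)
#'
#' Used for the simulation study, where the per-dipole CM errors are the
#' observations and the references the groups: the error term is the pooled
#' within-group mean square.
#'
#' @param values Numeric observations.
#' @param groups Group labels (same length).
#' @return A `tukey_result` (see [tukey_hsd()]) with an `anova` attribute
#'   holding the one-way F test.
#' @export
tukey_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  ns <- tapply(values, groups, length)
  means <- tapply(values, groups, mean)
  k <- nlevels(groups)
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_err <- length(values) - k
  ms_within <- ss_within / df_err
  ss_between <- sum(ns * (means - mean(values))^2)
  Fv <- (ss_between / (k - 1)) / ms_within
  res <- tukey_core(means, ms_within, df_err, n_per_group = as.numeric(ns))
  structure(res, k = k, df_error = df_err,
            anova = list(F = Fv, df = c(k - 1, df_err),
                         p = stats::pf(Fv, k - 1, df_err, lower.tail = FALSE)),
            class = c("tukey_result", "data.frame"))
}

#' Pearson correlation with least-squares line fit
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return List: `R` (correlation coefficient), `p` (two-sided, t based),
#'   `slope`, `intercept`, `n`.
#' @examples
#' pearson_corr_fit(1:10, 2 * (1:10) + 1)
#' @export
pearson_corr_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(R = unname(ct$estimate), p = ct$p.value,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(x))
}
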