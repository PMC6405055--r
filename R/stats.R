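# Inferential layer: one-way repeated-measures ANOVA with Bonferroni
# pairwise comparisons and partial eta squared, and independent two-sample
# t-tests (pooled or Welch) with Cohen's d.

#' One-way repeated-measures ANOVA
#'
#' One within-subject factor. With `missing = "complete"` (default),
#' subjects missing any condition are dropped and the balanced design is
#' fitted with `aov(value ~ condition + Error(subject))`; with
#' `missing = "available"` every observed cell is used and the condition
#' effect is tested after the subject effect in a sequential two-way
#' `lm` fit. Effect size is partial eta squared,
#' `SS_condition / (SS_condition + SS_error)`. Pairwise condition
#' comparisons are paired t-tests (complete cases per pair) with
#' Bonferroni-adjusted p values, `min(1, p * n_pairs)`.
#'
#' @param values Numeric matrix, subjects in rows, conditions in columns
#'   (column names label the conditions); NA allowed.
#' @param missing `"complete"` (complete-case, default) or `"available"`.
#' @return An object of class `improv_anova`: list with `F`, `df1`, `df2`,
#'   `p`, `eta_sq`, `n_subjects` (used), `n_dropped`, `missing`, and
#'   `pairwise` (`data.frame(pair, mean_diff, p_adj)`).
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 5, 6))
#' rm_anova(m)
#' @export
rm_anova <- function(values, missing = c("complete", "available")) {
  missing <- match.arg(missing)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  k <- ncol(values)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  observed <- !is.na(values)
  usable_cond <- colSums(observed) > 0
  if (sum(usable_cond) < 2)
    stop("fewer than 2 usable conditions", call. = FALSE)

  complete <- rowSums(observed) == k
  n_dropped <- if (missing == "complete") sum(!complete) else 0L

  if (missing == "complete") {
    m <- values[complete, , drop = FALSE]
    n <- nrow(m)
    if (n < 2) stop("fewer than 2 complete subjects", call. = FALSE)
    long <- data.frame(
      value = as.vector(m),
      condition = factor(rep(colnames(m), each = n), levels = colnames(m)),
      subject = factor(rep(seq_len(n), times = k)))
    fit <- stats::aov(value ~ condition + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    ss_cond <- tab["condition", "Sum Sq"]
    ss_err <- tab["Residuals", "Sum Sq"]
    df1 <- tab["condition", "Df"]
    df2 <- tab["Residuals", "Df"]
    fval <- tab["condition", "F value"]
    pval <- tab["condition", "Pr(>F)"]
    n_sub <- n
  } else {
    idx <- which(observed, arr.ind = TRUE)
    long <- data.frame(
      value = values[observed],
      condition = factor(colnames(values)[idx[, 2]], levels = colnames(values)),
      subject = factor(idx[, 1]))
    fit <- stats::lm(value ~ subject + condition, data = long)
    tab <- stats::anova(fit)
    ss_cond <- tab["condition", "Sum Sq"]
    ss_err <- tab["Residuals", "Sum Sq"]
    df1 <- tab["condition", "Df"]
    df2 <- tab["Residuals", "Df"]
    fval <- tab["condition", "F value"]
    pval <- tab["condition", "Pr(>F)"]
    n_sub <- length(unique(long$subject))
  }
  # all cells (numerically) equal: no effect and no error variance
  degenerate <- ss_cond + ss_err <=
    1e-12 * max(1, sum(values^2, na.rm = TRUE))
  if (degenerate) { fval <- 0; pval <- 1 }

  pairs <- utils::combn(colnames(values), 2, simplify = FALSE)
  n_pairs <- length(pairs)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    x <- values[, pr[1]]; y <- values[, pr[2]]
    ok <- !is.na(x) & !is.na(y)
    diff_ok <- x[ok] - y[ok]
    if (sum(ok) >= 2 && stats::sd(diff_ok) > 0) {
      tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
      p_raw <- tt$p.value
    } else p_raw <- if (sum(ok) >= 2 && mean(diff_ok) == 0) 1 else NA_real_
    data.frame(pair = paste(pr[1], pr[2], sep = " - "),
               mean_diff = mean(diff_ok),
               p_adj = pmin(1, p_raw * n_pairs))
  }))
  structure(
    list(F = unname(fval), df1 = unname(df1), df2 = unname(df2),
         p = unname(pval),
         eta_sq = if (degenerate) 0 else ss_cond / (ss_cond + ss_err),
         n_subjects = n_sub, n_dropped = n_dropped, missing = missing,
         pairwise = pairwise),
    class = "improv_anova"
  )
}

#' @export
print.improv_anova <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA (%s-case, %d subjects%s):\n  F(%g, %g) = %s, p = %s, partial eta^2 = %s\n",
    x$missing, x$n_subjects,
    if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else "",
    x$df1, x$df2, format(x$F, digits = digits),
    format.pval(x$p, digits = digits), format(x$eta_sq, digits = digits)))
  cat("  Bonferroni pairwise comparisons:\n")
  pw <- x$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("    %-24s diff = %s, p_adj = %s\n", pw$pair[i],
                format(pw$mean_diff[i], digits = digits),
                format.pval(pw$p_adj[i], digits = digits)))
  invisible(x)
}

#' Independent two-sample t-test with Cohen's d
#'
#' Pooled-variance (`df = n1 + n2 - 2`) or Welch (Satterthwaite df)
#' variants, two-sided or one-sided. Cohen's d is
#' `(mean(x) - mean(y)) / s_pooled` in both variants. The degenerate case
#' of zero variance in both groups with equal means returns `t = 0, p = 1`.
#'
#' @param x,y Numeric samples, each of length `>= 2`.
#' @param variant `"pooled"` or `"welch"`.
#' @param alternative `"two.sided"`, `"greater"` (mean of `x` greater) or
#'   `"less"`.
#' @return An object of class `improv_ttest`: list with `t`, `df`, `p`,
#'   `d`, `mean_x`, `mean_y`, `n_x`, `n_y`, `variant`, `alternative`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4), variant = "pooled")
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch"),
                         alternative = c("two.sided", "greater", "less")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  d <- if (sp2 > 0) (mean(x) - mean(y)) / sqrt(sp2)
       else if (mean(x) == mean(y)) 0 else NA_real_
  if (sp2 == 0 && mean(x) == mean(y)) {
    tt <- list(statistic = 0, parameter = n1 + n2 - 2,
               p.value = if (alternative == "two.sided") 1 else 0.5)
  } else if (sp2 == 0) {
    stop("zero variance in both groups with unequal means", call. = FALSE)
  } else {
    tt <- stats::t.test(x, y, var.equal = variant == "pooled",
                        alternative = alternative)
  }
  structure(
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, d = d,
         mean_x = mean(x), mean_y = mean(y), n_x = n1, n_y = n2,
         variant = variant, alternative = alternative),
    class = "improv_ttest"
  )
}

#' @export
print.improv_ttest <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Two-sample t-test (%s, %s):\n  t(%s) = %s, p = %s, Cohen's d = %s\n  means: %s (n = %d) vs %s (n = %d)\n",
    x$variant, x$alternative, format(x$df, digits = digits),
    format(x$t, digits = digits), format.pval(x$p, digits = digits),
    format(x$d, digits = digits), format(x$mean_x, digits = digits),
    x$n_x, format(x$mean_y, digits = digits), x$n_y))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Compare two collectives on every metric
#'
#' Runs a two-sample t-test per metric column between the two groups of a
#' binary grouping (e.g. gender, proficiency, median age split). Missing
#' metric values are excluded per parameter; a parameter with fewer than
#' two usable values in either group is flagged (`NA` statistics). The
#' one-sided direction reported is toward the group with the larger mean.
#'
#' @param mt Metrics table from [metrics_table()].
#' @param by Grouping as in [aggregate_metrics()]; must yield exactly two
#'   groups.
#' @param variant `"pooled"`, `"welch"`, or `"both"` (one result row per
#'   variant).
#' @param params Metric columns to test; default all.
#' @return A `data.frame` with one row per parameter (and variant):
#'   group means and n, `t`, `df`, `p` (two-sided), `p_one_sided`,
#'   `direction` (label of the larger-mean group), `d`, `stars`
#'   (`* p < .05, ** p < .01, *** p < .001`).
#' @export
compare_collectives <- function(mt, by, variant = c("pooled", "welch", "both"),
                                params = NULL) {
  variant <- match.arg(variant)
  variants <- if (variant == "both") c("pooled", "welch") else variant
  labels <- grouping_labels(mt, by)
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) != 2)
    stop("grouping must yield exactly 2 groups, got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  if (is.null(params)) params <- metric_columns(mt)
  rows <- list()
  for (p in params) {
    x <- mt[[p]][labels == groups[1] & !is.na(labels)]
    y <- mt[[p]][labels == groups[2] & !is.na(labels)]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    for (v in variants) {
      row <- data.frame(parameter = p, variant = v,
                        group1 = groups[1], group2 = groups[2],
                        mean1 = if (length(x)) mean(x) else NA_real_,
                        mean2 = if (length(y)) mean(y) else NA_real_,
                        n1 = length(x), n2 = length(y),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        p_one_sided = NA_real_,
                        direction = NA_character_, d = NA_real_,
                        stars = "")
      if (length(x) >= 2 && length(y) >= 2 &&
          (stats::sd(x) > 0 || stats::sd(y) > 0 || mean(x) == mean(y))) {
        tt <- two_sample_t(x, y, variant = v)
        dir_alt <- if (tt$mean_x >= tt$mean_y) "greater" else "less"
        t1 <- two_sample_t(x, y, variant = v, alternative = dir_alt)
        row$t <- tt$t; row$df <- tt$df; row$p <- tt$p
        row$p_one_sided <- t1$p
        row$direction <- if (dir_alt == "greater") groups[1] else groups[2]
        row$d <- tt$d
        row$stars <- significance_stars(tt$p)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("collective_comparison", "data.frame")
  out
}
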