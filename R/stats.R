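#' Per-group mean and standard deviation
#'
#' Results are reported as mean plus or minus the sample SD (n - 1
#' denominator); the SD is `NA` for a single observation.
#'
#' @param values Non-empty numeric vector of measurements.
#' @param group Group label.
#' @return An object of class `group_summary`: `group`, `n`, `mean`, `sd`.
#' @export
summarize_group <- function(values, group = "group") {
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  structure(list(group = as.character(group), n = length(values),
                 mean = mean(values),
                 sd = if (length(values) >= 2) sd(values) else NA_real_),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n = %d)\n", x$group, x$mean, x$sd, x$n))
  invisible(x)
}

t_result <- function(t, df, p, alpha, groups = c(NA, NA)) {
  structure(list(t = t, df = df, p = p, alpha = alpha,
                 significant = p <= alpha, groups = groups),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %g, p = %.4g (%ssignificant at alpha = %.2f)\n",
              x$t, x$df, x$p, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Unpaired two-tailed Student's t test
#'
#' Classical pooled-variance two-sample t test with `n1 + n2 - 2` degrees of
#' freedom and a two-tailed p-value; significance is declared at `p <=
#' alpha` inclusive. When both groups have zero variance, equal means give
#' `t = 0, p = 1` and unequal means are an error (the statistic is
#' undefined). Set `welch = TRUE` for the unequal-variance (Welch) variant.
#'
#' @param a,b Numeric vectors, each with at least 2 observations.
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch-Satterthwaite degrees of freedom instead of
#'   pooling (default FALSE, matching the classical Student test).
#' @return An object of class `t_test_result`: `t`, `df`, `p`, `alpha`,
#'   `significant`.
#' @export
students_t_test <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  from_summary_t_test(summarize_group(a, "a"), summarize_group(b, "b"),
                      alpha = alpha, welch = welch)
}

#' Pooled t test from group summaries
#'
#' Computes the same unpaired two-tailed t test as [students_t_test()]
#' directly from per-group mean, SD and n — the form in which published
#' results are reported — so printed summaries can be re-tested.
#'
#' @param s1,s2 [summarize_group()] objects (or lists with `mean`, `sd`,
#'   `n`), each with `n >= 2`.
#' @inheritParams students_t_test
#' @return An object of class `t_test_result`.
#' @examples
#' wt    <- list(group = "WT", n = 12, mean = 62.3, sd = 5.5)
#' lname <- list(group = "L-NAME", n = 12, mean = 72.7, sd = 4.0)
#' from_summary_t_test(lname, wt)
#' @export
from_summary_t_test <- function(s1, s2, alpha = 0.05, welch = FALSE) {
  n1 <- s1$n; n2 <- s2$n
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  v1 <- s1$sd^2; v2 <- s2$sd^2
  delta <- s1$mean - s2$mean
  if (v1 + v2 == 0) {
    if (delta == 0) {
      return(t_result(0, n1 + n2 - 2, 1, alpha,
                      c(s1$group %||% NA, s2$group %||% NA)))
    }
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  t <- delta / se
  p <- 2 * pt(-abs(t), df)
  t_result(t, df, p, alpha, c(s1$group %||% NA, s2$group %||% NA))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a group-comparison report
#'
#' Produces the tabular mirror of a figure panel: one row per group with
#' mean, SD and n, and one row per pairwise test with t, df, p and the
#' significance flag. Written as CSV (two files, `_summary.csv` and
#' `_tests.csv`) and/or a single Markdown file with both tables; a footer
#' notes that p-values are unadjusted.
#'
#' @param summaries List of [summarize_group()] objects.
#' @param tests List of [t_test_result] objects whose `groups` labels must
#'   all appear among the summaries.
#' @param output_path Path stem (no extension); `NULL` writes nothing.
#' @param format `"csv"`, `"markdown"` or both.
#' @return Invisibly, a list with data frames `summary` and `tests`.
#' @export
make_report <- function(summaries, tests = list(), output_path = NULL,
                        format = c("csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  groups <- vapply(summaries, function(s) s$group, character(1))
  sum_df <- data.frame(group = groups,
                       n = vapply(summaries, function(s) s$n, numeric(1)),
                       mean = vapply(summaries, function(s) s$mean,
                                     numeric(1)),
                       sd = vapply(summaries, function(s) s$sd, numeric(1)),
                       stringsAsFactors = FALSE)
  test_df <- if (length(tests) > 0) {
    refs <- unlist(lapply(tests, function(tt) tt$groups))
    refs <- refs[!is.na(refs)]
    unknown <- setdiff(refs, groups)
    if (length(unknown) > 0) {
      stop(sprintf("unknown group reference in tests: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    data.frame(group1 = vapply(tests, function(tt) tt$groups[1],
                               character(1)),
               group2 = vapply(tests, function(tt) tt$groups[2],
                               character(1)),
               t = vapply(tests, function(tt) tt$t, numeric(1)),
               df = vapply(tests, function(tt) tt$df, numeric(1)),
               p = vapply(tests, function(tt) tt$p, numeric(1)),
               significant = vapply(tests, function(tt) tt$significant,
                                    logical(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group1 = character(), group2 = character(), t = numeric(),
               df = numeric(), p = numeric(), significant = logical())
  }
  if (!is.null(output_path)) {
    if ("csv" %in% format) {
      write.csv(sum_df, paste0(output_path, "_summary.csv"),
                row.names = FALSE)
      write.csv(test_df, paste0(output_path, "_tests.csv"),
                row.names = FALSE)
    }
    if ("markdown" %in% format) {
      md <- c("# Group comparison report", "",
              "## Summaries (mean +/- SD)", "",
              "| group | n | mean | sd |", "|---|---|---|---|",
              sprintf("| %s | %d | %.4g | %.4g |", sum_df$group, sum_df$n,
                      sum_df$mean, sum_df$sd), "")
      if (nrow(test_df) > 0) {
        md <- c(md, "## Pairwise tests (unpaired two-tailed Student's t)",
                "", "| group1 | group2 | t | df | p | significant |",
                "|---|---|---|---|---|---|",
                sprintf("| %s | %s | %.4f | %g | %.4g | %s |",
                        test_df$group1, test_df$group2, test_df$t,
                        test_df$df, test_df$p, test_df$significant), "")
      }
      md <- c(md, "_p-values are unadjusted for multiple comparisons._")
      writeLines(md, paste0(output_path, ".md"))
    }
  }
  invisible(list(summary = sum_df, tests = test_df))
}
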