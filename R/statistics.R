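#' Pearson product-moment correlation with t-based p-value
#'
#' Standard Pearson correlation; the two-sided p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' A constant vector has no defined correlation and is an error, not r = 0.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return Object of class `correlation_result`: `r`, `r_squared`,
#'   `p_value`, `n_pairs`, `t`.
#' @export
#' @examples
#' pearson_cor(c(0, 4, 6, 8, 9), c(100, 60.5, 43.8, 24.3, 12.1))
pearson_cor <- function(x, y) {
  .assert(is.numeric(x) && is.numeric(y), "x and y must be numeric")
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3L, "need at least 3 pairs")
  .assert(!anyNA(x) && !anyNA(y), "missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, r_squared = r^2, p_value = ct$p.value,
                 n_pairs = length(x), t = unname(ct$statistic)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: R = %.3f; R^2 = %.3f; P = %.3g (n = %d)\n",
              x$r, x$r_squared, x$p_value, x$n_pairs))
  invisible(x)
}

#' Balanced fixed-effects two-way ANOVA with interaction
#'
#' Classical two-way analysis of variance for a balanced complete design
#' (every factor-A x factor-B cell has the same number >= 2 of
#' observations), with both factors fixed. F for each effect is its mean
#' square over the residual mean square.
#'
#' @param data data frame.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns. Omit
#'   `factor_b` (`NULL`) for a one-way ANOVA.
#' @return Object of class `anova_table`: data frame with one row per
#'   effect (`factor_a`, `factor_b`, `interaction`, `residual`) and columns
#'   `term`, `ss`, `df`, `ms`, `f`, `p`.
#' @export
viability_anova <- function(data, response, factor_a, factor_b = NULL) {
  .assert(is.data.frame(data) && nrow(data) > 0L, "empty table")
  .assert(all(c(response, factor_a, factor_b) %in% names(data)),
          "response/factor columns not found in data")
  y <- data[[response]]
  .assert(is.numeric(y) && !anyNA(y), "response must be numeric without NAs")
  a <- factor(data[[factor_a]])
  if (is.null(factor_b)) {
    cell_n <- table(a)
    .assert(length(unique(cell_n)) == 1L && min(cell_n) >= 2L,
            "unbalanced design: balanced cells with >= 2 observations required ",
            "(this implementation supports balanced designs only)")
    fit <- stats::aov(y ~ a)
    terms <- c(factor_a, "residual")
  } else {
    b <- factor(data[[factor_b]])
    cell_n <- table(a, b)
    .assert(length(unique(as.vector(cell_n))) == 1L && min(cell_n) >= 2L,
            "unbalanced design: balanced cells with >= 2 observations required ",
            "(this implementation supports balanced designs only)")
    fit <- stats::aov(y ~ a * b)
    terms <- c(factor_a, factor_b, "interaction", "residual")
  }
  sm <- summary(fit)[[1]]
  out <- data.frame(term = terms,
                    ss = sm[["Sum Sq"]], df = sm[["Df"]],
                    ms = sm[["Mean Sq"]], f = sm[["F value"]],
                    p = sm[["Pr(>F)"]], stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Analysis of variance\n")
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6); df$ms <- signif(df$ms, 6)
  df$f <- signif(df$f, 4); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Scheffé post-hoc comparisons between group means
#'
#' For every pair of groups the Scheffé statistic is
#' `(m_i - m_j)^2 / (MS_res * (1/n_i + 1/n_j))`; the pair is significant at
#' level `alpha` when the statistic exceeds `(k - 1) * F_crit(k - 1,
#' df_res, alpha)`, and its p-value is the upper-tail F probability of
#' `statistic / (k - 1)` on `(k - 1, df_res)` degrees of freedom. Scheffé
#' controls the family-wise error over *all* contrasts, hence is
#' conservative for pairwise use.
#'
#' @param means named numeric vector of group means.
#' @param n group sizes (scalar or vector matching `means`).
#' @param ms_res residual mean square from the ANOVA.
#' @param df_res residual degrees of freedom (> 0).
#' @param alpha significance level (default 0.05).
#' @return Data frame of class `scheffe_result` with one row per unordered
#'   pair: `group_i`, `group_j`, `diff`, `statistic`, `critical`, `p`,
#'   `significant`.
#' @export
#' @examples
#' scheffe_posthoc(c(a = 0, b = 0, c = 5), n = 5, ms_res = 1, df_res = 12)
scheffe_posthoc <- function(means, n, ms_res, df_res, alpha = 0.05) {
  k <- length(means)
  .assert(k >= 2L, "need at least 2 groups")
  .assert(df_res > 0, "df_residual must be positive")
  .assert(ms_res >= 0, "ms_res must be non-negative")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (length(n) == 1L) n <- rep(n, k)
  .assert(length(n) == k && all(n >= 1), "n must match means")
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))

  crit <- (k - 1) * stats::qf(1 - alpha, k - 1, df_res)
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    d <- means[i] - means[j]
    stat <- d^2 / (ms_res * (1 / n[i] + 1 / n[j]))
    data.frame(group_i = names(means)[i], group_j = names(means)[j],
               diff = unname(d), statistic = unname(stat), critical = crit,
               p = stats::pf(stat / (k - 1), k - 1, df_res, lower.tail = FALSE),
               significant = unname(stat > crit), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res), alpha = alpha,
            class = c("scheffe_result", "data.frame"))
}

#' @export
print.scheffe_result <- function(x, ...) {
  cat(sprintf("Scheffé post-hoc comparisons (alpha = %.2f)\n", attr(x, "alpha")))
  df <- as.data.frame(x)
  df$diff <- signif(df$diff, 4); df$statistic <- signif(df$statistic, 4)
  df$critical <- signif(df$critical, 4); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk routine with the sample
#' size contract made explicit (3 <= n <= 5000).
#'
#' @param values numeric vector.
#' @return Object of class `normality_result`: `W`, `p_value`, `n`.
#' @export
shapiro_wilk <- function(values) {
  .assert(is.numeric(values) && !anyNA(values), "values must be numeric without NAs")
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  sw <- stats::shapiro.test(values)
  structure(list(W = unname(sw$statistic), p_value = sw$p.value, n = n),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.4f, P = %.3g (n = %d)\n",
              x$W, x$p_value, x$n))
  invisible(x)
}

# Hours of ischemia encoded in a condition label: Control -> 0, "4I" -> 4,
# "9I" -> 9; reperfusion groups ("8IR") and unknown labels -> NA (excluded
# from the duration-response correlation).
.ischemia_hours <- function(condition) {
  h <- rep(NA_real_, length(condition))
  h[condition == "Control"] <- 0
  m <- regmatches(condition, regexec("^([0-9]+)I$", condition))
  ok <- lengths(m) == 2L
  h[ok] <- as.numeric(vapply(m[ok], `[`, "", 2L))
  h
}

#' Run the study's full statistical layer on an animal-level table
#'
#' Reproduces the analysis plan for a viability table: Shapiro-Wilk
#' normality per condition x measurement; balanced two-way ANOVA
#' (condition x measurement); Scheffé post-hoc comparisons between the
#' condition marginal means using the two-way residual mean square; and
#' Pearson correlation of viability against hours of ischemia
#' (ischemia-only groups plus control at 0 h), per measurement.
#'
#' @param normalized animal-level table with columns `condition`, `total`,
#'   `type1`, `type2b` (typically from [normalize_to_control()]).
#' @param alpha significance level (default 0.05).
#' @param correlation_mode `"animals"` (default): correlate per-animal
#'   values against duration; `"group_means"`: correlate the condition
#'   means.
#' @return Object of class `stats_report`: lists `normality`, `anova`,
#'   `scheffe`, `correlation` (one `correlation_result` per measurement, or
#'   `NULL` when fewer than 3 durations are present), plus `alpha`.
#' @export
run_study_stats <- function(normalized, alpha = 0.05,
                            correlation_mode = c("animals", "group_means")) {
  correlation_mode <- match.arg(correlation_mode)
  .assert(is.data.frame(normalized) && nrow(normalized) > 0L, "empty table")
  .assert(all(c("condition", "total", "type1", "type2b") %in% names(normalized)),
          "table must have condition, total, type1, type2b columns")

  meas <- c("total", "type1", "type2b")
  long <- do.call(rbind, lapply(meas, function(m)
    data.frame(condition = normalized$condition, measurement = m,
               viability = normalized[[m]], stringsAsFactors = FALSE)))
  long <- long[!is.na(long$viability), , drop = FALSE]

  normality <- list()
  for (cond in unique(long$condition))
    for (m in meas) {
      v <- long$viability[long$condition == cond & long$measurement == m]
      key <- paste(cond, m, sep = ".")
      normality[[key]] <- if (length(v) >= 3L) shapiro_wilk(v) else NULL
    }

  anova_tab <- viability_anova(long, "viability", "condition", "measurement")
  res <- anova_tab[anova_tab$term == "residual", ]
  marg <- tapply(long$viability, long$condition, mean)
  marg_n <- tapply(long$viability, long$condition, length)
  scheffe <- scheffe_posthoc(marg, n = as.numeric(marg_n),
                             ms_res = res$ss / res$df, df_res = res$df,
                             alpha = alpha)

  hours <- .ischemia_hours(normalized$condition)
  correlation <- NULL
  keep <- !is.na(hours)
  if (length(unique(hours[keep])) >= 3L) {
    correlation <- lapply(meas, function(m) {
      x <- hours[keep]; y <- normalized[[m]][keep]
      ok <- !is.na(y)
      if (correlation_mode == "group_means") {
        y <- as.numeric(tapply(y[ok], x[ok], mean))
        x <- sort(unique(x[ok]))
      } else {
        x <- x[ok]; y <- y[ok]
      }
      pearson_cor(x, y)
    })
    names(correlation) <- meas
  }

  structure(list(normality = normality, anova = anova_tab, scheffe = scheffe,
                 correlation = correlation, alpha = alpha,
                 correlation_mode = correlation_mode),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  print(x$anova)
  cat("\n")
  print(x$scheffe)
  if (!is.null(x$correlation)) {
    cat("\nViability vs hours of ischemia (", x$correlation_mode, "):\n", sep = "")
    for (m in names(x$correlation)) {
      cat(sprintf("  %-7s ", m)); print(x$correlation[[m]])
    }
  }
  nsmall <- sum(vapply(x$normality, function(z)
    !is.null(z) && z$p_value < x$alpha, TRUE))
  cat(sprintf("\nShapiro-Wilk: %d of %d condition x measurement cells depart from normality at alpha = %.2f\n",
              nsmall, length(x$normality), x$alpha))
  invisible(x)
}
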