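#' One-way ANOVA with Tukey HSD post hocs
#'
#' Classic one-way analysis of variance of a continuous variable across
#' diagnostic groups, with Tukey Honestly-Significant-Difference pairwise
#' comparisons and pooled-SD Cohen's d effect sizes. Missing values are
#' dropped pairwise-complete (the analysis n is recorded, since it varies by
#' variable in multi-variable tables).
#'
#' @param values Numeric outcome.
#' @param group Factor (or coercible) of group labels, same length.
#' @return Object of class `group_test`: list with `statistic` (F), `df`
#'   (c(between, within)), `p_value`, `n`, `posthoc` (data frame: pair,
#'   difference, tukey_p, cohen_d, direction), `means`.
#' @export
one_way_anova <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- droplevels(factor(group[keep]))
  k <- nlevels(group)
  if (k < 2) stop("at least 2 groups are required", call. = FALSE)
  if (any(table(group) < 2)) stop("every group needs n >= 2", call. = FALSE)
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]
  df <- as.integer(c(an[["Df"]][1], an[["Df"]][2]))
  p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- rownames(tk)
  d <- vapply(pairs, function(pr) {
    gg <- strsplit(pr, "-", fixed = TRUE)[[1]]
    cohen_d(values[group == gg[1]], values[group == gg[2]])
  }, 0)
  means <- tapply(values, group, mean)
  posthoc <- data.frame(pair = pairs, difference = tk[, "diff"],
                        tukey_p = tk[, "p adj"], cohen_d = unname(d),
                        direction = posthoc_direction(pairs, tk[, "diff"]),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(test = "one-way ANOVA", statistic = unname(f), df = df,
                 p_value = unname(p), n = length(values), posthoc = posthoc,
                 means = means),
            class = "group_test")
}

posthoc_direction <- function(pairs, diffs) {
  vapply(seq_along(pairs), function(i) {
    gg <- strsplit(pairs[i], "-", fixed = TRUE)[[1]]
    if (diffs[i] > 0) paste(gg[1], ">", gg[2]) else paste(gg[2], ">", gg[1])
  }, "")
}

# Pooled-SD Cohen's d on raw values.
cohen_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) on a
#' groups x outcome-levels count table.
#'
#' @param counts Integer matrix of counts (>= 2 rows and columns), rows
#'   typically diagnostic groups.
#' @return A `group_test` with `statistic` (chi-square), `df`, `p_value`,
#'   `n` (total count).
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || nrow(counts) < 2 || ncol(counts) < 2) {
    stop("counts must be a non-negative matrix, at least 2x2", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal row/column in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(test = "Pearson chi-square", statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = unname(ht$p.value),
                 n = sum(counts), posthoc = NULL, means = NULL),
            class = "group_test")
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Linear model of the outcome on group plus covariates (typically age, sex
#' and years of education); the group effect is the partial F after covariate
#' adjustment, with Tukey HSD contrasts on the covariate-adjusted group means
#' (via [multcomp::glht()]) and pooled-SD Cohen's d on the raw values for
#' reference.
#'
#' @param outcome Numeric outcome.
#' @param group Factor of group labels.
#' @param covariates Data frame of covariates (numeric or factor columns).
#' @return A `group_test` with the adjusted group F, df, p, and Tukey post
#'   hocs on adjusted means.
#' @export
ancova <- function(outcome, group, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- stats::complete.cases(outcome, group, covariates)
  dat <- data.frame(.y = outcome[keep],
                    .group = droplevels(factor(group[keep])),
                    covariates[keep, , drop = FALSE])
  if (nlevels(dat$.group) < 2) stop("at least 2 groups are required", call. = FALSE)
  full <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  reduced <- stats::lm(.y ~ . - .group, data = dat)
  cmp <- stats::anova(reduced, full)
  f <- cmp[["F"]][2]
  df <- as.integer(c(cmp[["Df"]][2], cmp[["Res.Df"]][2]))
  p <- cmp[["Pr(>F)"]][2]
  if (!is.finite(f)) {
    # covariates already fit the outcome exactly: no additional group variance
    f <- 0; p <- 1
  }
  glht_fit <- multcomp::glht(full, linfct = multcomp::mcp(.group = "Tukey"))
  sm <- summary(glht_fit)
  pairs <- sub(" - ", "-", names(sm$test$coefficients))
  diffs <- unname(sm$test$coefficients)
  d <- vapply(seq_along(pairs), function(i) {
    gg <- strsplit(pairs[i], "-", fixed = TRUE)[[1]]
    cohen_d(dat$.y[dat$.group == gg[1]], dat$.y[dat$.group == gg[2]])
  }, 0)
  posthoc <- data.frame(pair = pairs, difference = diffs,
                        tukey_p = unname(sm$test$pvalues), cohen_d = d,
                        direction = posthoc_direction(pairs, diffs),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(test = "ANCOVA", statistic = unname(f), df = df,
                 p_value = unname(p), n = nrow(dat), posthoc = posthoc,
                 means = tapply(dat$.y, dat$.group, mean)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  stat_name <- if (grepl("chi", x$test)) "chi-square" else "F"
  if (length(x$df) == 2) {
    cat(sprintf("%s: %s(%d, %d) = %.3f, p = %.3g, n = %d\n", x$test,
                stat_name, x$df[1], x$df[2], x$statistic, x$p_value, x$n))
  } else {
    cat(sprintf("%s: %s(%d) = %.3f, p = %.3g, n = %d\n", x$test, stat_name,
                x$df, x$statistic, x$p_value, x$n))
  }
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$tukey_p < 0.05, ]
    if (nrow(sig)) {
      cat("  Tukey HSD (p < .05):",
          paste(sprintf("%s (p=%.3g, d=%.2f)", sig$direction, sig$tukey_p,
                        sig$cohen_d), collapse = "; "), "\n")
    } else cat("  Tukey HSD: no pair significant at .05\n")
  }
  invisible(x)
}

#' Group-comparison summary table for a set of variables
#'
#' Runs [one_way_anova()] on each continuous variable and
#' [chi_square_test()] on each categorical variable of a participant table,
#' emitting one row per variable in the style of a cohort characteristics
#' table (statistic, df, p, post-hoc directionality string).
#'
#' @param data Data frame with a `group` column.
#' @param continuous,categorical Names of columns to test.
#' @return Data frame, one row per variable.
#' @export
group_summary_table <- function(data, continuous = character(),
                                categorical = character()) {
  rows <- list()
  for (v in continuous) {
    r <- one_way_anova(data[[v]], data$group)
    sig <- r$posthoc[r$posthoc$tukey_p < 0.05, ]
    rows[[v]] <- data.frame(
      variable = v, test = "ANOVA", statistic = r$statistic,
      df1 = r$df[1], df2 = r$df[2], p = r$p_value, n = r$n,
      comparisons = paste(sig$direction, collapse = "; "))
  }
  for (v in categorical) {
    tab <- table(data$group, data[[v]])
    r <- chi_square_test(tab)
    rows[[v]] <- data.frame(
      variable = v, test = "chi-square", statistic = r$statistic,
      df1 = r$df, df2 = NA_integer_, p = r$p_value, n = r$n,
      comparisons = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
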