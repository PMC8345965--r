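## Case-control statistical layer: assay QC, normality-gated group
## comparisons, correlation screens, and lipid-composition ratios.

#' Coefficient of variation of assay replicates
#'
#' `CV = 100 * sample sd / mean`, the intra-/inter-assay reproducibility
#' metric (8.3% intra- and 8.9% inter-assay in the assay's calibration).
#'
#' @param replicates Numeric vector of >= 2 replicate measurements with
#'   non-zero mean.
#' @return CV in percent.
#' @export
assay_cv <- function(replicates) {
  replicates <- as.numeric(replicates)
  if (length(replicates) < 2L)
    stop_format("need at least 2 replicates, got %d", length(replicates))
  m <- mean(replicates)
  if (m == 0) stop_format("replicate mean is zero; CV undefined")
  100 * stats::sd(replicates) / m
}

is_categorical <- function(x) {
  if (is.factor(x) || is.character(x) || is.logical(x)) return(TRUE)
  vals <- unique(x[!is.na(x)])
  length(vals) <= 2L && all(vals %in% c(0, 1))
}

#' Compare one variable between the two cohort groups
#'
#' Numeric variables go through a Shapiro--Wilk normality gate applied to
#' each group: if both groups pass at `alpha_normality` the (unpaired)
#' Student's t-test is used and summaries are mean +/- sd; otherwise the
#' Mann--Whitney U test with median (IQR) summaries. Categorical variables
#' use the chi-squared test without continuity correction, falling back to
#' Fisher's exact test (flagged) when any expected cell count is < 5.
#' `test` can override the gate.
#'
#' @param table A `cohort_table` (see [simulate_cohort()]) or data.frame with
#'   a `group` column (levels control/ACS).
#' @param variable Column name to compare.
#' @param alpha_normality Normality-gate alpha (default 0.05).
#' @param test `"auto"` (gate, default), `"t"`, `"mann_whitney"` or `"chi2"`.
#' @return An object of class `group_comparison`: `variable`, `test_used`,
#'   `statistic`, `p_value`, `summary` (named character, one per group),
#'   `shapiro_p` (numeric per group, numeric variables only),
#'   `fisher_fallback`.
#' @export
compare_groups <- function(table, variable, alpha_normality = 0.05,
                           test = c("auto", "t", "mann_whitney", "chi2")) {
  test <- match.arg(test)
  if (!variable %in% names(table))
    stop_format("variable '%s' not found in the cohort table", variable)
  g <- table$group
  x <- table[[variable]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(factor(g))[keep]
  lv <- levels(g)
  if (length(lv) != 2L) stop_format("need exactly 2 groups, got %d", length(lv))
  xs <- split(x, g)
  if (any(lengths(xs) == 0L))
    stop_format("variable '%s': a group has no observations", variable)
  categorical <- is_categorical(x)
  fisher_fallback <- FALSE
  shapiro_p <- NULL
  if (test == "auto") {
    if (categorical) {
      test <- "chi2"
    } else {
      shapiro_p <- vapply(xs, function(v) {
        if (length(v) < 3L || stats::sd(v) == 0) return(0)
        stats::shapiro.test(v)$p.value
      }, numeric(1))
      test <- if (all(shapiro_p > alpha_normality)) "t" else "mann_whitney"
    }
  } else if (!categorical && test != "chi2") {
    shapiro_p <- vapply(xs, function(v) {
      if (length(v) < 3L || stats::sd(v) == 0) return(0)
      stats::shapiro.test(v)$p.value
    }, numeric(1))
  }
  if (test == "chi2") {
    tab <- base::table(g, factor(x))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      ft <- stats::fisher.test(tab)
      fisher_fallback <- TRUE
      statistic <- NA_real_; p <- ft$p.value
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      statistic <- unname(ct$statistic); p <- ct$p.value
    }
    summ <- vapply(lv, function(l) {
      v <- xs[[l]]
      sprintf("%d (%.0f%%)", sum(v == 1), 100 * mean(v == 1))
    }, character(1))
  } else if (test == "t") {
    tt <- stats::t.test(xs[[1]], xs[[2]], var.equal = TRUE)
    statistic <- unname(tt$statistic); p <- tt$p.value
    summ <- vapply(xs, function(v)
      sprintf("%.2f ± %.2f", mean(v), stats::sd(v)), character(1))
  } else {
    wt <- stats::wilcox.test(xs[[1]], xs[[2]], exact = FALSE, correct = FALSE)
    statistic <- unname(wt$statistic); p <- wt$p.value
    summ <- vapply(xs, function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.2f (%.2f–%.2f)", q[2], q[1], q[3])
    }, character(1))
  }
  structure(
    list(variable = variable, test_used = test, statistic = statistic,
         p_value = p, summary = summ, shapiro_p = shapiro_p,
         fisher_fallback = fisher_fallback),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s  [%s%s]  p = %.4g\n", x$variable,
              x$test_used, if (x$fisher_fallback) ", Fisher fallback" else "",
              x$p_value))
  for (g in names(x$summary)) cat(sprintf("  %s: %s\n", g, x$summary[g]))
  invisible(x)
}

#' Spearman correlation screen against the stability score
#'
#' Rank correlation of every numeric covariate with the target over the
#' pooled cohort, with unadjusted p-values (Benjamini--Hochberg column
#' optional). Constant variables get `NA` rho and a flag.
#'
#' @param table A cohort table.
#' @param target Target column (default `pct_denat_8h`).
#' @param variables Covariates to screen; defaults to all numeric columns
#'   except the target and identifiers.
#' @param adjust Add a Benjamini--Hochberg adjusted p column (default FALSE).
#' @return data.frame: `variable`, `rho`, `p`, `n`, `significant` (p < 0.05),
#'   `flag`, and `p_bh` if `adjust`.
#' @export
spearman_screen <- function(table, target = "pct_denat_8h", variables = NULL,
                            adjust = FALSE) {
  if (!target %in% names(table))
    stop_format("target '%s' not found", target)
  if (is.null(variables)) {
    variables <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                         c(target, "subject_id"))
  }
  y <- table[[target]]
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    keep <- !is.na(x) & !is.na(y)
    n <- sum(keep)
    if (n < 3L)
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_, n = n,
                        significant = FALSE, flag = "too_few_pairs"))
    if (stats::sd(x[keep]) == 0)
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_, n = n,
                        significant = FALSE, flag = "constant"))
    ct <- suppressWarnings(
      stats::cor.test(x[keep], y[keep], method = "spearman", exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate), p = ct$p.value, n = n,
               significant = ct$p.value < 0.05, flag = "")
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' First-order partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `variable` and `target` after
#' regressing each on the controlling covariate (statin intake in the
#' study's analysis), with the t-based p-value on n - 3 degrees of freedom.
#'
#' @param table A cohort table.
#' @param variable,target Column names of the two variables.
#' @param covariate Controlling covariate column (numeric or 0/1-coded;
#'   default `statin_use`); must be non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
partial_correlation <- function(table, variable, target = "pct_denat_8h",
                                covariate = "statin_use") {
  for (v in c(variable, target, covariate)) {
    if (!v %in% names(table)) stop_format("column '%s' not found", v)
  }
  x <- as.numeric(table[[variable]])
  y <- as.numeric(table[[target]])
  z <- as.numeric(table[[covariate]])
  keep <- stats::complete.cases(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4L) stop_format("need >= 4 complete cases, got %d", n)
  if (stats::sd(z) == 0)
    stop_format("covariate '%s' is constant; partial correlation undefined",
                covariate)
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  # variable fully explained by covariate -> null residual -> r = 0
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    return(list(r = 0, p = 1, n = n))
  r <- stats::cor(rx, ry)
  df <- n - 3
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Apo A-I-to-HDL-lipid composition ratios
#'
#' Per-subject ratios of apo A-I to HDL-cholesterol, HDL-triglycerides and
#' HDL-phospholipids (mg of apo A-I per mg of lipid), with per-group mean
#' +/- sd of the ratios (mean of ratios, not ratio of means). Subjects with a
#' non-positive denominator are flagged and excluded from the summaries.
#'
#' @param table A cohort table with `apo_a1`, `hdl_cholesterol`,
#'   `hdl_triglycerides`, `hdl_phospholipids`.
#' @return List with `per_subject` (data.frame of ratios and `flag`) and
#'   `summary` (data.frame: group, ratio, mean, sd, n).
#' @export
lipid_ratios <- function(table) {
  need <- c("apo_a1", "hdl_cholesterol", "hdl_triglycerides",
            "hdl_phospholipids")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop_format("missing column(s): %s", paste(missing, collapse = ", "))
  denoms <- c(apoa1_to_hdl_cholesterol = "hdl_cholesterol",
              apoa1_to_hdl_triglycerides = "hdl_triglycerides",
              apoa1_to_hdl_phospholipids = "hdl_phospholipids")
  per <- data.frame(subject_id = table$subject_id, group = table$group)
  flag <- rep("", nrow(table))
  for (rn in names(denoms)) {
    den <- table[[denoms[rn]]]
    bad <- !is.finite(den) | den <= 0
    v <- ifelse(bad, NA_real_, table$apo_a1 / den)
    per[[rn]] <- v
    flag[bad] <- "zero_denominator"
  }
  per$flag <- flag
  rows <- list()
  for (g in levels(factor(table$group))) {
    for (rn in names(denoms)) {
      v <- per[[rn]][per$group == g & per$flag == ""]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, ratio = rn, mean = mean(v), sd = stats::sd(v),
        n = length(v))
    }
  }
  list(per_subject = per, summary = do.call(rbind, rows))
}
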