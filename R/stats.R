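#' Variance-stabilizing transforms
#'
#' Square-root or log transform of a variable, as applied to the allocation
#' and retention ratios before testing (amounts and their ratios are
#' right-skewed). For `log`, non-positive values are excluded and counted;
#' for `sqrt`, negatives are an error.
#'
#' @param values numeric vector.
#' @param kind `"sqrt"` or `"log"` (natural log).
#' @return Transformed values, with attributes `n_excluded` and `excluded`
#'   (logical index of dropped entries). All values excluded is an error.
#' @export
transform_values <- function(values, kind = c("sqrt", "log")) {
  kind <- match.arg(kind)
  if (kind == "sqrt") {
    if (any(values < 0, na.rm = TRUE)) {
      stop("sqrt transform requires nonnegative values")
    }
    excluded <- is.na(values)
    out <- sqrt(values[!excluded])
  } else {
    excluded <- is.na(values) | values <= 0
    out <- log(values[!excluded])
  }
  if (length(out) == 0) stop("all values excluded by the transform")
  attr(out, "n_excluded") <- sum(excluded)
  attr(out, "excluded") <- excluded
  out
}

#' Two-sample Student's t test
#'
#' Classical pooled-variance two-sided Student's t test (the default), with
#' Welch's unequal-variance form available by flag.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param equal_variance TRUE (default) for the pooled Student form, FALSE
#'   for Welch.
#' @param variable,grouping optional labels carried into the result.
#' @return Object of class `qd_ttest`: `t_statistic`, `p_value`, `df`,
#'   `n_per_group`, `mean_difference`, `equal_variance`, labels.
#' @export
ttest_two_sample <- function(group_a, group_b, equal_variance = TRUE,
                             variable = NA_character_,
                             grouping = NA_character_) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least two observations")
  }
  if (equal_variance && stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("zero pooled variance; t statistic undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = equal_variance,
                      alternative = "two.sided")
  structure(
    list(variable = variable, grouping = grouping,
         t_statistic = unname(ht$statistic),
         p_value = ht$p.value, df = unname(ht$parameter),
         n_per_group = c(length(group_a), length(group_b)),
         mean_difference = unname(diff(rev(ht$estimate))) * -1,
         equal_variance = equal_variance),
    class = "qd_ttest"
  )
}

#' @export
print.qd_ttest <- function(x, ...) {
  cat(sprintf("%s t test%s: t = %.3f, df = %.4g, p = %.4g (n = %d, %d)\n",
              if (x$equal_variance) "Student's" else "Welch's",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$t_statistic, x$df, x$p_value,
              x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}

#' Normality and variance-homogeneity checks
#'
#' Per-group Shapiro-Wilk normality tests and a Levene test of variance
#' homogeneity across groups (Brown-Forsythe median centering by default).
#' Constant groups are flagged and skipped for normality.
#'
#' @param values_by_group named list of numeric vectors.
#' @param center centering for the Levene test: `"median"`
#'   (Brown-Forsythe, default) or `"mean"`.
#' @return List with `normality` (data.frame: group, W, p, n,
#'   flag_constant) and `variance_homogeneity` (data.frame: statistic, p).
#' @export
assumption_checks <- function(values_by_group, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  if (is.null(names(values_by_group))) {
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  }
  norm <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]][!is.na(values_by_group[[g]])]
    const <- stats::var(v) == 0
    if (length(v) < 3 || const) {
      data.frame(group = g, W = NA_real_, p_value = NA_real_,
                 n = length(v), flag_constant = const)
    } else {
      sw <- stats::shapiro.test(v)
      data.frame(group = g, W = unname(sw$statistic),
                 p_value = sw$p.value, n = length(v), flag_constant = FALSE)
    }
  }))
  y <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(names(values_by_group),
                    lengths(values_by_group)))
  lev <- car::leveneTest(y ~ grp, center = if (center == "median") stats::median else mean)
  list(
    normality = norm,
    variance_homogeneity = data.frame(statistic = lev[1, "F value"],
                                      df = lev[1, "Df"],
                                      p_value = lev[1, "Pr(>F)"])
  )
}

#' Mean and SEM summaries by group
#'
#' Cell means with standard errors (`sd / sqrt(n)`), the summary used for
#' plotting; grouping keys are preserved.
#'
#' @param table data.frame.
#' @param value name of the value column.
#' @param by character vector of grouping columns.
#' @return data.frame with grouping columns plus `mean`, `sem`
#'   (NA-flagged for single-observation cells), and `n`.
#' @export
summarize_mean_sem <- function(table, value, by) {
  stopifnot(value %in% names(table), all(by %in% names(table)))
  groups <- split(table, table[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(d) {
    v <- d[[value]][!is.na(d[[value]])]
    n <- length(v)
    cbind(d[1, by, drop = FALSE],
          data.frame(mean = mean(v),
                     sem = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
                     n = n))
  }))
  rownames(out) <- NULL
  out
}

#' Per-timepoint allocation tests
#'
#' The headline contrast of the experiment: for each injection color,
#' compare the per-plate young/established allocation ratio between the
#' control and low-P treatments with a two-sample Student's t test on the
#' square-root-transformed ratios. The three tests are reported
#' uncorrected (as in the underlying analysis), alongside a clearly
#' labeled Bonferroni-adjusted column.
#'
#' @param table experiment table (see [allocation_ratio()]).
#' @param equal_variance passed to [ttest_two_sample()].
#' @param transform `"sqrt"` (default), `"log"`, or `"none"`.
#' @return data.frame: `color`, `injection_age_days`, `t_statistic`,
#'   `p_value`, `p_bonferroni`, `n_control`, `n_lowp`,
#'   `transform_applied`.
#' @export
allocation_tests <- function(table, equal_variance = TRUE,
                             transform = c("sqrt", "log", "none")) {
  transform <- match.arg(transform)
  ratios <- allocation_ratio(table)
  colors <- unique(ratios[, c("color", "injection_age_days")])
  rows <- lapply(seq_len(nrow(colors)), function(i) {
    d <- ratios[ratios$color == colors$color[i], ]
    a <- d$ratio[d$treatment == "control"]
    b <- d$ratio[d$treatment == "low-P"]
    if (transform != "none") {
      a <- as.numeric(transform_values(a, transform))
      b <- as.numeric(transform_values(b, transform))
    }
    tt <- ttest_two_sample(a, b, equal_variance = equal_variance,
                           variable = paste0("ratio_", colors$color[i]),
                           grouping = "treatment")
    data.frame(color = colors$color[i],
               injection_age_days = colors$injection_age_days[i],
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               n_control = tt$n_per_group[1], n_lowp = tt$n_per_group[2],
               transform_applied = transform, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  out
}
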