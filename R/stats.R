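#' Normality flag for a cohort variable
#'
#' Shapiro-Wilk at alpha = 0.05 over the pooled values. Degenerate
#' (constant) vectors are flagged non-normal so downstream summaries fall
#' back to median (IQR).
#'
#' @param values numeric vector, n >= 3.
#' @param alpha test level (default 0.05).
#' @return `"normal"` or `"non-normal"`.
#' @export
normality_flag <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (sd(values) == 0) return("non-normal")
  n <- length(values)
  if (n > 5000) values <- values[round(seq(1, n, length.out = 5000))]
  p <- shapiro.test(values)$p.value
  if (p < alpha) "non-normal" else "normal"
}

group_summaries <- function(values, group, flag) {
  split_vals <- split(values, group, drop = FALSE)
  vapply(split_vals, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_character_)
    if (flag == "normal")
      sprintf("%.3g ± %.2g", mean(v), sd(v))
    else
      sprintf("%.3g (%.2g)", median(v), IQR(v))
  }, character(1))
}

#' Compare a metric across AF groups
#'
#' One-way ANOVA when the variable is flagged normal; Kruskal-Wallis
#' otherwise, with the independent-samples median test reported alongside.
#' Group summaries follow the presentation rule: mean ± SD for normal
#' variables, median (IQR) for non-normal ones. Significance at p < 0.05.
#'
#' @param cohort data frame with a `group` factor and the metric column.
#' @param variable column name.
#' @param normality `"auto"` (Shapiro-Wilk, default), `"normal"` or
#'   `"non-normal"`.
#' @return An object of class `la_test_result`.
#' @export
compare_groups <- function(cohort, variable, normality = "auto") {
  values <- cohort[[variable]]
  if (is.null(values)) stop("no column `", variable, "` in cohort", call. = FALSE)
  group <- droplevels(factor(cohort$group))
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  flag <- if (normality == "auto") normality_flag(values) else normality
  n_per <- table(group)
  extra <- NULL
  if (flag == "normal" && all(n_per >= 2)) {
    fit <- aov(values ~ group)
    tab <- summary(fit)[[1]]
    res <- list(test = "one-way ANOVA", statistic = tab$`F value`[1],
                p_value = tab$`Pr(>F)`[1])
  } else {
    if (flag == "normal")
      warning("a group has n < 2; falling back to Kruskal-Wallis")
    kw <- kruskal.test(values, group)
    res <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                p_value = kw$p.value)
    extra <- median_test(values, group)
  }
  structure(list(variable = variable, test = res$test,
                 statistic = res$statistic, p_value = res$p_value,
                 normality = flag,
                 summaries = group_summaries(values, group, flag),
                 n_per_group = as.integer(n_per),
                 median_test = extra),
            class = "la_test_result")
}

# Independent-samples median test: chi-square on counts above vs at-or-below
# the pooled median (no base-R implementation exists).
median_test <- function(values, group) {
  med <- median(values)
  above <- values > med
  tab <- table(group, factor(above, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(test = "median test", statistic = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(test = "median test", statistic = unname(ct$statistic),
       p_value = ct$p.value)
}

#' @export
print.la_test_result <- function(x, ...) {
  cat("<", x$test, "> ", x$variable, ": p = ", format.pval(x$p_value, digits = 3),
      " (", x$normality, ")\n", sep = "")
  s <- x$summaries
  for (g in names(s)) cat("  ", g, ": ", s[[g]], "\n", sep = "")
  if (!is.null(x$median_test) && is.finite(x$median_test$p_value))
    cat("  median test p = ", format.pval(x$median_test$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Paired test: overlap area vs total fibrosis area
#'
#' Wilcoxon signed-rank on per-subject differences (overlap − fibrosis).
#' Because overlap voxels are a subset of fibrotic voxels, differences are
#' non-positive by construction; the test quantifies how decisively the
#' overlap is smaller. Exact null distribution for n <= 25 without ties,
#' normal approximation with continuity correction above.
#'
#' @param cohort data frame of subject records.
#' @param method fibrosis method suffix (`"mvsi"`, `"iir12"`, `"iir132"`).
#' @param what `"area"` (cm^2, default) or `"pct"`.
#' @return An `la_test_result`; degenerate when all differences are zero.
#' @export
paired_overlap_vs_fibrosis <- function(cohort, method = "mvsi", what = "area") {
  stem <- if (what == "area") "_area_cm2_" else "_pct_"
  ov <- cohort[[paste0("overlap", stem, method)]]
  fb <- cohort[[paste0("fibrosis", stem, method)]]
  if (is.null(ov) || is.null(fb))
    stop("cohort lacks overlap/fibrosis columns for method `", method, "`",
         call. = FALSE)
  d <- ov - fb
  if (all(d == 0)) {
    return(structure(list(variable = paste0("overlap vs fibrosis (", method, ")"),
                          test = "Wilcoxon signed rank", statistic = NA_real_,
                          p_value = NA_real_, degenerate = TRUE,
                          n = length(d)),
                     class = "la_test_result"))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(wilcox.test(ov, fb, paired = TRUE, exact = exact,
                                     correct = TRUE))
  structure(list(variable = paste0("overlap vs fibrosis (", method, ")"),
                 test = "Wilcoxon signed rank",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 degenerate = FALSE, n = length(d),
                 summaries = c(overlap = sprintf("median %.3g", median(ov)),
                               fibrosis = sprintf("median %.3g", median(fb)))),
            class = "la_test_result")
}

#' Ordinal (proportional-odds) regression of AF type on one predictor
#'
#' Cumulative-logit model over the ordered AF stages, fitted by maximum
#' likelihood; reports the odds ratio per unit predictor with Wald 95% CI
#' and p-value. By default only the three AF groups (paroxysmal <
#' persistent < permanent) enter, matching the staging question; the
#' non-AF group can be included via `include_non_af`.
#'
#' @param cohort data frame with ordered `group` and the predictor column.
#' @param predictor column name.
#' @param include_non_af include the non-AF level (default `FALSE`).
#' @return An object of class `la_regression_result`.
#' @export
ordinal_af_regression <- function(cohort, predictor, include_non_af = FALSE) {
  dat <- cohort
  if (!include_non_af) dat <- dat[dat$group != "non-AF", , drop = FALSE]
  dat <- dat[is.finite(dat[[predictor]]) & !is.na(dat$group), , drop = FALSE]
  dat$group <- droplevels(dat$group)
  if (nlevels(dat$group) < 2)
    stop("outcome must have >= 2 observed AF levels", call. = FALSE)
  x <- dat[[predictor]]
  if (sd(x) == 0) {
    return(structure(list(model = "ordinal", predictor = predictor,
                          or = 1, ci = c(NA_real_, NA_real_), p_value = NA_real_,
                          slope = 0, se = NA_real_, n = nrow(dat),
                          flag = "constant predictor"),
                     class = "la_regression_result"))
  }
  fit <- MASS::polr(group ~ x, data = data.frame(group = dat$group, x = x),
                    Hess = TRUE, method = "logistic")
  ct <- coef(summary(fit))
  beta <- ct["x", "Value"]; se <- ct["x", "Std. Error"]
  flag <- NULL
  if (!is.finite(se) || se > 50) flag <- "possible complete separation; CI unbounded"
  p <- 2 * pnorm(-abs(beta / se))
  structure(list(model = "ordinal", predictor = predictor,
                 or = exp(beta),
                 ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
                 p_value = p, slope = beta, se = se, n = nrow(dat),
                 flag = flag),
            class = "la_regression_result")
}

#' Logistic regression against an LVEF median split
#'
#' Splits the AF patients at the cohort median LVEF (the median value
#' itself goes to the lower class), then fits a single-predictor logistic
#' regression of the split on the given metric; reports OR, Wald 95% CI
#' and p.
#'
#' @param cohort data frame with `lvef_pct` and the predictor column; only
#'   AF subjects (group != non-AF) enter when a `group` column is present.
#' @param predictor column name.
#' @return An object of class `la_regression_result` (also records the
#'   median used for the split).
#' @export
lvef_split_logistic <- function(cohort, predictor) {
  dat <- cohort
  if (!is.null(dat$group)) dat <- dat[dat$group != "non-AF", , drop = FALSE]
  dat <- dat[is.finite(dat$lvef_pct) & is.finite(dat[[predictor]]), , drop = FALSE]
  if (!nrow(dat)) stop("LVEF missing for all AF subjects", call. = FALSE)
  med <- median(dat$lvef_pct)
  y <- dat$lvef_pct > med   # median itself goes to the lower class
  if (length(unique(y)) < 2)
    stop("LVEF median split is degenerate (one outcome class empty)", call. = FALSE)
  x <- dat[[predictor]]
  fit <- glm(y ~ x, family = binomial())
  sm <- summary(fit)$coefficients
  beta <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  flag <- if (!is.finite(se) || se > 50) "possible complete separation" else NULL
  structure(list(model = "binary", predictor = predictor,
                 or = exp(beta),
                 ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
                 p_value = sm["x", "Pr(>|z|)"], slope = beta, se = se,
                 n = nrow(dat), lvef_median = med, flag = flag),
            class = "la_regression_result")
}

#' @export
print.la_regression_result <- function(x, ...) {
  cat("<", if (x$model == "ordinal") "ordinal logistic" else "logistic",
      "> ", x$predictor, ": OR = ", format(x$or, digits = 4),
      " 95%CI [", format(x$ci[1], digits = 3), ", ",
      format(x$ci[2], digits = 3), "], p = ",
      format.pval(x$p_value, digits = 3), " (n = ", x$n, ")\n", sep = "")
  if (!is.null(x$flag)) cat("  note: ", x$flag, "\n", sep = "")
  invisible(x)
}
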