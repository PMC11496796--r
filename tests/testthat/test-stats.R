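null_cohort <- function(n = c(9, 18, 10, 14), seed = 1) {
  set.seed(seed)
  data.frame(group = factor(rep(c("non-AF", "paroxysmal", "persistent", "permanent"), n),
                            levels = c("non-AF", "paroxysmal", "persistent", "permanent"),
                            ordered = TRUE),
             x = rnorm(sum(n)))
}

test_that("normality flag has the right level and power", {
  set.seed(1)
  flags_norm <- replicate(40, normality_flag(rnorm(500)))
  expect_gte(mean(flags_norm == "normal"), 0.9)
  flags_skew <- replicate(40, normality_flag(exp(rnorm(500, 0, 1.5))))
  expect_identical(unique(flags_skew), "non-normal")
  expect_identical(normality_flag(rep(3, 10)), "non-normal")
  expect_error(normality_flag(c(1, 2)), "at least 3")
})

test_that("compare_groups picks the test by normality and reports summaries", {
  co <- null_cohort(seed = 2)
  tr <- compare_groups(co, "x", normality = "normal")
  expect_identical(tr$test, "one-way ANOVA")
  expect_match(tr$summaries[["paroxysmal"]], "±")
  tr2 <- compare_groups(co, "x", normality = "non-normal")
  expect_identical(tr2$test, "Kruskal-Wallis")
  expect_match(tr2$summaries[["permanent"]], "\\(")
  expect_false(is.null(tr2$median_test))
  expect_true(tr2$p_value >= 0 && tr2$p_value <= 1)
  expect_error(compare_groups(data.frame(group = factor("a"), x = 1), "x"),
               "2 non-empty groups")
})

test_that("group-comparison type-I error is near the nominal 5% level", {
  set.seed(42)
  rej <- mean(replicate(600, {
    co <- null_cohort(seed = sample.int(1e8, 1))
    compare_groups(co, "x", normality = "non-normal")$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("a designed EAT-like group shift is detected with good power", {
  set.seed(7)
  shift <- c(0, 0, 0.8, 1.5)  # extreme-group separation ~1.5 SD
  rej <- mean(replicate(120, {
    co <- null_cohort(seed = sample.int(1e8, 1))
    co$x <- co$x + shift[as.integer(co$group)]
    compare_groups(co, "x", normality = "non-normal")$p_value < 0.05
  }))
  expect_gte(rej, 0.8)
})

test_that("paired overlap-vs-fibrosis test is decisive when overlap is a proper subset", {
  n <- 51
  set.seed(3)
  fib <- runif(n, 2, 15)
  co <- data.frame(overlap_area_cm2_mvsi = fib * runif(n, 0.05, 0.4),
                   fibrosis_area_cm2_mvsi = fib)
  tr <- paired_overlap_vs_fibrosis(co, "mvsi")
  expect_lt(tr$p_value, 0.001)
  codeg <- data.frame(overlap_area_cm2_mvsi = fib, fibrosis_area_cm2_mvsi = fib)
  trdeg <- paired_overlap_vs_fibrosis(codeg, "mvsi")
  expect_true(trdeg$degenerate)
  expect_true(is.na(trdeg$p_value))
})

test_that("ordinal regression recovers a known proportional-odds slope", {
  set.seed(11)
  ors <- replicate(150, {
    x <- rnorm(42, 0, 5)
    latent <- log(1.28) * x + rlogis(42)
    cuts <- quantile(latent, c(18, 28) / 42)
    g <- cut(latent, c(-Inf, cuts, Inf),
             labels = c("paroxysmal", "persistent", "permanent"),
             ordered_result = TRUE)
    co <- data.frame(group = g, x = x)
    tryCatch(ordinal_af_regression(co, "x")$or, error = function(e) NA)
  })
  expect_gte(median(ors, na.rm = TRUE), 1.15)
  expect_lte(median(ors, na.rm = TRUE), 1.42)
})

test_that("ordinal regression handles null and degenerate predictors", {
  set.seed(5)
  co <- null_cohort(seed = 5)
  rr <- ordinal_af_regression(co, "x")  # non-AF dropped by default
  expect_identical(rr$n, 42L)
  expect_true(rr$ci[1] <= rr$or && rr$or <= rr$ci[2])
  co$x <- 1
  rc <- ordinal_af_regression(co, "x")
  expect_identical(rc$or, 1)
  expect_identical(rc$flag, "constant predictor")
})

test_that("logistic and ordinal Wald CIs cover known slopes at ~95%", {
  set.seed(13)
  beta <- 0.8
  n <- 400
  covered <- mean(replicate(200, {
    x <- rnorm(n)
    y <- runif(n) < plogis(beta * x)
    # separate LVEF clusters so the median split reproduces y (at most one
    # boundary subject flips class)
    co <- data.frame(lvef_pct = ifelse(y, 60, 50) + rnorm(n, 0, 0.1), x = x)
    rr <- suppressWarnings(lvef_split_logistic(co, "x"))
    rr$ci[1] <= exp(beta) && exp(beta) <= rr$ci[2]
  }))
  expect_gte(covered, 0.92)
  expect_lte(covered, 0.98)

  bo <- log(1.3)
  covered_ord <- mean(replicate(150, {
    x <- rnorm(200, 0, 2)
    latent <- bo * x + rlogis(200)
    g <- cut(latent, c(-Inf, quantile(latent, c(0.4, 0.7)), Inf),
             labels = c("paroxysmal", "persistent", "permanent"),
             ordered_result = TRUE)
    rr <- ordinal_af_regression(data.frame(group = g, x = x), "x")
    rr$ci[1] <= exp(bo) && exp(bo) <= rr$ci[2]
  }))
  expect_gte(covered_ord, 0.92)
  expect_lte(covered_ord, 0.98)
})

test_that("LVEF median split puts the median in the lower class and flags degeneracy", {
  co <- data.frame(lvef_pct = c(50, 55, 57, 57, 60, 65),
                   x = c(1, 2, 3, 4, 5, 6))
  # n = 6 with a monotone predictor separates perfectly; that is the point
  # of the flag, so the fit warning is expected
  rr <- suppressWarnings(lvef_split_logistic(co, "x"))
  expect_identical(rr$lvef_median, 57)
  expect_identical(rr$n, 6L)
  same <- data.frame(lvef_pct = rep(57, 6), x = 1:6)
  expect_error(lvef_split_logistic(same, "x"), "degenerate")
})
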