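test_that("two timepoints force epsilon = 1 and uncorrected p", {
  set.seed(1)
  Y <- matrix(rnorm(12), 6, 2)
  a <- rm_anova_gg(tbl_from_wide(Y), "m")
  expect_equal(a$epsilon, 1)
  expect_equal(a$p_gg, a$p_uncorrected)
})

test_that("RM-ANOVA F and GG epsilon match an independent implementation", {
  skip_if_not_installed("car")
  set.seed(2)
  n <- 8
  k <- 5
  Y <- matrix(rnorm(n * k), n, k) + rnorm(n) +
    outer(rep(1, n), c(0, 0.5, 0.2, 0.8, 0.1))
  a <- rm_anova_gg(tbl_from_wide(Y), "m")
  mlm <- stats::lm(Y ~ 1)
  av <- car::Anova(mlm, idata = data.frame(time = factor(1:k)),
                   idesign = ~time, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  expect_equal(a$statistic,
               s$univariate.tests["time", "F value"], tolerance = 1e-8)
  expect_equal(a$p_uncorrected,
               s$univariate.tests["time", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(a$epsilon,
               unname(s$pval.adjustments["time", "GG eps"]), tolerance = 1e-8)
  expect_equal(a$p_gg,
               unname(s$pval.adjustments["time", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("a strongly shifted timepoint is detected (p_gg < 0.001)", {
  set.seed(3)
  n <- 6
  k <- 8
  Y <- matrix(rnorm(n * k, sd = 0.1), n, k) + rnorm(n, sd = 1)
  Y[, 4] <- Y[, 4] + 10
  a <- rm_anova_gg(tbl_from_wide(Y), "m")
  expect_lt(a$p_gg, 0.001)
  td <- tidy(a)
  expect_equal(td$statistic, a$statistic)
  expect_true(all(c("epsilon", "p.value.gg") %in% names(td)))
})

test_that("epsilon respects its theoretical bounds and GG never lowers p", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    k <- sample(3:6, 1)
    Y <- matrix(rnorm(n * k), n, k)
    a <- rm_anova_gg(tbl_from_wide(Y), "m")
    expect_gte(a$epsilon, 1 / (k - 1))
    expect_lte(a$epsilon, 1)
    # shrinking both dfs is conservative in the rejection region; for
    # unremarkable F near or below 1 the inequality can genuinely invert
    if (a$epsilon < 1 && a$p_uncorrected <= 0.10) {
      expect_gte(a$p_gg, a$p_uncorrected - 1e-12)
    }
  }
})

test_that("input validation: small designs and incomplete units", {
  set.seed(5)
  Y <- matrix(rnorm(4), 2, 2)
  expect_error(rm_anova_gg(tbl_from_wide(Y), "m"), class = "octapipe_data_error")
  tbl <- tbl_from_wide(matrix(rnorm(24), 6, 4))
  tbl2 <- tbl[-1, ]  # subject 1 missing a timepoint
  expect_warning(a <- rm_anova_gg(tbl2, "m"), "dropped")
  expect_equal(a$n_units, 5)
})

test_that("Tukey with two timepoints reduces to the single pairwise test", {
  set.seed(6)
  Y <- matrix(rnorm(12), 6, 2)
  tk <- tukey_posthoc(tbl_from_wide(Y), "m")
  expect_equal(nrow(tk), 1)
  a <- rm_anova_gg(tbl_from_wide(Y), "m")
  # with k = 2 the Tukey-adjusted p equals the RM-ANOVA p
  expect_equal(tk$p.adj, a$p_uncorrected, tolerance = 1e-8)
})

test_that("Tukey finds no pairs on near-constant data, all pairs for a shift", {
  set.seed(7)
  Y0 <- matrix(5 + rnorm(24, sd = 1e-3), 6, 4)
  tk0 <- tukey_posthoc(tbl_from_wide(Y0), "m")
  expect_true(all(tk0$p.adj > 0.05))
  expect_true(all(tk0$stars == ""))
  Y1 <- matrix(rnorm(24, sd = 0.1), 6, 4)
  Y1[, 3] <- Y1[, 3] + 50
  tk1 <- tukey_posthoc(tbl_from_wide(Y1), "m")
  has3 <- grepl("(^|-)3($|-)", tk1$pair)
  expect_true(all(tk1$p.adj[has3] < 0.001))
  expect_true(all(tk1$p.adj[!has3] > 0.05))
})

test_that("linear trends recover exact lines and validate inputs", {
  d <- tibble::tibble(subject = 1, eye = 1, plexus = "deep", metric = "m",
                      timepoint_weeks = c(1, 2, 3, 4), value = 2 * c(1, 2, 3, 4))
  tr <- suppressWarnings(linear_trend(d, "m"))
  expect_equal(tr$slope, 2)
  expect_equal(tr$r.squared, 1)
  d2 <- d[d$timepoint_weeks < 3, ]
  expect_error(linear_trend(d2, "m"), class = "octapipe_data_error")
})

test_that("slope sign is recovered under arbitrary scaling", {
  set.seed(8)
  for (scale in c(1e-6, 1, 1e6)) {
    d <- tibble::tibble(subject = 1, eye = 1, plexus = "deep", metric = "m",
                        timepoint_weeks = 1:8,
                        value = scale * (10 - 1:8))
    expect_lt(suppressWarnings(linear_trend(d, "m"))$slope, 0)
  }
})

test_that("averaging eyes halves the unit count", {
  set.seed(9)
  tbl <- tidyr::expand_grid(subject = 1:4, eye = 1:2, timepoint_weeks = 1:3)
  tbl$plexus <- "deep"
  tbl$metric <- "m"
  tbl$value <- rnorm(nrow(tbl))
  a2 <- rm_anova_gg(tbl, "m", average_eyes = FALSE)
  a1 <- rm_anova_gg(tbl, "m", average_eyes = TRUE)
  expect_equal(a2$n_units, 8)
  expect_equal(a1$n_units, 4)
})
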