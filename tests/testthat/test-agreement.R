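# Paired agreement battery, ICC(2,1), reliability bands, and the
# region-wise reproducibility table.

test_that("identical measurements give the degenerate perfect report", {
  x <- c(3, 7, 1, 9, 4, 6, 2, 8, 5, 10)
  g <- glance(paired_agreement(data.frame(a = x, b = x), a, b))
  expect_equal(g$slope, 1)
  expect_equal(g$intercept, 0)
  expect_equal(g$pearson_r, 1)
  expect_equal(g$ccc, 1)
  expect_equal(g$rmse, 0)
  expect_equal(g$p_value, 1) # zero differences: t = 0
  expect_equal(c(g$ba_mean_diff, g$ba_lower, g$ba_upper), c(0, 0, 0))
  expect_equal(c(g$pctdiff_mean, g$pctdiff_sd), c(0, 0))
})

test_that("a constant shift degrades CCC but not r, with closed-form CCC", {
  x <- c(12, 15, 11, 19, 14, 16, 13, 18, 17, 20)
  cshift <- 3
  g <- glance(paired_agreement(data.frame(a = x, b = x + cshift), a, b))
  expect_equal(g$pearson_r, 1)
  sx2 <- var(x)
  expect_equal(g$ccc, 2 * sx2 / (2 * sx2 + cshift^2)) # independent formula
  expect_lt(g$ccc, 1)
  expect_equal(g$ba_mean_diff, -cshift)
  expect_equal(g$ba_upper - g$ba_lower, 0) # constant differences
  expect_equal(g$p_value, 0)
})

test_that("every statistic matches the spreadsheet oracle on a hand table", {
  x <- c(81.4, 197.1, 71.4, 54.2, 216.0, 40.5)
  y <- c(80.3, 200.3, 71.0, 55.6, 217.1, 42.6)
  g <- glance(paired_agreement(data.frame(x = x, y = y), x, y))
  o <- oracle_agreement(x, y)
  expect_equal(g$slope, o$slope, tolerance = 1e-10)
  expect_equal(g$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(g$pearson_r, o$r, tolerance = 1e-10)
  expect_equal(g$ccc, o$ccc, tolerance = 1e-10)
  expect_equal(g$p_value, o$p_value, tolerance = 1e-10)
  expect_equal(g$rmse, o$rmse, tolerance = 1e-10)
  expect_equal(g$nrmse_pct, o$nrmse_pct, tolerance = 1e-10)
  expect_equal(g$ba_mean_diff, o$ba_mean, tolerance = 1e-10)
  expect_equal(g$ba_lower, o$ba_lower, tolerance = 1e-10)
  expect_equal(g$ba_upper, o$ba_upper, tolerance = 1e-10)
  expect_equal(g$pctdiff_mean, o$pct_mean, tolerance = 1e-10)
  expect_equal(g$pctdiff_sd, o$pct_sd, tolerance = 1e-10)
})

test_that("agreement statistics match the oracle on random inputs", {
  withr::local_seed(31)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    x <- runif(n, 50, 150)
    y <- x * runif(1, 0.8, 1.2) + rnorm(n, 0, 5) + runif(1, -10, 10)
    g <- glance(paired_agreement(data.frame(x = x, y = y), x, y))
    o <- oracle_agreement(x, y)
    expect_equal(g$slope, o$slope, tolerance = 1e-10)
    expect_equal(g$ccc, o$ccc, tolerance = 1e-10)
    expect_equal(g$rmse, o$rmse, tolerance = 1e-10)
    expect_equal(g$p_value, o$p_value, tolerance = 1e-10)
    expect_equal(g$ba_lower, o$ba_lower, tolerance = 1e-10)
    expect_equal(g$pctdiff_sd, o$pct_sd, tolerance = 1e-10)
    # structural invariants
    expect_lte(abs(g$ccc), abs(g$pearson_r) + 1e-12)
    expect_gte(g$rmse, 0)
    expect_gte(g$ba_upper, g$ba_lower)
  }
})

test_that("swapping the measurements mirrors the report correctly", {
  withr::local_seed(8)
  x <- runif(12, 80, 120)
  y <- x + rnorm(12, 2, 4)
  g1 <- glance(paired_agreement(data.frame(x = x, y = y), x, y))
  g2 <- glance(paired_agreement(data.frame(x = x, y = y), y, x))
  expect_equal(g2$pearson_r, g1$pearson_r)
  expect_equal(g2$ccc, g1$ccc)
  expect_equal(g2$rmse, g1$rmse)
  expect_equal(g2$ba_mean_diff, -g1$ba_mean_diff)
  expect_equal(g2$pctdiff_mean, g1$pctdiff_mean)
  expect_equal(g2$p_value, g1$p_value, tolerance = 1e-12)
})

test_that("degenerate paired inputs are rejected with clear messages", {
  expect_error(paired_agreement(data.frame(x = c(1, 1, 1), y = c(1, 2, 3)),
                                x, y), "constant")
  expect_error(paired_agreement(data.frame(x = c(1, 2), y = c(1, 2)), x, y),
               "n >= 3")
  expect_error(paired_agreement(data.frame(x = c(-4, 2, 3), y = c(4, 2, 3)),
                                x, y), "nonpositive")
})

test_that("Bland-Altman limits cover about 95 percent of Gaussian differences", {
  withr::local_seed(5)
  n <- 10000
  x <- rnorm(n, 100, 10)
  y <- x + rnorm(n, 0, 3)
  g <- glance(paired_agreement(data.frame(x = x, y = y), x, y))
  d <- x - y
  cover <- mean(d >= g$ba_lower & d <= g$ba_upper)
  expect_gt(cover, 0.945) # binomial tolerance at n = 1e4
  expect_lt(cover, 0.955)
})

test_that("ICC(2,1) handles the textbook extremes", {
  subj <- c(10, 14, 18, 25, 31)
  perfect <- cbind(subj, subj, subj)
  expect_equal(icc_2_1(perfect)$icc, 1)
  no_subject_var <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_lte(icc_2_1(no_subject_var)$icc, 0)
  expect_error(icc_2_1(matrix(5, 3, 3)), "constant")
})

test_that("ICC(2,1) matches the aov oracle on random matrices", {
  withr::local_seed(12)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 100, 20), n, k) +
      outer(rnorm(n, 0, 15), rep(1, k)) + # subject effects
      outer(rep(1, n), rnorm(k, 0, 5))    # rater effects
    got <- icc_2_1(m)
    expect_equal(got$icc, oracle_icc21(m), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(is.finite(got$lower) && is.finite(got$upper))
    expect_lte(got$lower, got$icc + 1e-9)
    expect_gte(got$upper + 1e-9, got$icc)
  }
})

test_that("reliability bands follow the published cut points", {
  expect_identical(classify_reliability(c(0.49, 0.499999)),
                   c("poor", "poor"))
  expect_identical(classify_reliability(c(0.50, 0.6, 0.75)),
                   c("moderate", "moderate", "moderate"))
  expect_identical(classify_reliability(c(0.7500001, 0.9)),
                   c("good", "good"))
  expect_identical(classify_reliability(c(0.9000001, 0.99, 1)),
                   c("excellent", "excellent", "excellent"))
  expect_error(classify_reliability(1.2), "exceed")
})

test_that("reproducibility tables pool all lobes and flag incomplete pairs", {
  withr::local_seed(20)
  pairs <- lapply(1:5, function(p) {
    base <- c(80, 200, 70, 55, 215, 40) * runif(1, 0.9, 1.1)
    m <- function(noise) {
      v <- c(base + rnorm(6, 0, noise))
      tibble::tibble(region = c(lobe_regions(), "GLOBAL"),
                     mass_g = c(v, sum(v)),
                     volume_ml = c(v, sum(v)) * 2)
    }
    list(m1 = m(2), m2 = m(2))
  })
  long <- stack_measurement_pairs(pairs, "mass_g")
  tab <- reproducibility_table(long)
  expect_identical(tab$region[1:2], c("GLOBAL", "LOBAR"))
  expect_identical(tab$n[tab$region == "LOBAR"], 30L) # 6 lobes x 5 pairs
  expect_identical(tab$n[tab$region == "LUL"], 5L)
  # a duplicated pair (x = y) keeps the table computable
  dup <- lapply(1:4, function(p) {
    vals <- c(80, 200, 70, 55, 215, 40) * (1 + p / 10)
    v <- tibble::tibble(region = c(lobe_regions(), "GLOBAL"),
                        mass_g = c(vals, sum(vals)))
    list(m1 = v, m2 = v) # second acquisition identical to the first
  })
  tab2 <- reproducibility_table(stack_measurement_pairs(dup, "mass_g"))
  expect_true(all(tab2$p_value == 1))
  incomplete <- dplyr::filter(long, !(pair_id == 2 & acquisition == 2 &
                                        region == "RML"))
  expect_error(reproducibility_table(incomplete), "incomplete")
})

test_that("autoplot produces both Bland-Altman and regression panels", {
  x <- c(10, 12, 14, 15, 18, 21)
  pa <- paired_agreement(data.frame(a = x, b = x + rnorm(6, 0, 1)), a, b)
  expect_s3_class(autoplot(pa), "ggplot")
  expect_s3_class(autoplot(pa, type = "regression"), "ggplot")
  expect_output(print(pa), "Bland-Altman")
})
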