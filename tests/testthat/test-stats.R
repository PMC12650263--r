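# Outlier filter, permutation Spearman machinery, Mann-Whitney, OLS report.

test_that("outlier filter reproduces the hand-computed cases", {
  t1 <- data.frame(v = c(rep(0, 9), 100))
  f1 <- filter_outliers(t1)
  expect_equal(nrow(f1$table), 9)
  expect_equal(f1$excluded$value, 100)
  # sample SD: mean 10, sd = sqrt((9*100 + 8100)/9) = 31.62; upper ~ 73.2
  expect_equal(f1$bounds$upper, 10 + 2 * sd(t1$v), tolerance = 1e-12)

  f2 <- filter_outliers(data.frame(v = 1:5))
  expect_equal(nrow(f2$table), 5)
  expect_equal(f2$bounds$lower, 3 - 2 * sd(1:5))

  f3 <- filter_outliers(data.frame(v = rep(7, 6)))
  expect_equal(nrow(f3$table), 6)  # inclusive bounds keep equal values

  expect_error(filter_outliers(data.frame(v = 1:2)), ">= 3")
  expect_error(filter_outliers(data.frame(v = 1:5), k = 0), "> 0")
})

test_that("outlier filtering is listwise and idempotent on its own output", {
  set.seed(31)
  t <- data.frame(participant_id = letters[1:10],
                  a = c(rep(1, 9), 50), b = rnorm(10))
  f <- filter_outliers(t)
  expect_false("j" %in% f$table$participant_id)
  expect_equal(f$excluded$variable, "a")
  # every surviving value is inside the original bounds
  for (j in seq_len(nrow(f$bounds))) {
    v <- f$table[[f$bounds$variable[j]]]
    expect_true(all(v >= f$bounds$lower[j] & v <= f$bounds$upper[j]))
  }
  # refiltering the hand cases excludes nothing further
  f2 <- filter_outliers(f$table)
  expect_equal(nrow(f2$table), nrow(f$table))
})

test_that("spearman_rho matches the hand mid-rank case and base R", {
  expect_equal(spearman_rho(1:3, 1:3), 1.0)
  expect_equal(spearman_rho(1:3, 3:1), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 0.9486833,
               tolerance = 1e-6)
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(15); y <- sample(1:5, 15, replace = TRUE)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_warning(expect_true(is.na(spearman_rho(rep(1, 5), 1:5))), "rank variance")
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
})

test_that("sampled permutation p matches full enumeration on a tiny case", {
  tab <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3))
  p_enum <- enumerate_spearman_p(tab$x, tab$y)
  expect_equal(p_enum, 2 / 6)
  res <- permutation_correlation_matrix(tab, n_perm = 2000, seed = 7)
  se <- sqrt(p_enum * (1 - p_enum) / 2000)
  expect_lt(abs(res$p_empirical["x", "y"] - p_enum), 3 * se)
  expect_equal(res$rho["x", "y"], 1.0)
})

test_that("permutation matrix is deterministic, symmetric and masked at alpha", {
  set.seed(33)
  tab <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  r1 <- permutation_correlation_matrix(tab, n_perm = 300, seed = 5)
  r2 <- permutation_correlation_matrix(tab, n_perm = 300, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$rho, t(r1$rho))
  expect_equal(r1$p_empirical, t(r1$p_empirical))
  expect_equal(diag(r1$rho), setNames(rep(1, 3), names(tab)))
  expect_identical(unname(r1$mask), unname(!is.na(r1$p_empirical) &
                                             r1$p_empirical < r1$alpha))
  r3 <- permutation_correlation_matrix(tab, n_perm = 300, seed = 6)
  expect_false(identical(r1$p_empirical, r3$p_empirical))
})

test_that("permutation inference is invariant under strictly monotone transforms", {
  set.seed(9)
  tab <- data.frame(x = rnorm(24), y = rnorm(24))
  base <- permutation_correlation_matrix(tab, n_perm = 500, seed = 2)
  warped <- data.frame(x = exp(tab$x), y = tab$y^3)
  same <- permutation_correlation_matrix(warped, n_perm = 500, seed = 2)
  expect_equal(base$rho, same$rho, tolerance = 1e-12)
  expect_equal(base$p_empirical, same$p_empirical, tolerance = 1e-12)
})

test_that("degenerate and missing-data cells are reported missing", {
  tab <- data.frame(x = rep(1, 10), y = rnorm(10),
                    z = c(rnorm(8), NA, NA))
  res <- permutation_correlation_matrix(tab, n_perm = 100, seed = 1)
  expect_true(is.na(res$rho["x", "y"]))
  expect_false(res$mask["x", "y"])
  expect_false(is.na(res$rho["y", "z"]))  # pairwise-complete on 8 cases
  short <- data.frame(x = c(1, 2, NA, NA, NA), y = c(2, 1, NA, NA, NA))
  res2 <- permutation_correlation_matrix(short, n_perm = 50, seed = 1)
  expect_true(is.na(res2$rho["x", "y"]))
})

test_that("smoothed p-values and BH adjustment behave as documented", {
  set.seed(4)
  tab <- data.frame(x = 1:15 + rnorm(15, 0, 0.1), y = 1:15 + rnorm(15, 0, 0.1))
  plain <- permutation_correlation_matrix(tab, n_perm = 200, seed = 3)
  expect_equal(plain$p_empirical["x", "y"], 0)  # extreme effect -> plain p can be 0
  smooth <- permutation_correlation_matrix(tab, n_perm = 200, seed = 3,
                                           smoothed = TRUE)
  expect_equal(smooth$p_empirical["x", "y"], 1 / 201)
  tab3 <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  bh <- permutation_correlation_matrix(tab3, n_perm = 100, seed = 3,
                                       p_adjust = "BH")
  raw <- permutation_correlation_matrix(tab3, n_perm = 100, seed = 3)
  expect_true(all(bh$p_empirical >= raw$p_empirical - 1e-12, na.rm = TRUE))
})

test_that("mann_whitney hand cases and oracle agreement", {
  m <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(m$U, 0)
  expect_equal(m$p_two_sided, 2 / 6, tolerance = 1e-12)
  expect_equal(m$method, "exact")

  balanced <- mann_whitney(c(1, 4), c(2, 3))
  expect_equal(balanced$U, 2)
  expect_equal(balanced$p_two_sided, 1.0)

  tied <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(tied$p_two_sided, 1.0)
  expect_equal(tied$method, "normal-approximation")

  expect_error(mann_whitney(numeric(0), 1:3), ">= 1")

  set.seed(21)
  for (i in 1:8) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(1:100, n1 + n2)  # no ties
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    expect_equal(mann_whitney(a, b)$p_two_sided, brute_force_mw_p(a, b),
                 tolerance = 1e-12)
    # U statistic agrees with base R's exact wilcox test statistic
    expect_equal(mann_whitney(a, b)$U, unname(wilcox.test(a, b)$statistic))
  }
})

test_that("large/tied samples fall back to the corrected normal approximation", {
  set.seed(12)
  a <- rnorm(25); b <- rnorm(25, 0.8)
  m <- mann_whitney(a, b)
  expect_equal(m$method, "normal-approximation")
  ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(m$p_two_sided, ref$p.value, tolerance = 1e-10)
  expect_true(m$U >= 0 && m$U <= 625)
})

test_that("ols_fit matches the spec hand cases exactly", {
  perfect <- suppressWarnings(ols_fit(c(0, 1, 2), c(1, 3, 5)))
  expect_equal(perfect$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-10)
  expect_true(all(abs(perfect$residuals) < 1e-10))

  hand <- suppressWarnings(ols_fit(c(0, 1, 2), c(0, 1, 1)))
  expect_equal(hand$coefficients$estimate[2], 0.5, tolerance = 1e-10)
  expect_equal(hand$coefficients$estimate[1], 1 / 6, tolerance = 1e-10)
  expect_equal(hand$r_squared, 0.75, tolerance = 1e-10)

  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3.0)
  expect_error(ols_fit(rep(2, 5), rnorm(5)), "constant predictor")
  expect_error(suppressWarnings(ols_fit(1:2, 1:2)), ">= 3")
})

test_that("the diagnostic suite matches frozen external-oracle values", {
  # statsmodels OLS on this fixture (computed once, frozen)
  x <- c(0.1, 0.9, 1.7, 2.2, 3.1, 3.8, 4.4, 5.0, 6.1, 6.9)
  y <- c(1.2, 1.9, 3.1, 3.0, 4.6, 4.2, 5.8, 5.5, 7.2, 7.1)
  r <- ols_fit(x, y)
  expect_equal(r$r_squared, 0.9617461745653006, tolerance = 1e-10)
  expect_equal(r$adj_r_squared, 0.9569644463859632, tolerance = 1e-10)
  expect_equal(r$f_statistic, 201.12941147954672, tolerance = 1e-8)
  expect_equal(r$aic, 13.225423930704025, tolerance = 1e-8)
  expect_equal(r$bic, 13.830594116692117, tolerance = 1e-8)
  expect_equal(r$coefficients$estimate, c(1.25120046, 0.90900571), tolerance = 1e-7)
  expect_equal(r$coefficients$std_error, c(0.25780494, 0.06409569), tolerance = 1e-7)
  expect_equal(r$coefficients$ci_lower, c(0.6567012, 0.76120079), tolerance = 1e-6)
  expect_equal(r$coefficients$ci_upper, c(1.84569972, 1.05681064), tolerance = 1e-6)
  expect_equal(r$durbin_watson, 3.5428233125139035, tolerance = 1e-10)
  expect_equal(r$condition_number, 7.989224685881705, tolerance = 1e-8)

  # scipy normaltest / jarque_bera / skew / kurtosis on this residual vector
  e <- c(0.12, -0.55, 0.33, -0.21, 0.47, -0.08, 0.91, -0.64,
         0.05, -0.37, 0.28, 1.42, -0.73, 0.16, -0.29, 0.61,
         -0.44, 0.09, -0.18, 0.52)
  z1 <- createlab:::dagostino_skew_z(e)
  z2 <- createlab:::anscombe_kurt_z(e)
  expect_equal(z1^2 + z2^2, 2.581176800343977, tolerance = 1e-10)
  expect_equal(pchisq(z1^2 + z2^2, 2, lower.tail = FALSE),
               0.2751088613556987, tolerance = 1e-10)
  m2 <- mean((e - mean(e))^2)
  skew <- mean((e - mean(e))^3) / m2^1.5
  kurt <- mean((e - mean(e))^4) / m2^2
  expect_equal(skew, 0.6517486854880635, tolerance = 1e-12)
  expect_equal(kurt, 3.1434699677447173, tolerance = 1e-12)
  expect_equal(length(e) / 6 * (skew^2 + (kurt - 3)^2 / 4),
               1.4330741898219543, tolerance = 1e-12)
})

test_that("regression invariants: R2 vs squared Pearson, CI brackets, dof", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    r <- suppressWarnings(ols_fit(x, y))
    expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-10)
    expect_lte(r$adj_r_squared, r$r_squared)
    expect_true(r$coefficients$ci_lower[2] <= r$coefficients$estimate[2] &&
                  r$coefficients$estimate[2] <= r$coefficients$ci_upper[2])
  }
})
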