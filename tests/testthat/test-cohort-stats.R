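test_that("Pearson correlation recovers exact linear relations with Fisher CI", {
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 1, z = -(1:20))
  expect_equal(pearson_with_ci(d, x, y)$estimate, 1)
  expect_equal(pearson_with_ci(d, x, z)$estimate, -1)

  set.seed(51)
  n <- 200
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = sqrt(1 - 0.25))
  res <- pearson_with_ci(data.frame(x = x, y = y), x, y)
  # cross-check the Fisher z-transform interval by hand
  z <- atanh(res$estimate)
  se <- 1 / sqrt(n - 3)
  expect_equal(res$conf_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(res$conf_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-9)
  # and the t-based p-value
  tstat <- res$estimate * sqrt((n - 2) / (1 - res$estimate^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-9)
})

test_that("the sampling distribution of r is centred on rho at the study size", {
  set.seed(52)
  rho <- 0.67
  n <- 36
  r <- replicate(2000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor(x, y)
  })
  expect_lt(abs(mean(r) - rho), 0.03)
})

test_that("correlation is affine invariant and rejects degenerate input", {
  set.seed(53)
  d <- data.frame(x = rnorm(30), y = rnorm(30))
  base <- pearson_with_ci(d, x, y)
  shifted <- data.frame(x = 3 * d$x + 7, y = 0.5 * d$y - 2)
  expect_equal(pearson_with_ci(shifted, x, y)$estimate, base$estimate, tolerance = 1e-12)
  expect_error(
    pearson_with_ci(data.frame(x = rep(1, 10), y = rnorm(10)), x, y),
    class = "focalindex_degenerate_error"
  )
  expect_error(
    pearson_with_ci(data.frame(x = 1:2, y = 2:1), x, y),
    class = "focalindex_input_error"
  )
  # spearman option works on ranks
  expect_equal(
    pearson_with_ci(data.frame(x = exp(1:10), y = (1:10)^3), x, y, method = "spearman")$estimate,
    1
  )
})

test_that("Cohen's kappa matches closed forms and is rater-symmetric", {
  expect_equal(cohen_kappa(c(10, 0, 0, 10))$kappa, 1)
  expect_equal(cohen_kappa(c(4, 4, 4, 4))$kappa, 0)

  # agreement table with an off-diagonal disagreement: kappa = 70/107
  k <- cohen_kappa(c(35, 1, 0, 1))
  expect_equal(k$kappa, 70 / 107, tolerance = 1e-12)
  expect_equal(k$p_observed, 36 / 37, tolerance = 1e-12)
  expect_equal(k$p_expected, 1262 / 1369, tolerance = 1e-12)
  expect_equal(round(k$kappa, 2), 0.65)
  expect_lte(k$conf_high, 1) # truncation

  # transposing the table (swapping raters) leaves kappa unchanged
  m <- matrix(c(35, 1, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(cohen_kappa(t(m))$kappa, cohen_kappa(m)$kappa)

  # independent cross-check of the point estimate
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(
      cohen_kappa(m)$kappa,
      e1071::classAgreement(m)$kappa,
      tolerance = 1e-12
    )
  }
  expect_error(
    cohen_kappa(c(10, 0, 0, 0)),
    class = "focalindex_degenerate_error"
  )
})

test_that("the sensitivity regression recovers exact coefficients and errors on collinearity", {
  d <- data.frame(
    peep_cmH2O = c(5, 8, 10, 12, 14, 16, 6, 9, 11, 13),
    rr_per_min = c(12, 14, 16, 18, 20, 22, 13, 15, 17, 19),
    vt_per_pbw_ml_kg = c(6, 6.5, 7, 7.5, 8, 8.5, 6.2, 6.8, 7.2, 7.8)
  )
  d$focal_index <- 3 * d$peep_cmH2O - 2 * d$rr_per_min + 5
  fit <- sensitivity_regression(d)
  co <- suppressWarnings(tidy(fit)) # exact fit: summary warns by design
  expect_equal(co$estimate[co$term == "peep_cmH2O"], 3, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "rr_per_min"], -2, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "vt_per_pbw_ml_kg"], 0, tolerance = 1e-8)
  expect_equal(suppressWarnings(glance(fit))$r_squared, 1, tolerance = 1e-12)

  # permutation invariance
  perm <- d[sample(nrow(d)), ]
  expect_equal(
    suppressWarnings(tidy(sensitivity_regression(perm)))$estimate,
    co$estimate,
    tolerance = 1e-9
  )

  # residual orthogonality to the design
  set.seed(54)
  d$focal_index <- d$focal_index + rnorm(10)
  fit2 <- sensitivity_regression(d)
  res <- residuals(fit2$fit)
  X <- as.matrix(d[, c("peep_cmH2O", "rr_per_min", "vt_per_pbw_ml_kg")])
  expect_true(all(abs(crossprod(X, res)) < 1e-8))

  d$vt_per_pbw_ml_kg <- 2 * d$peep_cmH2O # exact collinearity
  err <- tryCatch(sensitivity_regression(d), error = identity)
  expect_s3_class(err, "focalindex_collinearity_error")
  expect_match(conditionMessage(err), "vt_per_pbw_ml_kg|peep_cmH2O")
})

test_that("null regressions centre R^2 at k/(n-1) and adjusted R^2 at zero", {
  set.seed(55)
  n <- 36
  stats <- replicate(400, {
    d <- data.frame(
      focal_index = rnorm(n),
      peep_cmH2O = rnorm(n),
      rr_per_min = rnorm(n),
      vt_per_pbw_ml_kg = rnorm(n)
    )
    g <- glance(sensitivity_regression(d))
    c(g$r_squared, g$adj_r_squared)
  })
  expect_lt(abs(mean(stats[1, ]) - 3 / 35), 0.02)
  expect_lt(abs(mean(stats[2, ])), 0.02)
})
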