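#' Pearson correlation with a 95% confidence interval
#'
#' Sample correlation with a Fisher z-transform confidence interval and a
#' two-sided p-value from the t distribution on n - 2 degrees of freedom
#' (via [stats::cor.test()]). A Spearman option is exposed for rank-based
#' sensitivity checks (no interval in that case).
#'
#' @param data A data frame.
#' @param x,y Column names (strings) or bare column names of the paired
#'   variables.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `estimate`, `conf_low`, `conf_high`, `p_value`,
#'   `n`, `method`.
#' @export
#' @examples
#' d <- data.frame(a = 1:10, b = 2 * (1:10) + 1)
#' pearson_with_ci(d, a, b)
pearson_with_ci <- function(data, x, y, method = c("pearson", "spearman"),
                            conf_level = 0.95) {
  method <- match.arg(method)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  # accept column names given as strings as well as bare names
  if (is.character(xv) && length(xv) == 1 && xv %in% names(data)) xv <- data[[xv]]
  if (is.character(yv) && length(yv) == 1 && yv %in% names(data)) yv <- data[[yv]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) {
    abort("Correlation needs at least 3 complete pairs.",
      class = "focalindex_input_error"
    )
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    abort("Correlation is undefined: one of the variables has zero variance.",
      class = "focalindex_degenerate_error"
    )
  }
  ct <- suppressWarnings(
    cor.test(xv, yv, method = method, conf.level = conf_level, exact = FALSE)
  )
  tibble(
    estimate = unname(ct$estimate),
    conf_low = if (is.null(ct$conf.int)) NA_real_ else ct$conf.int[1],
    conf_high = if (is.null(ct$conf.int)) NA_real_ else ct$conf.int[2],
    p_value = ct$p.value,
    n = length(xv),
    method = method
  )
}

#' Cohen's kappa for two raters with an asymptotic confidence interval
#'
#' Chance-corrected agreement between two raters on a binary classification
#' (here: diffuse vs focal lung injury), `kappa = (p_o - p_e) / (1 - p_e)`
#' with the usual marginal expected agreement. The 95% interval uses the
#' large-sample standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` and is truncated to `[-1, 1]`.
#'
#' @param table A 2 x 2 matrix of counts (rows = rater 1, columns = rater 2),
#'   or a numeric length-4 vector `(both_diffuse, r1_diffuse_r2_focal,
#'   r1_focal_r2_diffuse, both_focal)`.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `kappa`, `conf_low`, `conf_high`, `p_observed`,
#'   `p_expected`, `n`.
#' @export
#' @examples
#' cohen_kappa(c(35, 1, 0, 1)) # kappa = 70/107
cohen_kappa <- function(table, conf_level = 0.95) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)))
    m <- table
  } else {
    stopifnot(length(table) == 4)
    m <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  }
  if (any(m < 0) || sum(m) < 1) {
    abort("Counts must be nonnegative with a positive total.",
      class = "focalindex_input_error"
    )
  }
  n <- sum(m)
  p <- m / n
  p_o <- sum(diag(p))
  p_e <- sum(rowSums(p) * colSums(p))
  if (1 - p_e < .Machine$double.eps^0.5) {
    abort("Kappa is undefined: expected agreement is 1 (degenerate marginals).",
      class = "focalindex_degenerate_error"
    )
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    kappa = kappa,
    conf_low = max(-1, kappa - z * se),
    conf_high = min(1, kappa + z * se),
    p_observed = p_o,
    p_expected = p_e,
    n = n
  )
}

#' Sensitivity regression of the focal index on ventilatory settings
#'
#' Ordinary least squares (with intercept) of the focal index on the
#' ventilator parameters recorded at the CT scan: PEEP (cmH2O), respiratory
#' rate (breaths/min) and tidal volume per predicted body weight (ml/kg PBW).
#' A null result supports the index reflecting intrinsic injury pattern
#' rather than ventilator configuration.
#'
#' @param data A data frame with the response and predictor columns.
#' @param response Response column name (default `"focal_index"`).
#' @param predictors Character vector of predictor column names.
#' @return A `sensitivity_fit` object wrapping the [stats::lm()] fit; use
#'   [generics::tidy()] for coefficients and [generics::glance()] for
#'   `r_squared`, `adj_r_squared` and the overall F-test p-value.
#' @export
sensitivity_regression <- function(data, response = "focal_index",
                                   predictors = c(
                                     "peep_cmH2O", "rr_per_min",
                                     "vt_per_pbw_ml_kg"
                                   )) {
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing columns: %s.", paste(missing_cols, collapse = ", ")),
      class = "focalindex_input_error"
    )
  }
  data <- data[stats::complete.cases(data[, c(response, predictors)]), , drop = FALSE]
  if (nrow(data) <= length(predictors) + 1) {
    abort("Need more observations than predictors plus intercept.",
      class = "focalindex_input_error"
    )
  }
  X <- as.matrix(data[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- predictors[setdiff(qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1, 0)]
    abort(
      sprintf(
        "Collinear design: column(s) %s are linearly dependent.",
        paste(aliased, collapse = ", ")
      ),
      class = "focalindex_collinearity_error"
    )
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = data)
  structure(
    list(fit = fit, response = response, predictors = predictors, n = nrow(data)),
    class = "sensitivity_fit"
  )
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sensitivity_fit> %s ~ %s (n = %d)\nR^2 = %.3f, adj R^2 = %.3f, F p = %.3g\n",
    x$response, paste(x$predictors, collapse = " + "), x$n,
    g$r_squared, g$adj_r_squared, g$f_p_value
  ))
  invisible(x)
}

#' @export
tidy.sensitivity_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' @export
glance.sensitivity_fit <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    f_statistic = unname(f[1]),
    f_p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
    n = x$n
  )
}
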