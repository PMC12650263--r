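# Statistical pipeline: +/- k SD outlier filtering, permutation-based
# Spearman correlation matrix with empirical p-values, Mann-Whitney group
# comparisons, and OLS regression with the full diagnostic report.

#' Listwise outlier filter at mean +/- k standard deviations
#'
#' Per variable, bounds are mean +/- k * sample SD (n-1 denominator) computed
#' on the non-missing values; a participant is excluded listwise if any
#' variable falls strictly outside its bounds (inclusive bounds, so
#' zero-variance columns exclude nobody).
#'
#' @param table data.frame of participants x numeric analysis variables; an
#'   id column named `participant_id` is carried through unexamined.
#' @param k SD multiplier (> 0), default 2.
#' @return list with `table` (filtered), `excluded` (data.frame of
#'   participant_id/row, variable, value, lower, upper), `bounds`.
#' @export
filter_outliers <- function(table, k = 2) {
  assert_scalar_num(k, "k")
  if (k <= 0) stop_validation("`k` must be > 0")
  if (NROW(table) < 3L) stop_validation("need >= 3 rows to estimate bounds")
  ids <- if ("participant_id" %in% names(table)) as.character(table$participant_id)
         else as.character(seq_len(nrow(table)))
  vars <- setdiff(names(table), "participant_id")
  vars <- vars[vapply(table[vars], is.numeric, logical(1))]
  bounds <- data.frame(variable = vars, lower = NA_real_, upper = NA_real_)
  drop <- rep(FALSE, nrow(table))
  excl <- list()
  for (j in seq_along(vars)) {
    v <- table[[vars[j]]]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s)) s <- 0
    lo <- m - k * s
    hi <- m + k * s
    bounds$lower[j] <- lo
    bounds$upper[j] <- hi
    out <- !is.na(v) & (v < lo | v > hi)
    if (any(out)) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant_id = ids[out], variable = vars[j], value = v[out],
        lower = lo, upper = hi, stringsAsFactors = FALSE)
      drop <- drop | out
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl)
              else data.frame(participant_id = character(0), variable = character(0),
                              value = numeric(0), lower = numeric(0), upper = numeric(0))
  list(table = table[!drop, , drop = FALSE], excluded = excluded, bounds = bounds)
}

#' Spearman rank correlation (mid-rank ties)
#'
#' Pearson correlation of average ranks. Returns `NA` with a warning when
#' either variable has zero rank variance over the complete pairs.
#'
#' @param x,y paired numeric vectors; pairs with a missing member are dropped.
#' @return correlation coefficient, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_validation("need >= 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Permutation-based Spearman correlation matrix
#'
#' For each variable pair (pairwise-complete cases), one variable's values
#' are randomly permuted across participants `n_perm` times and the Spearman
#' coefficient recomputed, building an empirical null; the empirical p-value
#' is the proportion of permuted coefficients greater than or equal in
#' magnitude to the observed one (two-sided by construction). Optionally a
#' `(count + 1) / (n_perm + 1)` smoothed p is used instead. Cells with fewer
#' than 3 complete pairs or zero rank variance are reported missing.
#'
#' @param table data.frame of numeric analysis variables (a `participant_id`
#'   column is ignored).
#' @param n_perm number of permutations, default 2000.
#' @param alpha significance level for the mask, default 0.05.
#' @param seed integer seed; results are deterministic under it.
#' @param smoothed use the add-one smoothed p-value (default FALSE: the plain
#'   proportion, which can be exactly 0 at extreme effects).
#' @param p_adjust "none" (default) or "BH" for Benjamini-Hochberg.
#' @return object of class `correlation_result`: list with `rho`,
#'   `p_empirical`, `mask` (p < alpha) matrices, `n_perm`, `alpha`, `seed`.
#' @export
permutation_correlation_matrix <- function(table, n_perm = 2000, alpha = 0.05,
                                           seed = 1L, smoothed = FALSE,
                                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  assert_scalar_num(n_perm, "n_perm", lower = 1)
  assert_scalar_num(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_validation("`alpha` must be in (0,1)")
  vars <- setdiff(names(table), "participant_id")
  vars <- vars[vapply(table[vars], is.numeric, logical(1))]
  if (anyDuplicated(vars)) stop_validation("duplicate column names")
  m <- length(vars)
  rho <- matrix(NA_real_, m, m, dimnames = list(vars, vars))
  pmat <- matrix(NA_real_, m, m, dimnames = list(vars, vars))
  diag(rho) <- 1
  with_seed(derive_seed(seed, "permcor"), {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        x <- table[[vars[i]]]
        y <- table[[vars[j]]]
        ok <- is.finite(x) & is.finite(y)
        n <- sum(ok)
        if (n < 3L) next
        rx <- rank(x[ok]); ry <- rank(y[ok])
        if (stats::sd(rx) == 0 || stats::sd(ry) == 0) next
        obs <- stats::cor(rx, ry)
        # permuting ranks is equivalent to permuting values then re-ranking
        perm_idx <- matrix(0L, n, n_perm)
        for (b in seq_len(n_perm)) perm_idx[, b] <- sample.int(n)
        ry_perm <- matrix(ry[perm_idx], n, n_perm)
        zx <- (rx - mean(rx)) / stats::sd(rx)
        zy <- scale(ry_perm)  # column-wise center/scale
        rho_perm <- as.vector(crossprod(zx, zy)) / (n - 1)
        count <- sum(abs(rho_perm) >= abs(obs) - 1e-12)
        p <- if (smoothed) (count + 1) / (n_perm + 1) else count / n_perm
        rho[i, j] <- rho[j, i] <- obs
        pmat[i, j] <- pmat[j, i] <- p
      }
    }
  })
  if (p_adjust == "BH") {
    up <- upper.tri(pmat)
    adj <- stats::p.adjust(pmat[up], method = "BH")
    pmat[up] <- adj
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  }
  mask <- !is.na(pmat) & pmat < alpha
  structure(list(rho = rho, p_empirical = pmat, mask = mask,
                 n_perm = as.integer(n_perm), alpha = alpha, seed = seed),
            class = "correlation_result")
}

#' Long-format view of a correlation result
#'
#' @param result a `correlation_result`.
#' @return data.frame with `var1`, `var2`, `rho`, `p`, `significant`, one row
#'   per unordered variable pair.
#' @export
correlation_long <- function(result) {
  vars <- rownames(result$rho)
  idx <- which(upper.tri(result$rho), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    var1 = vars[idx[, 1]],
    var2 = vars[idx[, 2]],
    rho = result$rho[idx],
    p = result$p_empirical[idx],
    significant = result$mask[idx],
    stringsAsFactors = FALSE
  )
}

#' Mann-Whitney U test (exact for small untied samples)
#'
#' Reports U for the first sample (rank-sum definition). Two-sided p comes
#' from full enumeration of all group assignments when `n1 * n2 <= 400` and
#' there are no ties (p = proportion of assignments with `|U - n1*n2/2|` at
#' least as large as observed); otherwise from the normal approximation with
#' tie and continuity corrections.
#'
#' @param a,b numeric samples (each non-empty).
#' @param variable optional name carried into the result.
#' @return list with `variable`, `n1`, `n2`, `U`, `p_two_sided`, `method`.
#' @export
mann_whitney <- function(a, b, variable = NA_character_) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop_validation("both groups need >= 1 observation")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n1 * n2 <= 400) {
    # exact: U depends only on which ranks go to group a
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal-approximation"
  }
  list(variable = variable, n1 = n1, n2 = n2, U = U,
       p_two_sided = p, method = method)
}

# --- OLS with full diagnostic report ---------------------------------------

# D'Agostino skewness test Z (requires n >= 8)
dagostino_skew_z <- function(e) {
  n <- length(e)
  m2 <- mean((e - mean(e))^2)
  m3 <- mean((e - mean(e))^3)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

# Anscombe-Glynn kurtosis test Z (requires n >= 5; stable from n >= 8)
anscombe_kurt_z <- function(e) {
  n <- length(e)
  m2 <- mean((e - mean(e))^2)
  m4 <- mean((e - mean(e))^4)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  num <- 1 - 2 / (9 * a)
  den <- ((1 - 2 / a) / (1 + x * sqrt(2 / (a - 4))))^(1 / 3)
  (num - den) / sqrt(2 / (9 * a))
}

#' Durbin-Watson statistic of a residual sequence
#'
#' `sum(diff(e)^2) / sum(e^2)`.
#' @param e numeric residual vector (length >= 2).
#' @return the statistic.
#' @export
durbin_watson <- function(e) {
  if (length(e) < 2L) stop_validation("need >= 2 residuals")
  sum(diff(e)^2) / sum(e^2)
}

#' Single-predictor OLS fit with a full diagnostic report
#'
#' Least squares with intercept, plus the conventional regression-report
#' diagnostics: R2, adjusted R2, F and its p, AIC/BIC from the Gaussian
#' log-likelihood (k = number of coefficients), Durbin-Watson,
#' D'Agostino-Pearson omnibus normality test on residuals (with p),
#' Jarque-Bera, residual skewness (g1) and kurtosis (non-excess b2), and the
#' design-matrix condition number (ratio of singular values of the raw
#' design matrix including the intercept column). 95% CIs use the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param x predictor vector.
#' @param y response vector.
#' @param conf_level confidence level for the coefficient intervals.
#' @return object of class `regression_report` (a list; see fields in source).
#' @export
ols_fit <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_validation("need >= 3 complete pairs")
  if (stats::sd(x) == 0) stop_validation("constant predictor: design matrix is rank deficient")
  fit <- stats::lm(y ~ x)
  beta <- stats::coef(fit)
  e <- stats::residuals(fit)
  rss <- sum(e^2)
  tss <- sum((y - mean(y))^2)
  k <- 2L  # coefficients
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k)
  fstat <- (r2 / (k - 1)) / ((1 - r2) / (n - k))
  prob_f <- stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  aic <- -2 * ll + 2 * k
  bic <- -2 * ll + log(n) * k
  sigma2 <- rss / (n - k)
  X <- cbind(1, x)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tvals <- beta / se
  pvals <- 2 * stats::pt(-abs(tvals), df = n - k)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - k)
  ci <- cbind(lower = beta - tcrit * se, upper = beta + tcrit * se)

  m2 <- mean((e - mean(e))^2)
  skew <- mean((e - mean(e))^3) / m2^1.5
  kurt <- mean((e - mean(e))^4) / m2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  if (n >= 8) {
    z1 <- dagostino_skew_z(e)
    z2 <- anscombe_kurt_z(e)
    omnibus <- z1^2 + z2^2
    prob_omnibus <- stats::pchisq(omnibus, df = 2, lower.tail = FALSE)
  } else {
    warning("n < 8: omnibus normality test not computed")
    omnibus <- NA_real_
    prob_omnibus <- NA_real_
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- max(sv) / min(sv)

  coef_table <- data.frame(
    term = c("(Intercept)", "x"),
    estimate = unname(beta),
    std_error = unname(se),
    t_value = unname(tvals),
    p_value = unname(pvals),
    ci_lower = unname(ci[, "lower"]),
    ci_upper = unname(ci[, "upper"])
  )
  structure(list(
    coefficients = coef_table,
    n = n,
    r_squared = r2,
    adj_r_squared = adj_r2,
    f_statistic = fstat,
    prob_f = prob_f,
    aic = aic,
    bic = bic,
    log_likelihood = ll,
    durbin_watson = durbin_watson(e),
    omnibus = omnibus,
    prob_omnibus = prob_omnibus,
    jarque_bera = jb,
    skewness = skew,
    kurtosis = kurt,
    condition_number = cond,
    residuals = e,
    fitted = stats::fitted(fit)
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("OLS regression report (n = %d)\n", x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("R-squared %.4f  adj %.4f  F %.3f (p %.4g)\n",
              x$r_squared, x$adj_r_squared, x$f_statistic, x$prob_f))
  cat(sprintf("AIC %.2f  BIC %.2f  DW %.3f  Omnibus %.3f (p %.3g)  JB %.3f\n",
              x$aic, x$bic, x$durbin_watson, x$omnibus, x$prob_omnibus,
              x$jarque_bera))
  cat(sprintf("skew %.3f  kurtosis %.3f  condition number %.3f\n",
              x$skewness, x$kurtosis, x$condition_number))
  invisible(x)
}
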