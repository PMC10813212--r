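#' Mann-Whitney U test with rank-biserial effect size
#'
#' U is computed from midranks. When `min(n1, n2) <= exact_max` the
#' two-sided p-value is exact, obtained by enumerating the permutation
#' null distribution of U over all assignments of the observed (mid)ranks
#' to groups — for tie-free data this is the classical exact U
#' distribution; with ties it is the exact conditional (permutation)
#' distribution. Otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' The rank-biserial effect size is `r = 2 U1 / (n1 n2) - 1`, where `U1`
#' is the U statistic of the first sample; `r < 0` when the first sample
#' tends to be smaller. Group order is therefore part of the API: pass the
#' comparison group first.
#'
#' @param x,y Numeric samples (first sample = comparison group).
#' @param exact_max Largest `min(n1, n2)` for which the exact enumeration
#'   is used (default 8, making 8-per-group comparisons exact).
#' @return List of class `rank_test_result`: `u_stat` (U1), `p_two_sided`,
#'   `rank_biserial`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  rb <- 2 * u1 / (n1 * n2) - 1
  if (min(n1, n2) <= exact_max && n <= 20) {
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u1 + eps), mean(u_all >= u1 - eps)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- sign(u1 - mu) * 0.5
    z <- if (sigma2 > 0) (u1 - mu - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(u_stat = u1, p_two_sided = p, rank_biserial = rb,
                 n1 = n1, n2 = n2, method = method),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d/%d), p = %.4g (%s), rank-biserial r = %.3f\n",
              x$u_stat, x$n1, x$n2, x$p_two_sided, x$method, x$rank_biserial))
  invisible(x)
}

# all permutations of 1..n as an (n! x n) matrix
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation
#'
#' `rho` is the product-moment correlation of midranks. For `n <=
#' exact_max` the two-sided p-value is exact, from the full permutation
#' distribution of `rho` (`P(|rho_perm| >= |rho_obs|)`); otherwise from
#' the t approximation `t = rho sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y Paired numeric samples, `n >= 3`.
#' @param exact_max Largest n for which the permutation null is enumerated
#'   (default 8; 8! = 40320 permutations).
#' @return List of class `correlation_result`: `rho`, `p_two_sided`, `n`,
#'   `method`.
#' @export
spearman <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    method <- "t-approx"
  }
  structure(list(rho = rho, p_two_sided = p, n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d), p = %.4g (%s)\n",
              x$rho, x$n, x$p_two_sided, x$method))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Flags each variable as `normal` or `non-normal` at level `alpha`; the
#' pipeline takes the nonparametric branch when any analysis variable is
#' flagged non-normal. Samples with `n < 3` or zero variance are skipped
#' with a warning (`NA`).
#'
#' @param samples Named list of numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector: `"normal"`, `"non-normal"` or `NA`.
#' @export
shapiro_wilk_gate <- function(samples, alpha = 0.05) {
  vapply(names(samples), function(nm) {
    s <- samples[[nm]]
    s <- s[!is.na(s)]
    if (length(s) < 3 || stats::sd(s) == 0) {
      warning("sample '", nm, "' skipped (n < 3 or constant)")
      return(NA_character_)
    }
    if (length(s) > 5000) s <- s[seq_len(5000)]
    p <- stats::shapiro.test(s)$p.value
    if (p < alpha) "non-normal" else "normal"
  }, character(1))
}

#' Ordinary least squares fit
#'
#' Least-squares fit with intercept via `stats::lm`, returning the
#' quantities the reporting layer needs. Rank-deficient designs are an
#' error naming the collinear terms.
#'
#' @param X Data frame of predictors.
#' @param y Numeric response.
#' @return List of class `regression_fit`: `coefficients` (named, incl.
#'   `(Intercept)`), `r2`, `adj_r2`, `f_stat`, `f_p`, `n`, `k`, `term_p`,
#'   `terms`, and the underlying `lm` object.
#' @export
ols_fit <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X) + 1) stop("need n > k + 1 observations")
  dat <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  s <- summary(fit)
  fstat <- if (ncol(X) > 0) unname(s$fstatistic[1]) else NA_real_
  fp <- if (ncol(X) > 0)
    stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE)
  else NA_real_
  structure(list(coefficients = stats::coef(fit),
                 r2 = s$r.squared, adj_r2 = s$adj.r.squared,
                 f_stat = fstat, f_p = unname(fp),
                 n = nrow(X), k = ncol(X),
                 term_p = s$coefficients[, 4],
                 terms = colnames(X), lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  co <- paste(sprintf("%s = %.3f", names(x$coefficients), x$coefficients),
              collapse = ", ")
  cat(sprintf("OLS (n = %d, k = %d): %s\n  R2 = %.3f, adj R2 = %.3f, F = %.3g\n",
              x$n, x$k, co, x$r2, x$adj_r2, x$f_stat))
  invisible(x)
}

#' Backward-stepwise model selection
#'
#' Starts from the full model and iteratively removes predictors.
#' Criteria:
#' \describe{
#'   \item{`adjr2`}{remove the predictor whose removal yields the largest
#'     increase in adjusted R-squared; stop when no removal increases it.
#'     This mirrors justifying the final model by adjusted R-squared, but
#'     note it retains a null predictor whenever its |t| exceeds 1.}
#'   \item{`pvalue`}{remove the predictor with the largest p-value while
#'     that p-value exceeds `p_remove`. A null predictor survives with
#'     probability ~`p_remove`, so small thresholds give high exact-model
#'     selection rates.}
#' }
#'
#' @param X Data frame of predictors.
#' @param y Numeric response.
#' @param criterion `"adjr2"` (default) or `"pvalue"`.
#' @param p_remove Removal threshold for `criterion = "pvalue"`.
#' @return The final [ols_fit()] with an added `drop_log` (character
#'   vector of removed terms in order) and `criterion`.
#' @export
backward_stepwise <- function(X, y, criterion = c("adjr2", "pvalue"),
                              p_remove = 0.05) {
  criterion <- match.arg(criterion)
  X <- as.data.frame(X)
  keep <- colnames(X)
  drop_log <- character(0)
  fit <- ols_fit(X[, keep, drop = FALSE], y)
  repeat {
    if (!length(keep)) break
    if (criterion == "adjr2") {
      cand <- vapply(keep, function(term) {
        rest <- setdiff(keep, term)
        if (!length(rest)) {
          # intercept-only model: adj R2 defined as 0
          0
        } else {
          ols_fit(X[, rest, drop = FALSE], y)$adj_r2
        }
      }, numeric(1))
      best <- names(cand)[which.max(cand)]
      if (cand[best] <= fit$adj_r2) break
      keep <- setdiff(keep, best)
      drop_log <- c(drop_log, best)
      fit <- if (length(keep)) ols_fit(X[, keep, drop = FALSE], y) else
        intercept_only_fit(y)
    } else {
      tp <- fit$term_p[setdiff(names(fit$term_p), "(Intercept)")]
      if (!length(tp) || max(tp) <= p_remove) break
      worst <- names(tp)[which.max(tp)]
      keep <- setdiff(keep, worst)
      drop_log <- c(drop_log, worst)
      fit <- if (length(keep)) ols_fit(X[, keep, drop = FALSE], y) else
        intercept_only_fit(y)
    }
    if (!length(keep)) break
  }
  fit$drop_log <- drop_log
  fit$criterion <- criterion
  fit
}

intercept_only_fit <- function(y) {
  fit <- stats::lm(y ~ 1)
  structure(list(coefficients = stats::coef(fit), r2 = 0, adj_r2 = 0,
                 f_stat = NA_real_, f_p = NA_real_, n = length(y), k = 0L,
                 term_p = summary(fit)$coefficients[, 4],
                 terms = character(0), lm = fit),
            class = "regression_fit")
}
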