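test_that("Mann-Whitney matches hand-derived exact cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$u_stat, 0)
  expect_equal(r$rank_biserial, -1)
  expect_equal(r$p_two_sided, 1 / 3)       # 2 x P(U <= 0) over C(4,2) splits
  expect_equal(r$method, "exact")
  # identical multisets give a null effect size
  expect_equal(mann_whitney(c(5, 7, 9), c(9, 5, 7))$rank_biserial, 0)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with enumeration oracle and wilcox.test", {
  set.seed(19)
  for (i in 1:300) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(100, n1); y <- sample(100, n2)      # tie-free
    while (length(intersect(x, y))) y <- sample(1000, n2)
    r <- mann_whitney(x, y)
    expect_equal(r$u_stat, oracle_u(x, y))
    expect_equal(r$p_two_sided, oracle_mw_p(x, y))
    expect_equal(r$rank_biserial, oracle_rank_biserial(x, y))
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(r$u_stat, unname(w$statistic))
    expect_equal(r$p_two_sided, w$p.value)
  }
  # ties: permutation-exact p still matches the oracle
  for (i in 1:100) {
    x <- sample(5, sample(2:6, 1), replace = TRUE)
    y <- sample(5, sample(2:6, 1), replace = TRUE)
    r <- mann_whitney(x, y)
    expect_equal(r$u_stat, oracle_u(x, y))
    expect_equal(r$p_two_sided, oracle_mw_p(x, y))
  }
})

test_that("Mann-Whitney is antisymmetric under sample swap", {
  set.seed(23)
  for (i in 1:50) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1))
    a <- mann_whitney(x, y); b <- mann_whitney(y, x)
    expect_equal(a$u_stat, length(x) * length(y) - b$u_stat)
    expect_equal(a$rank_biserial, -b$rank_biserial)
    expect_equal(a$p_two_sided, b$p_two_sided)
  }
})

test_that("exact Mann-Whitney holds its size at alpha = 0.05 for n = 5 + 5", {
  combs <- combn(10, 5)
  pvals <- apply(combs, 2, function(idx)
    mann_whitney(seq_len(10)[idx], seq_len(10)[-idx])$p_two_sided)
  expect_lte(mean(pvals <= 0.05), 0.05)
})

test_that("large-sample Mann-Whitney approximates wilcox.test with ties", {
  set.seed(29)
  x <- round(rnorm(30, 0, 2)); y <- round(rnorm(35, 0.8, 2))
  r <- mann_whitney(x, y)
  expect_equal(r$method, "normal-approx")
  w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$u_stat, unname(w$statistic))
  expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-10)
})

test_that("Spearman rho equals rank identities and the d2 closed form", {
  x <- c(3, 8, 21); y <- exp(x)
  expect_equal(spearman(x, y)$rho, 1)                 # monotone pair
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  set.seed(37)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    x <- sample(1000, n); y <- sample(1000, n)        # tie-free
    expect_equal(spearman(x, y)$rho, oracle_spearman_d2(x, y), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 2:1), "n >= 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(41)
  for (i in 1:30) {
    x <- rnorm(9); y <- rnorm(9)
    base <- spearman(x, y)
    tr <- spearman(exp(x), y^3 + 5 * y)
    expect_equal(tr$rho, base$rho)
    expect_equal(tr$p_two_sided, base$p_two_sided)
  }
})

test_that("exact Spearman p matches the exhaustive permutation null at n = 8", {
  set.seed(43)
  perms <- ssmpipe:::permutations_of(8)
  for (i in 1:3) {
    x <- sample(100, 8); y <- sample(100, 8)
    got <- spearman(x, y)
    expect_equal(got$method, "exact-permutation")
    rho_all <- apply(perms, 1, function(p) oracle_spearman_d2(x, y[p]))
    want <- mean(abs(rho_all) >= abs(oracle_spearman_d2(x, y)) - 1e-12)
    expect_equal(got$p_two_sided, want)
  }
})

test_that("Shapiro-Wilk gate flags distributions and skips degenerate input", {
  set.seed(47)
  expect_equal(unname(shapiro_wilk_gate(list(u = runif(5000)))), "non-normal")
  flags <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    unname(shapiro_wilk_gate(list(g = rnorm(5000))))
  }, character(1))
  expect_gte(mean(flags == "normal"), 0.94)
  expect_warning(g <- shapiro_wilk_gate(list(k = rep(3, 10))), "skipped")
  expect_true(is.na(g[["k"]]))
})

test_that("OLS reproduces exact fits and the normal-equations solution", {
  x <- 1:20
  f <- suppressWarnings(ols_fit(data.frame(x = x), 1 + 2 * x))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(f$r2, 1)
  set.seed(53)
  X <- data.frame(a = rnorm(40), b = runif(40), c = rnorm(40, 5))
  y <- 2 + 0.5 * X$a - 3 * X$b + rnorm(40)
  f2 <- ols_fit(X, y)
  # prediction at predictor means equals the response mean (OLS identity)
  pred <- sum(f2$coefficients * c(1, colMeans(X)))
  expect_equal(pred, mean(y), tolerance = 1e-10)
  # independent normal-equations solve
  M <- cbind(1, as.matrix(X))
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(unname(f2$coefficients), as.numeric(beta), tolerance = 1e-8)
  expect_error(ols_fit(data.frame(a = X$a, b = 2 * X$a), y), "collinear")
})

test_that("adjusted R2 of a nested submodel never exceeds the full-model R2", {
  set.seed(59)
  for (i in 1:20) {
    X <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    y <- rnorm(30)
    full <- ols_fit(X, y)
    sub <- ols_fit(X[, 1:2], y)
    expect_lte(sub$adj_r2, full$r2)
  }
})

test_that("backward stepwise keeps signal and sheds pure-noise predictors", {
  set.seed(61)
  hits <- 0
  for (i in 1:50) {
    X <- data.frame(x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200))
    y <- 3 * X$x1 + rnorm(200)
    f <- backward_stepwise(X, y, criterion = "pvalue", p_remove = 0.01)
    if (identical(f$terms, "x1")) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
  # all-noise design collapses to intercept-only in the majority of runs
  drops <- vapply(1:40, function(i) {
    X <- data.frame(a = rnorm(60), b = rnorm(60))
    length(backward_stepwise(X, rnorm(60), criterion = "pvalue")$terms) == 0
  }, logical(1))
  expect_gt(mean(drops), 0.5)
  # a perfect single predictor is always retained
  x <- rnorm(30)
  f <- suppressWarnings(backward_stepwise(data.frame(x = x), 2 * x))
  expect_equal(f$terms, "x")
  expect_equal(f$r2, 1)
  # drop log records removals in order under the adjusted-R2 criterion
  X <- data.frame(s = rnorm(100))
  X$n1 <- rnorm(100) * 0.001
  y <- X$s + rnorm(100, 0, 0.1)
  f2 <- backward_stepwise(X, y)
  expect_true("s" %in% f2$terms)
})
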