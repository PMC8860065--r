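# AICc as the tests compute it independently, from an lm fit
aicc_lm <- function(fit) {
  n <- nobs(fit); k <- length(coef(fit)) + 1
  -2 * as.numeric(logLik(fit)) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

test_that("ols_fit matches the normal-equations/lm oracle on a fixed toy", {
  set.seed(111)
  n <- 8
  X <- random_design(n, 2)
  y <- 0.7 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.5)
  fit <- ols_fit(y, X, c("x1", "x2"))
  ref <- lm(y ~ x1 + x2, data = data.frame(y = y, X))
  s <- summary(ref)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  # normal equations, computed directly
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-10)
  expect_equal(unname(fit$std_errors), unname(s$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(fit$p_values), unname(s$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(fit$adj_r2, s$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$aicc, aicc_lm(ref), tolerance = 1e-8)
})

test_that("degenerate fits behave as forced", {
  set.seed(121)
  X <- random_design(12, 2)
  y <- X[, 1]
  fit <- ols_fit(y, X, "x1")
  expect_equal(unname(fit$coefficients["x1"]), 1, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  expect_equal(unname(fit$pR["x1"]), 1, tolerance = 1e-12)

  # intercept-only model of a standardized response explains nothing
  ys <- standardize(rnorm(12))
  fit0 <- ols_fit(ys, X, character(0))
  expect_equal(fit0$adj_r2, 0, tolerance = 1e-12)

  # rank-deficient designs name the aliased column
  X2 <- cbind(X, x3 = X[, 1])
  expect_error(ols_fit(rnorm(12), X2, c("x1", "x3")), "aliased.*x3")
})

test_that("all_subsets enumerates and ranks like the brute-force oracle", {
  set.seed(131)
  X <- random_design(14, 2)
  y <- rnorm(14)
  rk <- all_subsets(y, X)
  expect_equal(nrow(rk$table), 4)  # 2^2 subsets

  # y identical to x1 forces {x1} (perfect fit has AICc -Inf)
  y1 <- X[, 1]
  rk1 <- all_subsets(y1, X)
  expect_equal(rk1$table$predictors[1], "x1")

  # 3-candidate ranking equals lm-based recomputation for all 8 subsets
  X3 <- random_design(16, 3)
  y3 <- 0.8 * X3[, 1] + rnorm(16, 0, 0.7)
  rk3 <- all_subsets(y3, X3)
  d <- data.frame(y = y3, X3)
  oracle <- do.call(rbind, lapply(0:7, function(m) {
    subset <- colnames(X3)[bitwAnd(m, c(1L, 2L, 4L)) > 0]
    f <- if (length(subset)) reformulate(subset, "y") else y ~ 1
    data.frame(predictors = paste(subset, collapse = "+"),
               aicc = aicc_lm(lm(f, data = d)))
  }))
  oracle <- oracle[order(oracle$aicc), ]
  expect_equal(rk3$table$predictors, oracle$predictors)
  expect_equal(rk3$table$aicc, oracle$aicc, tolerance = 1e-8)
  expect_equal(rk3$table$delta_aicc[1], 0)
})

test_that("top_models applies the strict delta cutoff", {
  set.seed(141)
  X <- random_design(20, 2)
  y <- rnorm(20)
  rk <- all_subsets(y, X)
  # override the table to the worked deltas; only the filter is under test
  rk$table <- rk$table[order(rk$table$size), ]
  rk$table$delta_aicc <- c(0, 1.5, 2.0, 3)
  tp <- top_models(rk, delta_max = 2)
  expect_equal(length(tp), 2)
  expect_equal(vapply(tp, function(f) f$delta_aicc, numeric(1)), c(0, 1.5))
  # delta_max = Inf keeps everything
  expect_equal(length(top_models(rk, delta_max = Inf)), 4)
})

test_that("contribution is the presence frequency over top models", {
  set.seed(151)
  X <- random_design(20, 3)
  y <- rnorm(20)
  mk <- function(subset) ols_fit(y, X, subset)
  top <- list(mk("x1"), mk(c("x1", "x2")), mk(c("x1", "x3")),
              mk("x2"), mk(c("x2", "x3")))
  expect_equal(contribution("x1", top), 0.6)     # 3 of 5
  expect_equal(contribution("x3", top), 0.4)
  all_in <- list(mk("x1"), mk(c("x1", "x2")))
  expect_equal(contribution("x1", all_in), 1)
  expect_equal(contribution("x3", all_in), 0)
  # akaike-weight variant stays in [0, 1] and is 1 for ever-present vars
  for (f in seq_along(all_in)) all_in[[f]]$delta_aicc <- c(0, 1.2)[f]
  expect_equal(akaike_weight_contribution("x1", all_in), 1)
})

test_that("partial correlations equal the residual-on-residual oracle", {
  set.seed(161)
  n <- 30
  X <- random_design(n, 2)
  y <- 0.5 * X[, 1] - 0.8 * X[, 2] + rnorm(n)
  pr <- partial_correlations(y, X, c("x1", "x2"))
  d <- data.frame(y = y, X)
  oracle1 <- cor(resid(lm(y ~ x2, d)), resid(lm(x1 ~ x2, d)))
  oracle2 <- cor(resid(lm(y ~ x1, d)), resid(lm(x2 ~ x1, d)))
  expect_equal(unname(pr), c(oracle1, oracle2), tolerance = 1e-10)

  # single predictor reduces to the marginal correlation
  expect_equal(unname(partial_correlations(y, X, "x1")), cor(y, X[, 1]),
               tolerance = 1e-12)
})

test_that("pR satisfies the t-statistic identity and matches the fit signs", {
  set.seed(171)
  for (i in 1:25) {
    n <- sample(15:40, 1); p <- sample(1:4, 1)
    X <- random_design(n, p)
    y <- X %*% rnorm(p) + rnorm(n)
    fit <- ols_fit(as.numeric(y), X)
    df <- n - p - 1
    expect_equal(unname(fit$pR),
                 unname(fit$t_values[fit$predictors] /
                          sqrt(fit$t_values[fit$predictors]^2 + df)),
                 tolerance = 1e-8)
    expect_equal(sign(fit$pR), sign(fit$coefficients[fit$predictors]))
    expect_equal(fit$partial_r2, fit$pR^2, tolerance = 1e-12)
    expect_true(all(fit$vif > 1 - 1e-9))
  }
})

test_that("vif equals the auxiliary-regression formula", {
  set.seed(181)
  n <- 40
  x1 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = x1 + rnorm(n, 0, 0.05), x3 = rnorm(n))
  v <- vif(X, c("x1", "x2", "x3"))
  r2 <- summary(lm(x1 ~ x2 + x3, data.frame(X)))$r.squared
  expect_equal(unname(v["x1"]), 1 / (1 - r2), tolerance = 1e-8)
  expect_gt(v["x1"], 50)
  expect_equal(unname(vif(X, "x3")), 1)
  X2 <- random_design(50, 2)
  expect_lt(max(vif(X2, c("x1", "x2"))), 1.3)
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.60)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.60))
  set.seed(191)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("trend_with_bh recovers exact trends and flat series", {
  years <- 1982:2017
  exact <- setNames(0.3 * (years - 1982), years)
  flat <- setNames(rep(1.5, length(years)), years)
  noisy <- setNames(0.1 * (years - 1982) + rnorm(length(years), 0, 2), years)
  tr <- trend_with_bh(list(EX = exact, FL = flat, NO = noisy))
  expect_equal(tr$slope[1], 0.3, tolerance = 1e-10)
  expect_equal(tr$r2[1], 1, tolerance = 1e-10)
  expect_equal(tr$total_shift[1], 0.3 * 35, tolerance = 1e-10)
  expect_equal(tr$slope[2], 0, tolerance = 1e-12)
  expect_equal(tr$p_raw[2], 1)
  expect_true(all(tr$p_bh >= tr$p_raw - 1e-12))
})

test_that("window_profile has the right shape and a clean null", {
  set.seed(201)
  n <- 200
  X <- random_design(n, 9, prefix = "v")
  rownames(X) <- 1801:2000
  subs <- lapply(setNames(paste0("SP", 1:9), paste0("SP", 1:9)),
                 function(s) setNames(rnorm(n), rownames(X)))
  wp <- window_profile(subs, X)
  expect_equal(dim(wp$matrix), c(9L, 9L))
  expect_true(all(abs(wp$matrix) <= 1))
  # response independent of all predictors: entries near 0 at this n
  expect_lt(max(abs(wp$matrix)), 0.25)
  expect_equal(nrow(wp$long), 81)
})
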