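test_that("knot rule follows max(5, min(floor(T/4), 40))", {
  expect_equal(knot_count(6), 5)
  expect_equal(knot_count(24), 6)
  expect_equal(knot_count(200), 40)
  expect_equal(knot_count(2), 5)
  expect_error(knot_count(1), "at least 2")
})

test_that("truncated line basis is (t - kappa)_+ with duplicates collapsed", {
  expect_equal(drop(truncated_line_basis(5, c(2, 4, 6))), c(3, 1, 0))
  expect_equal(drop(truncated_line_basis(4, c(2, 4, 6)))[2], 0)  # t = knot
  expect_equal(drop(truncated_line_basis(1, c(2, 4, 6))), c(0, 0, 0))
  b <- spline_basis(c(0, 0, 0, 1, 1, 1), K = 5)
  expect_lt(length(b$knots), 5)                 # duplicates collapsed
  expect_equal(b$knots, sort(unique(b$knots)))
})

test_that("noiseless line: OLS recovers it and the spline stays flat", {
  pr <- make_profile(2 + 3 * rep(std_times, 10))
  f0 <- fit_lmms(pr, 0)
  expect_equal(f0$beta0, 2, tolerance = 1e-8)
  expect_equal(f0$beta1, 3, tolerance = 1e-8)
  expect_lt(f0$sigma_eps2, 1e-12)
  f1 <- fit_lmms(pr, 1)
  expect_lt(max(abs(f1$u)), 1e-6)  # no curvature to absorb
  expect_equal(predict_curve(f1, std_times), 2 + 3 * std_times,
               tolerance = 1e-6)
})

test_that("penalized spline fit solves ridge at lambda = s2_eps/s2_u", {
  set.seed(3)
  pr <- make_profile(sin(1.5 * rep(std_times, 10)) +
                       rnorm(60, sd = 0.2))
  f1 <- fit_lmms(pr, 1)
  lambda <- f1$sigma_eps2 / f1$sigma_u2
  C <- cbind(1, pr$time, truncated_line_basis(pr$time, f1$basis))
  P <- diag(c(0, 0, rep(1, length(f1$basis$knots))))
  coef <- solve(crossprod(C) + lambda * P, crossprod(C, pr$value))
  expect_equal(unname(c(f1$beta0, f1$beta1, f1$u)), drop(coef),
               tolerance = 1e-6)
  expect_equal(predict_curve(f1, std_times),
               drop(cbind(1, std_times,
                          truncated_line_basis(std_times, f1$basis)) %*%
                      coef),
               tolerance = 1e-6)
})

test_that("fitted curve is continuous; derivative matches finite differences", {
  set.seed(8)
  pr <- make_profile(cos(rep(std_times, 10)) + rnorm(60, sd = 0.1))
  f <- fit_lmms(pr, 1)
  for (k in f$basis$knots) {
    eps <- 1e-9
    expect_lt(abs(predict_curve(f, k - eps) - predict_curve(f, k + eps)),
              1e-6)
  }
  grid <- seq(0.05, 3.95, by = 0.05)
  grid <- grid[vapply(grid, function(g)
    all(abs(g - f$basis$knots) > 1e-4), logical(1))]
  h <- 1e-6
  fd <- (predict_curve(f, grid + h) - predict_curve(f, grid - h)) / (2 * h)
  expect_equal(lmms_derivative(f, grid), fd, tolerance = 1e-6)
  # piecewise-constant structure: slope left of all knots, full sum right
  expect_equal(lmms_derivative(f, -1), f$beta1)
  expect_equal(lmms_derivative(f, 100), f$beta1 + sum(f$u))
  # class 0: constant slope everywhere
  f0 <- fit_lmms(pr, 0)
  expect_equal(lmms_derivative(f0, c(0, 1, 7)), rep(f0$beta1, 3))
})

test_that("ML log-likelihoods are monotone across nested classes", {
  set.seed(12)
  for (r in 1:5) {
    y <- sin(rep(std_times, 10)) +
      rep(rnorm(10, sd = 0.3), each = 6) + rnorm(60, sd = 0.2)
    pr <- make_profile(y)
    ll <- sapply(0:3, function(k) fit_lmms(pr, k)$loglik_ml)
    expect_true(all(diff(ll) >= -1e-6))
  }
})

test_that("serial selection recovers planted generating classes", {
  set.seed(101)
  reps <- 60
  cls <- function(y) select_lmms(make_profile(y))$fit$model_class
  # straight line, small noise -> class 0
  c0 <- replicate(reps, cls(1 + 0.5 * rep(std_times, 10) +
                              rnorm(60, sd = 0.05)))
  expect_gte(mean(c0 == 0), 0.9)
  # curvature, no subject structure -> class 1
  c1 <- replicate(reps, cls(sin(1.5 * rep(std_times, 10)) +
                              rnorm(60, sd = 0.05)))
  expect_gte(mean(c1 == 1), 0.9)
  # curvature + strong subject offsets (5x noise SD) -> class >= 2
  c2 <- replicate(reps, cls(sin(1.5 * rep(std_times, 10)) +
                              rep(rnorm(10, sd = 0.25), each = 6) +
                              rnorm(60, sd = 0.05)))
  expect_gte(mean(c2 >= 2), 0.9)
})

test_that("promotion rate on pure class-0 data is near the test level", {
  set.seed(55)
  reps <- 200
  promoted <- replicate(reps, {
    y <- 1 + 0.5 * rep(std_times, 10) + rnorm(60, sd = 0.3)
    select_lmms(make_profile(y))$fit$model_class > 0
  })
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(promoted), 0.05 + 3 * se)
})

test_that("model_all summarises classes and honours the grid default", {
  exp <- make_noise_experiment(n_mol = 12, n_subj = 8, sd = 0.05,
                               n_trend = 12, slope = 0.5, seed = 2)
  res <- lmms_model_all(exp, derivative = TRUE)
  expect_equal(res$grid, sort(unique(exp$time)))
  expect_equal(dim(res$curves), c(12, 6))
  expect_equal(dim(res$derivatives), c(12, 6))
  expect_equal(sum(res$class_counts), 12)
  expect_gte(res$class_counts[["LIN"]], 10)  # all-linear synthetic data
  # n = 1 subject: classes 2-3 never attempted
  one <- make_profile(sin(std_times) + rnorm(6, sd = 0.01), n_subj = 1)
  expect_lte(select_lmms(one)$fit$model_class, 1)
})

test_that("engine agrees with nlme on spline and subject models", {
  skip_if_not_installed("nlme")
  set.seed(42)
  d <- make_design(10)
  y <- sin(d$time) + 0.3 * d$time + rnorm(60, sd = 0.2)
  pr <- data.frame(subject = d$subject, time = d$time, value = y)
  b <- spline_basis(d$time)
  Z <- truncated_line_basis(d$time, b)
  df <- data.frame(y = y, t = d$time, subj = factor(d$subject), all = 1)
  df$Z <- Z  # matrix column so the pdIdent formula finds it in `data`
  m1 <- nlme::lme(y ~ t, random = list(all = nlme::pdIdent(~ Z - 1)),
                  data = df, method = "ML",
                  control = nlme::lmeControl(opt = "optim"))
  m2 <- nlme::lme(y ~ t,
                  random = list(all = nlme::pdIdent(~ Z - 1), subj = ~1),
                  data = df, method = "ML",
                  control = nlme::lmeControl(opt = "optim"))
  expect_equal(fit_lmms(pr, 1, b)$loglik_ml, as.numeric(logLik(m1)),
               tolerance = 1e-5)
  expect_equal(fit_lmms(pr, 2, b)$loglik_ml, as.numeric(logLik(m2)),
               tolerance = 1e-5)
})
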