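test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)                     # single p
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))     # ranks cancel
  set.seed(14)
  for (r in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # missing p-values excluded and reinserted
  p <- c(0.01, NA, 0.04, 0.03, NA)
  out <- adjust_bh(p)
  expect_true(all(is.na(out[c(2, 5)])))
  expect_equal(out[!is.na(p)], bh_oracle(p[!is.na(p)]),
               tolerance = 1e-12)
  # monotone and >= p
  expect_true(all(out >= p, na.rm = TRUE))
})

de_profile <- function(n_subj = 30, group_sizes = c(10, 20), f) {
  d <- make_design(n_subj, group_sizes = group_sizes)
  data.frame(subject = d$subject, time = d$time, group = d$group,
             value = f(d))
}

test_that("time test: strong trends are detected, equal fits give p = 1", {
  set.seed(31)
  # slope 5x noise SD over the range
  ps <- replicate(30, {
    pr <- de_profile(f = function(d) 0.5 * d$time + rnorm(180, sd = 0.1))
    lmmsde_test(pr, "time")$p
  })
  expect_true(all(ps < 1e-4))
  # flat truth: identical log-likelihood limit gives statistic ~ 0
  pr0 <- de_profile(f = function(d) rep(1, 180))
  r0 <- lmmsde_test(pr0, "time")
  expect_lt(r0$statistic, 1e-6)
  expect_equal(r0$p, 1, tolerance = 1e-6)
})

test_that("group test needs a contrast and detects mean offsets", {
  set.seed(32)
  pr <- de_profile(f = function(d)
    0.8 * (d$group == "g2") + rnorm(180, sd = 0.2))
  expect_lt(lmmsde_test(pr, "group")$p, 1e-4)
  pr1 <- pr; pr1$group <- "g1"
  expect_error(lmmsde_test(pr1, "group"), ">= 2 groups")
  prn <- pr; prn$group <- NULL
  expect_error(lmmsde_test(prn, "group"), "group annotation")
})

test_that("interaction test flags opposite slopes", {
  set.seed(33)
  pr <- de_profile(f = function(d)
    0.4 * d$time * ifelse(d$group == "g1", 1, -1) + rnorm(180, sd = 0.2))
  expect_lt(lmmsde_test(pr, "interaction")$p, 1e-4)
  # identical trajectories: interaction should not fire
  set.seed(34)
  pvals <- replicate(20, {
    pr2 <- de_profile(f = function(d) sin(d$time) + rnorm(180, sd = 0.3))
    lmmsde_test(pr2, "interaction")$p
  })
  expect_gte(mean(pvals > 0.05), 0.8)
})

test_that("full-model log-likelihood dominates the null's", {
  set.seed(35)
  for (r in 1:10) {
    pr <- de_profile(f = function(d) rnorm(180, sd = 0.5))
    for (eff in c("time", "group", "interaction")) {
      res <- lmmsde_test(pr, eff)
      expect_gte(res$loglik_full, res$loglik_null - 1e-6)
    }
  }
})

test_that("type-I error at 0.05 is held or conservative under the null", {
  # moderate replicate count here; the acceptance suite re-checks at 1000
  sc <- sim_scenario("time", 1, 1.5, sigma0 = 0.4, n_profiles = 300,
                     n_de = 0)
  ds <- simulate_dataset(sc, seed = 99, index = 1)
  for (eff in c("time", "group", "interaction")) {
    res <- lmmsde(ds$experiment, effects = eff)
    frac <- mean(res$p < 0.05, na.rm = TRUE)
    se <- sqrt(0.05 * 0.95 / sum(!is.na(res$p)))
    expect_lte(frac, 0.05 + 3 * se)
  }
})

test_that("spline-df accounting switches between variance and fixed modes", {
  set.seed(36)
  pr <- de_profile(f = function(d) 0.2 * d$time + rnorm(180, sd = 0.3))
  b <- spline_basis(pr$time)
  K <- length(b$knots)
  r_rand <- lmmsde_test(pr, "time", basis = b, spline_df = "random")
  r_fix <- lmmsde_test(pr, "time", basis = b, spline_df = "fixed")
  expect_equal(r_rand$df, 2)
  expect_equal(r_fix$df, 1 + K)
  r_int <- lmmsde_test(pr, "interaction", basis = b)
  expect_equal(r_int$df, 2)
  expect_equal(lmmsde_test(pr, "group", basis = b)$df, 1)
})

test_that("de pipeline adjusts within effect and respects filter_first", {
  sc <- sim_scenario("time", 1, 2, sigma0 = 0.3, n_profiles = 40,
                     n_de = 15)
  ds <- simulate_dataset(sc, seed = 5, index = 1)
  res <- lmmsde(ds$experiment, effects = c("time", "group"))
  expect_setequal(unique(res$effect), c("time", "group"))
  for (eff in unique(res$effect)) {
    sub <- res[res$effect == eff, ]
    expect_identical(sub$adj_p, adjust_bh(sub$p))
  }
  expect_error(lmmsde(ds$experiment, effects = character(0)), "no effects")
  expect_error(lmmsde(ds$experiment, effects = "shape"), "unknown effect")
  # filtering first on all-null data reduces the number of tested
  # molecules while significance stays controlled
  sc0 <- sim_scenario("time", 1, 1.5, sigma0 = 0.4, n_profiles = 80,
                      n_de = 0)
  ds0 <- simulate_dataset(sc0, seed = 8, index = 1)
  res_f <- lmmsde(ds0$experiment, effects = "time", filter_first = TRUE)
  expect_lt(length(unique(res_f$molecule)), 80)
  expect_lte(mean(res_f$significant), 0.1)
})
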