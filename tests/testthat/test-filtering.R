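test_that("filter statistics match direct evaluation on a 6-cell matrix", {
  # 2 subjects x 3 times, y1 = (1,2,3), y2 = (1,4,3)
  vals <- matrix(c(1, 2, 3, 1, 4, 3), nrow = 1)
  exp <- tc_experiment(vals, subject = rep(c("a", "b"), each = 3),
                       time = rep(c(0, 1, 2), 2))
  st <- filter_statistics(exp)
  # direct evaluation of the three formulas
  sT <- mean(c(sd(c(1, 1)), sd(c(2, 4)), sd(c(3, 3))))
  sI <- mean(c(sd(c(1, 2, 3)), sd(c(1, 4, 3))))
  sM <- sd(c(1, 2, 3, 1, 4, 3))
  expect_equal(st$sT, sT)
  expect_equal(st$sI, sI)
  expect_equal(st$sM, sM)
  expect_equal(st$RT, sT / sM)
  expect_equal(st$RI, 1 - sI / sM)
})

test_that("degenerate and structured profiles get the expected labels", {
  d <- make_design(n_subj = 4, times = c(0, 1, 2))
  vals <- rbind(
    constant = rep(5, 12),
    # identical across subjects at every time, varying over time
    shared = rep(c(1, 7, 3), 4))
  exp <- tc_experiment(vals, subject = d$subject, time = d$time)
  st <- filter_statistics(exp)
  expect_equal(st$label[1], "degenerate")  # sM = 0
  expect_equal(st$sT[2], 0)                # per-time SDs all zero
  expect_equal(st$RT[2], 0)
})

test_that("missing cells shrink denominators and can exclude a molecule", {
  d <- make_design(n_subj = 3, times = c(0, 1, 2))
  y <- c(1, NA, 3, 2, NA, 4, 3, NA, 5)  # time 1 entirely missing
  exp <- tc_experiment(rbind(a = y, b = rnorm(9)),
                       subject = d$subject, time = d$time)
  st <- filter_statistics(exp)
  # the empty time point is skipped from the per-time mean
  expect_equal(st$sT[1], mean(c(sd(c(1, 2, 3)), sd(c(3, 4, 5)))))
  expect_equal(st$missing_fraction[1], 1 / 3)
  # missing rule: present in 2 of 6 time points -> removed
  exp2 <- make_noise_experiment(n_mol = 60, n_subj = 6)
  exp2$values[1, exp2$time > 0.5] <- NA  # 4/6 missing
  fl <- filter_experiment(exp2, max_missing = 0.5, seed = 1)
  expect_equal(fl$report$label[1], "excluded_missing")
  expect_false("m001" %in% rownames(fl$experiment$values))
})

test_that("two-component classification separates planted ratio blobs", {
  set.seed(11)
  pts <- rbind(
    cbind(rnorm(100, 0.35, 0.05), rnorm(100, 0.05, 0.05)),
    cbind(rnorm(100, 0.95, 0.05), rnorm(100, 0.40, 0.05)))
  st <- data.frame(molecule = paste0("m", 1:200),
                   sT = NA, sI = NA, sM = 1,
                   RT = pts[, 1], RI = pts[, 2],
                   missing_fraction = 0, label = "unclassified",
                   stringsAsFactors = FALSE)
  out <- classify_informative(st, seed = 5)
  expect_gte(mean(out$label[1:100] == "informative"), 0.95)
  expect_gte(mean(out$label[101:200] == "noninformative"), 0.95)
})

test_that("identical ratio points fall back to all-informative", {
  st <- data.frame(molecule = c("a", "b", "c"), sT = 1, sI = 1, sM = 1,
                   RT = 0.5, RI = 0.1, missing_fraction = 0,
                   label = "unclassified", stringsAsFactors = FALSE)
  expect_warning(out <- classify_informative(st), "fell back")
  expect_true(all(out$label == "informative"))
})

test_that("pure-noise profiles have RT near 1 and RI near 0", {
  exp <- make_noise_experiment(n_mol = 1000, n_subj = 20, seed = 42)
  st <- filter_statistics(exp)
  expect_lt(abs(mean(st$RT) - 1), 0.05)
  expect_lt(abs(mean(st$RI) - 0), 0.05)
})

test_that("a strong time trend drives RT well below 1", {
  exp <- make_noise_experiment(n_mol = 300, n_trend = 300, slope = 1,
                               sd = 0.05, n_subj = 10, seed = 9)
  st <- filter_statistics(exp)
  expect_gte(mean(st$RT < 0.5), 0.99)
})

test_that("per-condition rule keeps molecules informative in any group", {
  # 60 molecules; signal molecules have a clear trend. Molecule m001 has
  # signal only in group 2: non-informative in g1, informative in g2.
  set.seed(21)
  d <- make_design(n_subj = 20, group_sizes = c(10, 10))
  n_mol <- 60
  vals <- matrix(rnorm(n_mol * length(d$subject), sd = 0.3),
                 n_mol, length(d$subject))
  trend <- d$time
  vals[2:30, ] <- vals[2:30, ] + rep(trend, each = 29)  # both groups
  g2 <- d$group == "g2"
  vals[1, g2] <- vals[1, g2] + trend[g2]                # g2 only
  rownames(vals) <- sprintf("m%03d", 1:n_mol)
  exp <- tc_experiment(vals, d$subject, d$time, d$group)
  fl <- filter_experiment(exp, per_group = TRUE, seed = 3)
  labs <- sapply(fl$report$per_group, function(r) r$label[1])
  expect_true("informative" %in% labs)     # informative in group 2
  expect_true("m001" %in% rownames(fl$experiment$values))
  # pooled classification on the same data is a single run
  fl2 <- filter_experiment(exp, per_group = FALSE, seed = 3)
  expect_s3_class(fl2$report, "data.frame")
})

test_that("removal never alters the survivors' statistics", {
  exp <- make_noise_experiment(n_mol = 120, n_trend = 60, slope = 1,
                               sd = 0.3, seed = 5)
  fl <- filter_experiment(exp, seed = 2)
  st_before <- filter_statistics(exp)
  st_after <- filter_statistics(fl$experiment)
  keep <- match(st_after$molecule, st_before$molecule)
  expect_equal(st_after$RT, st_before$RT[keep])
  expect_equal(st_after$RI, st_before$RI[keep])
})
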