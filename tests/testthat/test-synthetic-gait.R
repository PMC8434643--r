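test_that("pattern registry holds four distinct normalized templates", {
  pats <- gait_patterns()
  expect_length(pats, 4L)
  for (p in pats) {
    for (k in seq_len(p$phase_count)) {
      expect_equal(sum(p$template[, , k]), 1)
      expect_true(all(p$template[, , k] >= 0))
    }
  }
  nms <- names(pats)
  for (i in seq_along(nms)) {
    for (j in seq_len(i - 1)) {
      diffs <- abs(pats[[i]]$template[, , 1] - pats[[j]]$template[, , 1])
      expect_gt(max(diffs), 0) # pairwise distinct on at least one cell
    }
  }
})

test_that("generated sequences peak at the requested total force", {
  for (nm in names(gait_patterns())) {
    s <- generate_sequence(nm, peak_force = 30, seed = 5)
    total <- apply(s$frames, 3, sum) * 25
    expect_gte(max(total), 29.7)
    expect_lte(max(total), 30.3)
    expect_true(all(s$frames >= 0))
  }
})

test_that("sequence generation is deterministic per seed", {
  a <- generate_sequence("normal", seed = 42)
  b <- generate_sequence("normal", seed = 42)
  c <- generate_sequence("normal", seed = 43)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))
})

test_that("unknown pattern names are rejected by the registry", {
  expect_error(generate_sequence("moonwalk"), "unknown gait pattern")
})

test_that("noise-free cell pressures stay inside the calibrated span", {
  for (nm in names(gait_patterns())) {
    s <- generate_sequence(nm, peak_force = 45, seed = 3, jitter = 0.06)
    expect_lte(max(s$frames), 0.25)
  }
})

test_that("additive noise follows f = a + omega * b with zero-noise identity", {
  s <- generate_sequence("normal", seed = 1)
  expect_identical(add_noise(s, 0), s)

  # omega scales the sd of the perturbation (constant-level sequence)
  const <- pressure_sequence(array(1, dim = c(6, 6, 280)), sample_rate = 100)
  noisy <- add_noise(const, omega = 0.1, seed = 9)
  pert <- as.vector(noisy$frames - const$frames)
  expect_length(pert, 10080L)
  expect_equal(sd(pert), 0.1, tolerance = 0.05)

  n1 <- add_noise(s, omega = 0.05, seed = 4)
  n2 <- add_noise(s, omega = 0.05, seed = 4)
  expect_identical(n1$frames, n2$frames)
  expect_true(all(n1$frames >= 0))
  expect_error(add_noise(s, -1), "omega")
})

test_that("proportion sample size reproduces the cohort calculation", {
  expect_identical(sample_size(1.645, 0.5, 0.15), 30L)
  expect_identical(sample_size(1.645, 0.5, 0.075), 120L)
  # p = 0.5 maximizes n for fixed z and e
  n_half <- sample_size(1.645, 0.5, 0.15)
  for (p in c(0.1, 0.3, 0.7, 0.9)) {
    expect_lte(sample_size(1.645, p, 0.15), n_half)
  }
  # monotone: non-increasing in e, non-decreasing in z
  es <- c(0.05, 0.1, 0.15, 0.2)
  expect_true(all(diff(sapply(es, function(e) sample_size(1.645, 0.5, e))) <= 0))
  zs <- c(1.28, 1.645, 1.96, 2.58)
  expect_true(all(diff(sapply(zs, function(z) sample_size(z, 0.5, 0.15))) >= 0))
  expect_error(sample_size(1.645, 0, 0.15), "p must")
  expect_error(sample_size(1.645, 0.5, 0), "e must")
})

test_that("generated cohorts match the recruitment structure", {
  coh <- generate_cohort(30, seed = 2)
  expect_equal(nrow(coh), 30L)
  expect_equal(sum(coh$gender == "F"), 15L)
  expect_equal(sum(coh$gender == "M"), 15L)
  expect_true(all(coh$age >= 16 & coh$age <= 45))
  expect_equal(length(unique(coh$age_group)), 6L)
  expect_true(all(coh$weight >= 43 & coh$weight <= 84))
  expect_true(all(coh$left_pressure + coh$right_pressure <= coh$weight + 5))
  expect_true(all(coh$left_pressure < coh$weight))
  expect_true(all(coh$right_pressure < coh$weight))
  expect_identical(coh, generate_cohort(30, seed = 2))
  expect_error(generate_cohort(1), ">= 2")
})

test_that("datasets are balanced and assign 20 trials per subject", {
  ds <- generate_gait_dataset(n_trials = 600, seed = 6)
  expect_true(all(table(ds$labels) == 150L))
  expect_true(all(table(ds$subjects) == 20L))
  expect_true(all(vapply(ds$trials, function(s) all(s$frames >= 0), logical(1))))
})

test_that("classes are separable by a nearest-centroid oracle at low noise", {
  ds <- generate_gait_dataset(n_trials = 200, omega = 0.05, seed = 8)
  expect_gte(nearest_centroid_accuracy(ds), 0.95)
})
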