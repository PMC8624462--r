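test_that("rr_components handles degenerate and hand-computable inputs", {
  d <- expand.grid(session = 1:2, operator = 1:3, subject = 1:2)
  d$value <- 7
  comp <- rr_components(d)
  expect_equal(comp$s_r, 0)
  expect_equal(comp$s_L, 0)
  expect_equal(comp$s_R, 0)

  # single operator, each subject's two sessions at {0, 2}: pooled
  # within-cell variance 2
  d2 <- data.frame(subject = rep(1:2, each = 2), operator = 1,
                   value = c(0, 2, 0, 2))
  expect_warning(comp2 <- rr_components(d2), "single operator")
  expect_equal(comp2$s_r, sqrt(2))
  expect_equal(comp2$s_R, sqrt(2))

  expect_error(rr_components(data.frame(subject = 1:4, operator = 1,
                                        value = rnorm(4))),
               "2 subjects|replicates")
  expect_error(rr_components(data.frame(subject = c(1, 2), operator = 1,
                                        value = c(0, 1))), "replicates")
})

test_that("rr_components matches the ANOVA oracle on balanced data", {
  set.seed(14)
  for (k in 1:25) {
    d <- random_rr_instance(sample(2:3, 1), sample(3:6, 1),
                            sample(2:3, 1))
    got <- suppressWarnings(rr_components(d))
    want <- anova_rr_oracle(d)
    expect_equal(got$s_r, want$s_r, tolerance = 1e-12)
    expect_equal(got$s_L, want$s_L, tolerance = 1e-12)
    expect_equal(got$s_R, want$s_R, tolerance = 1e-12)
  }
})

test_that("RR statistics are invariant to labels, order and location", {
  set.seed(15)
  d <- random_rr_instance(3, 6, 2)
  base <- rr_components(d)

  perm <- d[sample(nrow(d)), ]
  perm$operator <- c(3, 1, 2)[perm$operator]
  perm$subject <- sample(6)[perm$subject]
  shuffled <- rr_components(perm)
  expect_equal(shuffled$s_r, base$s_r, tolerance = 1e-12)
  expect_equal(shuffled$s_L, base$s_L, tolerance = 1e-12)

  shifted <- d
  shifted$value <- shifted$value + 123.456 * (shifted$subject == 2)
  loc <- rr_components(shifted)
  expect_equal(loc$s_r, base$s_r, tolerance = 1e-10)
  expect_equal(loc$s_L, base$s_L, tolerance = 1e-10)

  expect_gte(base$s_R, base$s_r)
})

test_that("missing cells degrade gracefully", {
  set.seed(16)
  d <- random_rr_instance(3, 5, 2)
  # drop one replicate (cell keeps contributing to means, not to s_r)
  d_miss <- d[-1, ]
  comp <- rr_components(d_miss)
  expect_equal(comp$n_cells_used, 14)
  expect_true(is.finite(comp$s_R))
  # drop a whole operator for one subject: s_L still estimable
  d_op <- d[!(d$subject == 1 & d$operator == 3), ]
  expect_true(is.finite(rr_components(d_op)$s_L))
})

test_that("reliability classification follows the 1 mm / 2 mm clinical bands", {
  expect_equal(classify_reliability(2.05, 3.40), "caution")
  expect_equal(classify_reliability(0.24, 0.35), "acceptable")
  expect_equal(classify_reliability(1.27, 1.51), "useful")
  # boundaries are inclusive
  expect_equal(classify_reliability(1.00, 0.90), "acceptable")
  expect_equal(classify_reliability(2.00, 1.10), "useful")
  expect_equal(classify_reliability(0.10, 2.01), "caution")
  expect_error(classify_reliability(-0.1, 0.5), "non-negative")
})

test_that("sample_size reproduces the design calculation and its structure", {
  expect_identical(sample_size(0.15, 6), 17L)
  expect_identical(sample_size(0.15, 2), 85L)
  # doubling (repetitions - 1) halves the unrounded requirement
  a <- 1.96^2 / (2 * 0.1^2 * (3 - 1))
  b <- 1.96^2 / (2 * 0.1^2 * (5 - 1))
  expect_equal(a / b, 2)
  expect_error(sample_size(0, 6), "between 0 and 1")
  expect_error(sample_size(0.15, 1), ">= 2")
})

test_that("rr_table covers every estimable stratum with coherent CIs", {
  sim <- simulate_annotations(simulation_truth(seed = 31), 6, 3, 2)
  frames <- fh_frames(sim$dataset)
  rr <- rr_table(sim$dataset, frames)
  expect_equal(nrow(rr), 33 * 3)
  expect_true(all(rr$s_R >= rr$s_r - 1e-12))
  expect_equal(rr$ci_repeat, 2 * rr$s_r)
  expect_equal(rr$ci_repro, 2 * rr$s_R)
  expect_true(all(abs(rr$s_R^2 - (rr$s_r^2 + rr$s_L^2)) < 1e-10))

  # a noise-free study has identically zero dispersion, all acceptable
  tr0 <- simulation_truth(sigma_r = 0, sigma_L = 0, seed = 32)
  sim0 <- simulate_annotations(tr0, 3, 3, 2)
  rr0 <- rr_table(sim0$dataset, fh_frames(sim0$dataset))
  expect_lt(max(rr0$ci_repro), 1e-9)
  expect_true(all(rr0$reliability_class == "acceptable"))
})

test_that("rr_table is invariant under a global rigid motion", {
  set.seed(33)
  sim <- simulate_annotations(simulation_truth(seed = 33), 5, 3, 2)
  rr1 <- rr_table(sim$dataset, fh_frames(sim$dataset))
  moved <- apply_rigid(random_rigid(), sim$dataset)
  # the superior hint must move with the data; use the Menton fallback
  rr2 <- rr_table(moved, fh_frames(moved, superior_hint = NULL))
  ord <- function(t) t[order(t$landmark, t$axis), ]
  expect_equal(ord(rr2)$s_r, ord(rr1)$s_r, tolerance = 1e-8)
  expect_equal(ord(rr2)$s_R, ord(rr1)$s_R, tolerance = 1e-8)
})

test_that("Bland-Altman deviations are centred with ~95% coverage limits", {
  sim <- simulate_annotations(simulation_truth(seed = 41), 8, 3, 2)
  frames <- fh_frames(sim$dataset)
  ba <- bland_altman(sim$dataset, "Na", "x", frames)
  sums <- tapply(ba$deviation, ba$subject_id, sum)
  expect_lt(max(abs(sums)), 1e-10)
  lim <- attr(ba, "limits")
  expect_equal(lim[2], -lim[1])

  # noise-free data: all deviations and limits vanish
  sim0 <- simulate_annotations(simulation_truth(sigma_r = 0, sigma_L = 0,
                                                seed = 42), 3, 3, 2)
  ba0 <- bland_altman(sim0$dataset, "Na", "z", fh_frames(sim0$dataset))
  expect_lt(max(abs(ba0$deviation)), 1e-9)
  expect_lt(attr(ba0, "limits")[2], 1e-9)

  # Gaussian data: close to 95% of deviations inside +/- 2 s_R
  set.seed(43)
  sim2 <- simulate_annotations(simulation_truth(seed = 43), 20, 3, 2)
  frames2 <- fh_frames(sim2$dataset)
  cover <- sapply(c("Na", "Me", "S", "Go-L"), function(lm) {
    b <- bland_altman(sim2$dataset, lm, "y", frames2)
    mean(abs(b$deviation) <= attr(b, "limits")[2])
  })
  expect_true(all(cover > 0.85))
})
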