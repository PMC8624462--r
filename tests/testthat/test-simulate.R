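test_that("the template satisfies its anatomical ordering invariants", {
  tpl <- default_template()
  expect_equal(nrow(tpl), 33)
  expect_setequal(rownames(tpl), default_catalog()$name)
  d_po <- sqrt(sum((tpl["Po-L", ] - tpl["Po-R", ])^2))
  expect_gt(d_po, 60); expect_lt(d_po, 70)
  expect_lt(tpl["Me", "z"], tpl["Na", "z"])
  # conventional FH plane roughly axial
  fh <- plane_from_points(tpl["Or-L", ], tpl["Po-R", ], tpl["Po-L", ],
                          orient_hint = c(0, 0, 1))
  expect_lt(acos(fh$normal[3]) * 180 / pi, 15)
  # IAF medial to porion
  expect_lt(abs(tpl["IAF-L", "x"]), abs(tpl["Po-L", "x"]))
  # bilateral pairs mirror-plausible
  expect_lt(abs(tpl["Or-L", "x"] + tpl["Or-R", "x"]), 10)
})

test_that("simulation is deterministic and produces the full design", {
  tr <- simulation_truth(seed = 61)
  a <- simulate_annotations(tr, 20, 3, 2)
  b <- simulate_annotations(tr, 20, 3, 2)
  expect_identical(a$dataset$observations, b$dataset$observations)
  expect_identical(a$truth$realized_cant_deg, b$truth$realized_cant_deg)
  expect_equal(nrow(a$dataset$observations), 20 * 3 * 2 * 33)
  expect_equal(unname(a$dataset$design), c(20, 3, 2))
  c2 <- simulate_annotations(tr, 20, 3, 2, seed = 62)
  expect_false(identical(a$dataset$observations$x,
                         c2$dataset$observations$x))
})

test_that("zero dispersion collapses repetitions and the downstream table", {
  tr <- simulation_truth(sigma_r = 0, sigma_L = 0,
                         pose = list(max_rot_deg = 0, max_trans_mm = 0),
                         seed = 63)
  sim <- simulate_annotations(tr, 2, 3, 2)
  obs <- sim$dataset$observations
  spread <- tapply(obs$x, paste(obs$subject_id, obs$landmark),
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
  rr <- rr_table(sim$dataset, fh_frames(sim$dataset))
  expect_lt(max(rr$ci_repro), 1e-9)
})

test_that("generative variance components are recovered at scale", {
  tr <- simulation_truth(sigma_r = 0.25, sigma_L = 0.15, seed = 64)
  sims <- lapply(1:8, function(k) {
    simulate_annotations(tr, 60, 3, 2, seed = 64 + k)
  })
  est <- sapply(sims, function(s) {
    rr <- rr_table(s$dataset, fh_frames(s$dataset))
    c(mean(rr$s_r), mean(rr$s_R))
  })
  expect_equal(mean(est[1, ]) / 0.25, 1, tolerance = 0.05)
  expect_equal(mean(est[2, ]) / sqrt(0.25^2 + 0.15^2), 1, tolerance = 0.10)
})

test_that("the paperlike scenario encodes the documented study conditions", {
  tr <- paperlike_scenario()
  out <- tr$outliers
  expect_equal(length(unique(out$landmark)), 2)
  expect_setequal(unique(out$landmark), c("MF-L", "MF-R"))
  expect_equal(length(unique(out$subject)), 17)
  expect_setequal(unique(out$subject), 4:20)
  expect_true(all(out$operator == "O3" & out$session == "R1"))
  expect_equal(nrow(out), 34)
  # orbitale noisiest along x, tight along z
  expect_gt(tr$sigma_r["Or-L", "x"], tr$sigma_r["Or-L", "z"])
  expect_gt(tr$sigma_r["Po-R", "x"], tr$sigma_r["Po-R", "z"])
  expect_gt(tr$sigma_r["Go-L", "z"], tr$sigma_r["Go-L", "x"])
})

test_that("injected cant is recovered exactly when noise vanishes", {
  tr <- paperlike_scenario()
  tr$sigma_r[] <- 0
  tr$sigma_L[] <- 0
  tr$outliers <- NULL
  sim <- simulate_annotations(tr, 6, 3, 2, seed = 65)
  par <- parallelism(sim$dataset)
  realized <- sim$truth$realized_cant_deg[par$per_subject$subject_id]
  expect_lt(max(abs(par$per_subject$angle_deg - unname(realized))), 0.05)
})

test_that("invalid truths are rejected", {
  expect_error(simulation_truth(sigma_r = -1), "non-negative")
  expect_error(simulation_truth(subject_sd = -1), "non-negative")
  bad <- data.frame(operator = "O1", landmark = "nope", session = "R1",
                    subject = 1, dx = 1, dy = 0, dz = 0)
  expect_error(simulation_truth(outliers = bad), "not in template")
  expect_error(simulate_annotations(simulation_truth(), 2, 3, 2),
               "seed")
})
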