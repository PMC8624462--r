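test_that("session planes pass through their defining landmarks", {
  sim <- simulate_annotations(simulation_truth(seed = 71), 3, 3, 2)
  ds <- sim$dataset
  obs <- ds$observations
  for (r in list(c("S01", "O1", "R1"), c("S02", "O3", "R2"))) {
    pl <- session_planes(ds, r[1], r[2], r[3])
    sel <- obs$subject_id == r[1] & obs$operator_id == r[2] &
      obs$session_id == r[3]
    pt <- function(nm) {
      i <- which(sel & obs$landmark == nm)
      c(obs$x[i], obs$y[i], obs$z[i])
    }
    for (nm in c("Or-L", "Po-R", "Po-L")) {
      expect_lt(abs(signed_vertical_distance(pl$conventional, pt(nm))),
                1e-9)
    }
    for (nm in c("Or-R", "Or-L")) {
      expect_lt(abs(signed_vertical_distance(pl$novel, pt(nm))), 1e-9)
    }
    expect_lt(abs(signed_vertical_distance(
      pl$novel, midpoint(pt("IAF-L"), pt("IAF-R")))), 1e-9)
  }
})

test_that("a session missing a defining landmark is skipped with a reason", {
  sim <- simulate_annotations(simulation_truth(seed = 72), 3, 3, 2)
  obs <- sim$dataset$observations
  drop <- obs$subject_id == "S01" & obs$operator_id == "O1" &
    obs$session_id == "R1" & obs$landmark == "Po-L"
  ds <- annotation_dataset(obs[!drop, ], sim$dataset$catalog)
  expect_error(session_planes(ds, "S01", "O1", "R1"), "Po-L")
  v <- vertical_rr(ds)
  expect_length(attr(v, "skipped_sessions"), 1)
  expect_match(attr(v, "skipped_sessions"), "Po-L")
})

test_that("an IAF pair lifted above the orbital line produces the analytic tilt", {
  # conventional plane z = 0; novel plane tilts by atan(t/d) when mid-IAF
  # sits t above the plane at distance d behind the inter-orbital line
  orl <- c(28, -65, 0); orr <- c(-28, -65, 0)
  por <- c(-32.5, 10, 0); pol <- c(32.5, 10, 0)
  t_mm <- 4
  iafl <- c(12, 8, t_mm); iafr <- c(-12, 8, t_mm)
  d <- 8 - (-65)
  conv <- plane_from_points(orl, por, pol, orient_hint = c(0, 0, 1))
  nov <- plane_from_points(orr, orl, midpoint(iafl, iafr),
                           orient_hint = c(0, 0, 1))
  expect_equal(angle_between_planes(conv, nov),
               atan(t_mm / d) * 180 / pi, tolerance = 1e-10)
})

test_that("noise-free studies give identically zero vertical dispersion", {
  tr <- simulation_truth(sigma_r = 0, sigma_L = 0, seed = 73)
  sim <- simulate_annotations(tr, 3, 3, 2)
  v <- vertical_rr(sim$dataset)
  expect_equal(nrow(v$conventional), 33)
  expect_equal(nrow(v$novel), 33)
  expect_lt(max(v$conventional$ci_repro), 1e-9)
  expect_lt(max(v$novel$ci_repro), 1e-9)
})

test_that("defining landmarks have zero vertical R&R under their own plane", {
  sim <- simulate_annotations(simulation_truth(seed = 74), 5, 3, 2)
  v <- vertical_rr(sim$dataset)
  conv <- v$conventional
  for (nm in c("Or-L", "Po-R", "Po-L")) {
    expect_lt(conv$ci_repro[conv$landmark == nm], 1e-9)
  }
  nov <- v$novel
  for (nm in c("Or-R", "Or-L")) {
    expect_lt(nov$ci_repro[nov$landmark == nm], 1e-9)
  }
  # non-defining landmarks do accumulate vertical error
  expect_gt(conv$ci_repro[conv$landmark == "Me"], 1e-3)
})

test_that("vertical tables are invariant under a global rigid motion", {
  set.seed(75)
  sim <- simulate_annotations(simulation_truth(seed = 75), 4, 3, 2)
  v1 <- vertical_rr(sim$dataset)
  rig <- random_rigid()
  moved <- apply_rigid(rig, sim$dataset)
  v2 <- vertical_rr(moved, superior_hint = drop(rig$R %*% c(0, 0, 1)))
  ord <- function(t) t[order(t$landmark), ]
  expect_equal(ord(v2$conventional)$s_R, ord(v1$conventional)$s_R,
               tolerance = 1e-8)
  expect_equal(ord(v2$novel)$s_r, ord(v1$novel)$s_r, tolerance = 1e-8)
})

test_that("coplanar defining landmarks make the two vertical tables agree", {
  # noise confined to the template FH plane for the five defining
  # landmarks keeps every session's conventional and novel plane equal to
  # that same plane, so vertical measurements agree landmark by landmark
  set.seed(76)
  tpl <- default_template()
  fh <- plane_from_points(tpl["Or-L", ], tpl["Po-R", ], tpl["Po-L", ],
                          orient_hint = c(0, 0, 1))
  # make all five defining landmarks exactly coplanar, IAF on the plane
  for (nm in c("Or-R", "IAF-L", "IAF-R")) {
    tpl[nm, ] <- tpl[nm, ] - signed_vertical_distance(fh, tpl[nm, ]) *
      fh$normal
  }
  u <- tpl["Po-L", ] - tpl["Po-R", ]; u <- u / sqrt(sum(u^2))
  v_in <- cross_oracle(fh$normal, u)  # second in-plane direction
  rows <- list()
  for (su in c("S01", "S02", "S03")) {
    for (op in paste0("O", 1:3)) {
      for (se in c("R1", "R2")) {
        pts <- tpl
        defs <- c("Or-L", "Or-R", "Po-L", "Po-R", "IAF-L", "IAF-R")
        for (nm in defs) {
          pts[nm, ] <- pts[nm, ] + rnorm(1, sd = 0.5) * u +
            rnorm(1, sd = 0.5) * v_in
        }
        others <- setdiff(rownames(tpl), defs)
        pts[others, ] <- pts[others, ] +
          matrix(rnorm(3 * length(others), sd = 0.4), ncol = 3)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = su, operator_id = op, session_id = se,
          landmark = rownames(tpl), x = pts[, 1], y = pts[, 2],
          z = pts[, 3], stringsAsFactors = FALSE)
      }
    }
  }
  ds <- annotation_dataset(do.call(rbind, rows))
  v <- vertical_rr(ds)
  ord <- function(t) t[order(t$landmark), ]
  expect_equal(ord(v$novel)$s_r, ord(v$conventional)$s_r,
               tolerance = 1e-9)
  expect_equal(ord(v$novel)$s_R, ord(v$conventional)$s_R,
               tolerance = 1e-9)
})

test_that("parallelism agrees with angle_between_planes and rigid motion", {
  sim <- simulate_annotations(paperlike_scenario(), 6, 3, 2, seed = 77)
  ds <- sim$dataset
  par <- parallelism(ds)
  expect_true(all(par$per_subject$angle_deg >= 0 &
                    par$per_subject$angle_deg <= 90))
  # cross-module consistency for one subject
  su <- "S03"
  conv <- plane_from_points(mean_landmark(ds, su, "Or-L"),
                            mean_landmark(ds, su, "Po-R"),
                            mean_landmark(ds, su, "Po-L"),
                            orient_hint = c(0, 0, 1))
  nov <- plane_from_points(mean_landmark(ds, su, "Or-R"),
                           mean_landmark(ds, su, "Or-L"),
                           midpoint(mean_landmark(ds, su, "IAF-L"),
                                    mean_landmark(ds, su, "IAF-R")),
                           orient_hint = c(0, 0, 1))
  expect_equal(par$per_subject$angle_deg[par$per_subject$subject_id == su],
               angle_between_planes(conv, nov), tolerance = 1e-10)
  # 6 repetitions of both IAF landmarks per subject
  expect_equal(nrow(par$distances), 6 * 2 * 6)

  set.seed(78)
  rig <- random_rigid()
  moved <- apply_rigid(rig, ds)
  par2 <- parallelism(moved, superior_hint = drop(rig$R %*% c(0, 0, 1)))
  expect_equal(par2$per_subject$angle_deg, par$per_subject$angle_deg,
               tolerance = 1e-8)
  expect_equal(par2$summary$mean_abs_iaf_l_mm, par$summary$mean_abs_iaf_l_mm,
               tolerance = 1e-8)
})

test_that("IAF points on the conventional plane give zero distances and angle", {
  tr <- simulation_truth(sigma_r = 0, sigma_L = 0, asymmetry_sd = 0,
                         cant = list(type = "fixed", deg = 0), seed = 79)
  sim <- simulate_annotations(tr, 4, 3, 2)
  par <- parallelism(sim$dataset)
  expect_lt(max(abs(par$distances$distance)), 1e-9)
  expect_lt(max(par$per_subject$angle_deg), 1e-5)
  expect_equal(par$summary$mean_abs_angle_deg, mean(par$per_subject$angle_deg))
})
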