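test_that("plane_from_points recovers analytic normals and rejects degeneracy", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                          orient_hint = c(0, 0, 1))
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  pl2 <- plane_from_points(c(0, 0, 0), c(2, 0, 0), c(0, 0, 3),
                           orient_hint = c(0, 1, 0))
  expect_equal(pl2$normal, c(0, 1, 0), tolerance = 1e-12)
  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "degenerate")
  # all three defining points lie on the plane
  set.seed(11)
  for (k in 1:20) {
    pts <- matrix(rnorm(9, sd = 40), 3, 3)
    pl <- tryCatch(plane_from_points(pts[1, ], pts[2, ], pts[3, ]),
                   error = function(e) NULL)
    if (is.null(pl)) next
    expect_lt(max(abs(signed_vertical_distance(pl, pts))), 1e-9)
  }
})

test_that("plane orientation is permutation-invariant given a hint", {
  set.seed(3)
  pts <- matrix(rnorm(9, sd = 30), 3, 3)
  hint <- c(0, 0, 1)
  base <- plane_from_points(pts[1, ], pts[2, ], pts[3, ], hint)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    p <- plane_from_points(pts[perm[1], ], pts[perm[2], ], pts[perm[3], ],
                           hint)
    expect_equal(p$normal, base$normal, tolerance = 1e-10)
  }
})

test_that("signed vertical distance is signed and metric", {
  pl <- plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(signed_vertical_distance(pl, c(5, 5, 3)), 3)
  expect_equal(signed_vertical_distance(pl, c(5, 5, -3)), -3)
  expect_equal(signed_vertical_distance(pl, rbind(c(1, 2, 0.5),
                                                  c(0, 0, -2))),
               c(0.5, -2))
})

test_that("angle_between_planes is absolute, symmetric and analytic", {
  a <- plane(c(0, 0, 0), c(0, 0, 1))
  b <- plane(c(10, 0, 0), c(0, sin(5 * pi / 180), cos(5 * pi / 180)))
  expect_equal(angle_between_planes(a, a), 0)
  expect_equal(angle_between_planes(a, b), 5, tolerance = 1e-10)
  expect_equal(angle_between_planes(b, a), angle_between_planes(a, b))
  anti <- plane(c(0, 0, 0), c(0, 0, -1))
  expect_equal(angle_between_planes(a, anti), 0)
})

test_that("midpoint behaves as the arithmetic midpoint", {
  expect_equal(midpoint(c(0, 0, 0), c(2, 4, 6)), c(1, 2, 3))
  p <- c(-3, 2, 9)
  expect_equal(midpoint(p, p), p)
  q <- c(1, 1, 1)
  expect_equal(midpoint(p, q), midpoint(q, p))
})

test_that("the FH frame puts porions on the x axis and orbitale in-plane", {
  fr <- build_fh_frame(c(-40, 0, 0), c(40, 0, 0), c(30, -70, 0),
                       superior_hint = c(0, 0, 1))
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$x_axis, c(1, 0, 0))
  expect_equal(fr$y_axis, c(0, 1, 0))
  expect_equal(fr$z_axis, c(0, 0, 1))

  set.seed(7)
  for (k in 1:20) {
    rig <- random_rigid()
    mv <- function(p) drop(rig$R %*% p + rig$t)
    por_r <- mv(c(-32.5, 10, 0)); por_l <- mv(c(32.5, 10, 0))
    orb_l <- mv(c(28, -65, -2))
    fr <- build_fh_frame(por_r, por_l, orb_l,
                         superior_hint = drop(rig$R %*% c(0, 0, 1)))
    d <- sqrt(sum((por_l - por_r)^2))
    expect_equal(to_frame(fr, por_r), c(-d / 2, 0, 0), tolerance = 1e-9)
    expect_equal(to_frame(fr, por_l), c(d / 2, 0, 0), tolerance = 1e-9)
    expect_lt(abs(to_frame(fr, orb_l)[3]), 1e-9)
    # orthonormal right-handed triad
    R <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("to_frame is rigid: distances are preserved", {
  set.seed(21)
  fr <- build_fh_frame(c(-32.5, 10, 0), c(32.5, 10, 0), c(28, -65, -2))
  P <- matrix(rnorm(30, sd = 50), 10, 3)
  Q <- to_frame(fr, P)
  expect_equal(as.vector(dist(Q)), as.vector(dist(P)), tolerance = 1e-9)
  expect_equal(to_frame(fr, fr$origin), c(0, 0, 0))
})

test_that("mean_landmark averages usable observations only", {
  obs <- data.frame(subject_id = "S01", operator_id = c("O1", "O1", "O2"),
                    session_id = c("R1", "R2", "R1"), landmark = "Na",
                    x = c(0, 2, 100), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  ds <- annotation_dataset(obs)
  expect_equal(unname(mean_landmark(ds, "S01", "Na")),
               c(34, 0, 0))
  ds$observations$outlier_removed[3] <- TRUE
  expect_equal(unname(mean_landmark(ds, "S01", "Na")), c(1, 0, 0))
  expect_error(mean_landmark(ds, "S01", "Me"), "no usable")
})

test_that("fh_frames falls back to the Menton rule when no hint is given", {
  ds <- exact_dataset(n_subjects = 2)
  with_hint <- fh_frames(ds, superior_hint = c(0, 0, 1))
  no_hint <- fh_frames(ds, superior_hint = NULL)
  expect_equal(no_hint[["S01"]]$z_axis, with_hint[["S01"]]$z_axis,
               tolerance = 1e-12)
  me <- mean_landmark(ds, "S01", "Me")
  expect_lt(to_frame(no_hint[["S01"]], me)[3], 0)
})

test_that("frames and planes serialize to JSON", {
  fr <- build_fh_frame(c(-32.5, 10, 0), c(32.5, 10, 0), c(28, -65, -2))
  js <- jsonlite::fromJSON(geometry_json(fr))
  expect_equal(js$type, "frame")
  expect_equal(js$origin, c(0, 10, 0))
})
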