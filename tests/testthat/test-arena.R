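test_that("transform_point is the identity at the arena centre", {
  grid <- expand.grid(theta = 0:359, phi = 0:89)
  tp <- transform_point(grid$theta, grid$phi, agent_pose(), arena_config())
  expect_lt(max(abs(tp$theta - grid$theta)), 1e-9)
  expect_lt(max(abs(tp$phi - grid$phi)), 1e-9)
})

test_that("transform_point matches direct trigonometry in the collinear case", {
  # pose on the segment from centre towards azimuth 0; wall point straight
  # ahead at elevation 38: only the elevation changes
  tp <- transform_point(0, 38, agent_pose(0.6, 0), arena_config())
  expect_equal(tp$theta, 0)
  expect_equal(tp$phi, atan(1.5 * tan(38 * pi / 180) / 0.9) * 180 / pi)
  # floor-level points stay on the floor from any interior pose
  tp0 <- transform_point(c(10, 123, 300), c(0, 0, 0), agent_pose(0.4, -0.7))
  expect_equal(tp0$phi, c(0, 0, 0))
  expect_error(transform_point(10, 10, agent_pose(1.5, 0)), "inside")
})

test_that("elevation mapping is strictly monotone for a fixed azimuth", {
  phi <- seq(0, 89, by = 1)
  tp <- transform_point(rep(77, length(phi)), phi, agent_pose(0.3, 0.2))
  expect_true(all(diff(tp$phi) > 0))
})

test_that("rendering is exact for simple shapes seen from the centre", {
  pano <- centre_pano("rect_160x38")
  expect_identical(dim(pano), c(90L, 360L))
  expect_equal(sum(pano), 160 * 38)       # one pixel per square degree
  expect_true(all(pano %in% c(0, 1)))
  expect_true(all(render_panorama(list(), agent_pose()) == 0))
  wall <- shape_spec(cbind(c(0, 360, 360, 0), c(0, 0, 89.99, 89.99)))
  expect_true(all(render_panorama(wall, agent_pose()) == 1))
})

test_that("scanline rasteriser agrees with a point-in-polygon oracle off-centre", {
  skip_if_not_installed("pracma")
  arena <- arena_config()
  set.seed(7)
  shapes <- shape_library()[c("rect_160x38", "trapezoid_80", "double_triangle")]
  for (sh in shapes) {
    for (rep in 1:2) {
      pose <- agent_pose(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                         heading = runif(1, 0, 360))
      got <- render_panorama(sh, pose, arena)
      ref <- matrix(0, 90, 360)
      row_c <- 90.5 - 1:90
      col_c <- 1:360 - 180.5
      for (poly in sh$components) {
        dense <- mbnav:::sample_outline(poly, 0.1)
        tp <- transform_point(dense[, 1], dense[, 2], pose, arena)
        a <- mbnav:::unwrap_deg(((tp$theta - pose$heading + 180) %% 360) - 180)
        e <- tp$phi
        rows <- which(row_c <= max(e) & row_c >= min(e))
        for (k in floor((min(a) + 180) / 360):floor((max(a) + 180) / 360)) {
          ac <- col_c + 360 * k
          cols <- which(ac >= min(a) & ac <= max(a))
          if (!length(cols) || !length(rows)) next
          g <- expand.grid(y = row_c[rows], x = ac[cols])
          inside <- matrix(pracma::inpolygon(g$x, g$y, a, e), nrow = length(rows))
          ref[rows, cols] <- pmax(ref[rows, cols], inside)
        }
      }
      expect_identical(got, ref)
    }
  }
})

test_that("training path poses run from the centre to the feeder, facing ahead", {
  arena <- default_arena()
  poses <- training_path_poses(arena, 30)
  expect_length(poses, 30)
  d <- vapply(poses, function(p) sqrt(sum(p$position^2)), 0)
  expect_equal(d, seq(0, 0.6, length.out = 30))
  expect_true(all(vapply(poses, `[[`, 0, "heading") == 30))
  expect_equal(training_path_poses(arena, 1)[[1]]$position, c(0, 0))
  d2 <- vapply(training_path_poses(arena, 2), function(p)
    sqrt(sum(p$position^2)), 0)
  expect_equal(d2, c(0, 0.6))
  expect_error(training_path_poses(arena, 0))
})

test_that("FPM reference values follow the training geometry", {
  sh <- shape_library()
  expect_equal(compute_fpm(sh$rect_160x38, 30, "width"), 30 / 160)
  expect_equal(compute_fpm(sh$rect_160x38, 30, "area"), 30 / 160)
  # symmetric shape faced at its midline
  expect_equal(compute_fpm(sh$rect_80x38, 40, "width"), 0.5)
  expect_equal(compute_fpm(sh$double_triangle, 70, "area"), 0.5)
  # left edge and clamping
  expect_equal(compute_fpm(sh$rect_160x38, 0), 0)
  expect_equal(compute_fpm(sh$rect_160x38, -20), 0)
  expect_equal(compute_fpm(sh$rect_160x38, 400), 1)
  degenerate <- shape_spec(cbind(c(5, 5, 5), c(0, 1, 2)))
  expect_error(compute_fpm(degenerate, 10), "zero")
})

test_that("fpm_match_direction inverts compute_fpm", {
  sh <- shape_library()
  expect_equal(fpm_match_direction(0.1875, sh$rect_80x38, "width"), 15)
  expect_equal(fpm_match_direction(0.5, sh$rect_120x38, "width"), 60)
  expect_equal(fpm_match_direction(0, sh$rect_80x38), 0)
  for (nm in c("rect_80x38", "trapezoid_80", "triangle_160",
               "double_triangle")) {
    for (m in c("width", "area")) {
      for (f in seq(0.1, 0.9, by = 0.2)) {
        d <- fpm_match_direction(f, sh[[nm]], m)
        expect_equal(compute_fpm(sh[[nm]], sh[[nm]]$left_edge_azimuth + d, m),
                     f, tolerance = 1e-6)
      }
    }
  }
})
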