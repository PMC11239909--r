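test_that("slice_plane recovers analytic sections and topology", {
  cyl <- cylinder_mesh(r = 10, h = 40, ntheta = 128)
  loops <- slice_plane(cyl, c(0, 0, 17), c(0, 0, 1))
  expect_length(loops, 1)
  expect_true(loops[[1]]$closed)
  expect_lt(abs(polygon_area(loops[[1]]) - pi * 100) / (pi * 100), 0.01)

  # torus sliced through the hole plane: two loops
  tor <- torus_mesh(R = 50, r = 10)
  lt <- slice_plane(tor, c(0, 0, 0), c(0, 1, 0))
  expect_length(Filter(function(l) l$closed, lt), 2)

  # plane missing the mesh
  expect_length(slice_plane(cyl, c(0, 0, 100), c(0, 0, 1)), 0)

  # open boundary crossing yields an open polyline, flagged
  lo <- slice_plane(cyl, c(0, 0, 0), c(1, 0, 0))
  expect_true(any(!vapply(lo, function(l) l$closed, logical(1))))
})

test_that("polygon_area is exact and orientation-independent", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)
  th <- seq(0, 2 * pi, length.out = 1025)[-1025]
  gon <- cbind(10 * cos(th), 10 * sin(th))
  expect_lt(abs(polygon_area(gon) - pi * 100) / (pi * 100), 1e-4)
})

test_that("min_area_rect is exact on rectangles and rotation-invariant", {
  rect <- rbind(c(0, 0), c(20, 0), c(20, 10), c(0, 10))
  r0 <- min_area_rect(rect)
  expect_equal(c(r0$major, r0$minor), c(20, 10))

  a <- 37 * pi / 180
  Rm <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  r1 <- min_area_rect(rect %*% t(Rm))
  expect_equal(c(r1$major, r1$minor), c(20, 10), tolerance = 1e-6)

  th <- seq(0, 2 * pi, length.out = 513)[-513]
  ell <- cbind(10 * cos(th), 5 * sin(th))
  r2 <- min_area_rect(ell)
  expect_equal(c(r2$major, r2$minor), c(20, 10), tolerance = 0.005)

  expect_error(min_area_rect(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("min_area_rect is insensitive to vertex density on smooth loops", {
  for (n in c(64, 256, 1024)) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    ell <- cbind(8 * cos(th), 6 * sin(th))
    r <- min_area_rect(ell)
    expect_equal(r$major, 16, tolerance = 16 * 0.005)
    expect_equal(r$minor, 12, tolerance = 12 * 0.005)
  }
})

test_that("bounding rectangle bounds the loop area on convex sections", {
  cyl <- cylinder_mesh(r = 7, h = 30)
  sec <- section_series(cyl, c(0, 0, 0), c(0, 0, 1), step = 2, range = 25)
  tab <- sec$table
  expect_true(all(tab$area <= tab$rect_major * tab$rect_minor))
  expect_true(all(tab$rect_major * tab$rect_minor <= 4 * tab$area))
})

test_that("select_loop follows the reference and breaks ties by area", {
  tor <- torus_mesh(R = 50, r = 10)
  lt <- slice_plane(tor, c(0, 0, 0), c(0, 1, 0))
  picked <- select_loop(lt, c(50, 0, 0))
  expect_lt(abs(junctmorph:::loop_centroid3d(picked)[1] - 50), 2)
  picked2 <- select_loop(lt, c(-50, 0, 0))
  expect_lt(abs(junctmorph:::loop_centroid3d(picked2)[1] + 50), 2)

  # equidistant reference: the smaller-area loop wins
  big <- list(points = rbind(c(-2, -2), c(2, -2), c(2, 2), c(-2, 2)),
              points3d = cbind(rbind(c(-2, -2), c(2, -2), c(2, 2), c(-2, 2)), 0),
              closed = TRUE, basis = junctmorph:::orthobasis(c(0, 0, 1)))
  small <- big
  small$points <- big$points / 2
  small$points3d <- cbind(big$points / 2, 0)
  expect_equal(select_loop(list(big, small), c(0, 0, 0))$points, small$points)
})

test_that("section_series is constant on a cylinder and finds the hyperboloid neck", {
  cyl <- cylinder_mesh(r = 10, h = 50, ntheta = 128, nz = 60)
  sec <- section_series(cyl, c(0, 0, 0), c(0, 0, 1), step = 1, range = 45,
                        mode = "fixed")
  expect_lt(diff(range(sec$table$area)) / mean(sec$table$area), 0.01)

  j <- make_hourglass(junction_spec(neck_diameter = 20, neck_scale = 10,
                                    mesh_step = 0.5))
  sec <- section_series(j$mesh, j$base_point, j$axis, step = 0.5, range = 20)
  neck_at <- sec$table$station_s[which.min(sec$table$area)]
  expect_lt(abs(neck_at - j$truth$true_neck_station), 0.5)
  expect_lt(abs(min(sec$table$area) - pi * 100) / (pi * 100), 0.01)
})

test_that("adaptive mode tracks a bent tube where a fixed axis cannot", {
  tube <- elbow_mesh()
  sa <- section_series(tube, c(0, 0, 0), c(1, 0, 0), step = 1, range = 55,
                       mode = "adaptive")
  expect_gt(nrow(sa$table), 45)
  expect_lt(diff(range(sa$table$area)) / mean(sa$table$area), 0.05)

  sf <- section_series(tube, c(0, 0, 0), c(1, 0, 0), step = 1, range = 55,
                       mode = "fixed")
  fixed_spread <- diff(range(sf$table$area)) / mean(sf$table$area)
  expect_gt(fixed_spread, 0.2)  # fixed-axis sections diverge on the bend
})

test_that("section_series is deterministic and honours min_range", {
  j <- make_hourglass(junction_spec(neck_diameter = 16, mesh_step = 1,
                                    jitter_sd = 0.3, seed = 42))
  s1 <- section_series(j$mesh, j$base_point, j$axis, step = 0.5, range = 18)
  s2 <- section_series(j$mesh, j$base_point, j$axis, step = 0.5, range = 18)
  expect_identical(s1$table, s2$table)

  # series ends at the open stub: demanding sections beyond it must error
  expect_error(
    section_series(j$mesh, j$base_point, j$axis, step = 0.5, range = 60,
                   min_range = 50),
    "last valid station")
  expect_error(
    section_series(j$mesh, j$base_point + c(0, 0, 500), j$axis,
                   step = 0.5, range = 5),
    "misses the mesh")
})
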