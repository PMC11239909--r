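hourglass_sections <- function(d = 20, c_ = 10, mesh_step = 0.5, ...) {
  j <- make_hourglass(junction_spec(neck_diameter = d, neck_scale = c_,
                                    mesh_step = mesh_step, ...))
  list(j = j,
       sec = section_series(j$mesh, j$base_point, j$axis, step = 0.5,
                            range = 20))
}

test_that("find_neck locates the minimum-area section and applies the tie rule", {
  hs <- hourglass_sections()
  neck <- find_neck(hs$sec)
  expect_lt(abs(neck$station_s - hs$j$truth$true_neck_station), 0.5)
  expect_lt(abs(neck$area - pi * 100) / (pi * 100), 0.01)
  expect_false(neck$non_constricted)

  # tie between two equal minima: the station nearer the base wins
  fake <- junctmorph:::new_cross_sections(
    data.frame(station_s = c(1, 2, 3, 4), area = c(5, 4, 4, 6),
               rect_major = 2, rect_minor = 2, rect_angle = 0,
               centroid_x = 0, centroid_y = 0, centroid_z = 1:4),
    vector("list", 4))
  expect_equal(find_neck(fake)$station_s, 2)

  expect_error(find_neck(junctmorph:::new_cross_sections(
    data.frame(station_s = 30, area = 1, rect_major = 1, rect_minor = 1,
               rect_angle = 0, centroid_x = 0, centroid_y = 0,
               centroid_z = 0), list(NULL))), ">= 2 cross-sections")
})

test_that("wide cones are flagged non_constricted", {
  k <- make_wide_cone(junction_spec(neck_diameter = 60,
                                    shape_class = "wide_cone",
                                    mesh_step = 1, flare_length = 30))
  sec <- section_series(k$mesh, k$base_point, k$axis, step = 1, range = 28)
  expect_true(find_neck(sec)$non_constricted)
})

test_that("width and aspect ratio come from the neck rectangle", {
  hs <- hourglass_sections(d = 20)
  neck <- find_neck(hs$sec)
  expect_equal(junction_width(neck), 20, tolerance = 0.02 * 20)
  expect_equal(junction_aspect_ratio(neck), 1, tolerance = 0.01)

  he <- make_hourglass(junction_spec(neck_diameter = 10, ellipticity = 2,
                                     mesh_step = 0.5))
  sece <- section_series(he$mesh, he$base_point, he$axis, step = 0.5,
                         range = 20)
  necke <- find_neck(sece)
  expect_equal(junction_width(necke), 15, tolerance = 0.02 * 15)
  expect_equal(junction_aspect_ratio(necke), 2, tolerance = 0.02)
})

test_that("junction_length implements the 1.2-fold area rule", {
  hs <- hourglass_sections(d = 20, c_ = 10)
  neck <- find_neck(hs$sec)
  len <- junction_length(hs$sec, neck)
  expect_equal(len$L, 2 * 10 * sqrt(0.2), tolerance = 0.45 / 8.94)
  expect_equal(len$L1, len$L2, tolerance = 0.5)
  expect_length(len$flags, 0)

  # factor -> 1+: length collapses toward 0
  len_small <- junction_length(hs$sec, neck, factor = 1.001)
  expect_lt(len_small$L, 1.5)
  expect_error(junction_length(hs$sec, neck, factor = 1), "> 1")
})

test_that("junctions clipped before the 1.2-fold station are flagged truncated", {
  j <- make_hourglass(junction_spec(neck_diameter = 20, mesh_step = 0.5))
  clipped <- clip_mesh(j$mesh, origin = c(0, 0, 2), normal = c(0, 0, 1))
  m <- measure_junction(clipped, j$base_point, j$axis)
  expect_true("truncated_L2" %in% m$flags)
  expect_true(is.na(m$length_L))
  expect_false(is.na(m$L1))
})

test_that("correct_shrinkage rescales and is linear", {
  expect_equal(round(correct_shrinkage(20)), 24)
  expect_equal(round(correct_shrinkage(15)), 18)
  expect_equal(correct_shrinkage(0), 0)
  a <- 7.3; b <- 11.9
  expect_equal(correct_shrinkage(a + b),
               correct_shrinkage(a) + correct_shrinkage(b))
  expect_equal(correct_shrinkage(10, 0), 10)
  expect_error(correct_shrinkage(10, 1), "\\[0, 1\\)")
  expect_error(correct_shrinkage(10, -0.2), "\\[0, 1\\)")
})

test_that("side profiles trace the facing membranes", {
  j <- make_hourglass(junction_spec(neck_diameter = 20, mesh_step = 0.5))
  pr <- side_profile(j$mesh, j$base_point, j$axis)
  gap <- min(vapply(seq_len(nrow(pr$left)), function(i)
    min(sqrt((pr$right[, 1] - pr$left[i, 1])^2 +
             (pr$right[, 2] - pr$left[i, 2])^2)), numeric(1)))
  expect_equal(gap, 20, tolerance = 0.01 * 20)

  # rotational symmetry: a 90-degree re-slice gives the same gap
  pr2 <- side_profile(j$mesh, j$base_point, j$axis, angle = pi / 2)
  gap2 <- min(vapply(seq_len(nrow(pr2$left)), function(i)
    min(sqrt((pr2$right[, 1] - pr2$left[i, 1])^2 +
             (pr2$right[, 2] - pr2$left[i, 2])^2)), numeric(1)))
  expect_equal(gap2, gap, tolerance = 0.01 * gap)

  # cylinder: two parallel traces at constant +/- r
  cyl <- cylinder_mesh(r = 10, h = 30)
  prc <- side_profile(cyl, c(0, 0, 0), c(0, 0, 1))
  expect_lt(diff(range(prc$left[, 2])), 1e-6)
  expect_lt(diff(range(prc$right[, 2])), 1e-6)
})

test_that("two_point_width is the Euclidean distance of distinct points", {
  expect_equal(two_point_width(c(0, 0, 0), c(0, 0, 20)), 20)
  expect_error(two_point_width(c(1, 2, 3), c(1, 2, 3)), "coincide")
})

test_that("distance_to_surface agrees with a brute-force oracle", {
  m <- icosphere(20, subdiv = 2)  # 1280 faces
  p <- c(3, -7, 41)
  # oracle: dense barycentric sampling of every triangle
  V <- m$vertices; F <- m$faces
  wts <- expand.grid(u = seq(0, 1, by = 0.05), v = seq(0, 1, by = 0.05))
  wts <- wts[wts$u + wts$v <= 1, ]
  brute <- min(vapply(seq_len(nrow(F)), function(k) {
    tri <- V[F[k, ], ]
    pts <- outer(1 - wts$u - wts$v, tri[1, ]) + outer(wts$u, tri[2, ]) +
      outer(wts$v, tri[3, ])
    min(sqrt(rowSums(sweep(pts, 2, p)^2)))
  }, numeric(1)))
  expect_equal(distance_to_surface(p, m), brute, tolerance = 1e-3)

  # exact cases
  flat <- sheet_mesh(z = 0, ext = 200, pitch = 50)
  expect_equal(distance_to_surface(c(10, 20, 50), flat), 50)
  expect_equal(distance_to_surface(flat$vertices[5, ], flat), 0)
})

test_that("perinuclear width below a junction is compared to flanking controls", {
  inm <- sheet_mesh(z = -40, ext = 1000, pitch = 50)
  r <- ne_width_below_junction(c(0, 0, 0), inm, lateral = c(1, 0, 0))
  expect_equal(r$width_below, 40)
  expect_equal(r$control_widths, c(40, 40))

  # locally dilated envelope: width below exceeds the controls
  dil <- inm
  bulge <- sqrt(rowSums(dil$vertices[, 1:2]^2)) < 120
  dil$vertices[bulge, 3] <- dil$vertices[bulge, 3] - 25
  r2 <- ne_width_below_junction(c(0, 0, 0), dil, lateral = c(1, 0, 0))
  expect_gt(r2$width_below, max(r2$control_widths))

  expect_error(ne_width_below_junction(c(0, 0, 0), NULL, c(1, 0, 0)),
               "required")
})

test_that("full pipeline recovers ground truth across the neck range", {
  for (d in c(7, 12, 17, 24)) {
    j <- make_hourglass(junction_spec(neck_diameter = d, mesh_step = 1))
    m <- measure_junction(j$mesh, j$base_point, j$axis)
    expect_lt(abs(m$width_W - j$truth$true_width) / j$truth$true_width, 0.02,
              label = sprintf("width at d=%g", d))
    expect_lt(abs(m$length_L - j$truth$true_length) / j$truth$true_length,
              0.05, label = sprintf("length at d=%g", d))
    expect_false("non_constricted" %in% m$flags)
  }
})

test_that("width increases monotonically with the generating neck diameter", {
  ds <- c(7, 10, 13, 16, 19, 22)
  ws <- vapply(ds, function(d) {
    j <- make_hourglass(junction_spec(neck_diameter = d, mesh_step = 1))
    measure_junction(j$mesh, j$base_point, j$axis)$width_W
  }, numeric(1))
  expect_true(all(diff(ws) > 0))
})

test_that("measured morphometry is rigid-motion invariant", {
  j <- make_hourglass(junction_spec(neck_diameter = 17.4, mesh_step = 1))
  m0 <- measure_junction(j$mesh, j$base_point, j$axis)
  R <- random_rotation(11)
  tr <- c(250, -80, 130)
  mesh2 <- transform_mesh(j$mesh, R, tr)
  m1 <- measure_junction(mesh2, as.vector(R %*% j$base_point) + tr,
                         as.vector(R %*% j$axis))
  expect_equal(m1$width_W, m0$width_W, tolerance = 1e-6)
  expect_equal(m1$aspect_ratio_AR, m0$aspect_ratio_AR, tolerance = 1e-6)
  expect_equal(m1$length_L, m0$length_L, tolerance = 1e-6)
})
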