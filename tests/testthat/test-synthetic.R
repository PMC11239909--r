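test_that("hourglass ground truth matches closed forms and a brute-force scan", {
  j <- make_hourglass(junction_spec(neck_diameter = 20, neck_scale = 10,
                                    ellipticity = 1, jitter_sd = 0))
  expect_equal(j$truth$true_width, 20)
  expect_equal(j$truth$true_length, 2 * 10 * sqrt(0.2))

  # independent oracle: scan analytic section areas at 0.1 nm pitch for the
  # first station with a 1.2-fold larger area than the neck
  s <- seq(0, 10, by = 0.1)
  areas <- pi * (10 * sqrt(1 + s^2 / 10^2))^2
  s_12 <- s[which(areas >= 1.2 * pi * 100)[1]]
  expect_equal(2 * s_12, j$truth$true_length, tolerance = 0.1 / (10 * sqrt(0.2)))

  # elliptical neck: width is the mean of the bounding-rectangle sides
  j2 <- make_hourglass(junction_spec(neck_diameter = 10, ellipticity = 2))
  expect_equal(j2$truth$true_width, (10 + 20) / 2)
  expect_equal(j2$truth$true_aspect_ratio, 2)
})

test_that("the generator is a pure function of (spec, seed)", {
  sp <- junction_spec(neck_diameter = 15, jitter_sd = 0.8, seed = 7)
  a <- make_hourglass(sp)
  b <- make_hourglass(sp)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  c_ <- make_hourglass(junction_spec(neck_diameter = 15, jitter_sd = 0.8,
                                     seed = 8))
  expect_false(identical(a$mesh$vertices, c_$mesh$vertices))
})

test_that("unresolvable tessellation is rejected", {
  expect_error(make_hourglass(junction_spec(neck_diameter = 5, mesh_step = 6)),
               "unresolvable")
  expect_error(junction_spec(neck_diameter = -1), "neck_diameter")
  expect_error(junction_spec(ellipticity = 0.5), "ellipticity")
  expect_error(junction_spec(jitter_sd = -0.1), "jitter_sd")
})

test_that("wide cones widen monotonically and report the base width", {
  k <- make_wide_cone(junction_spec(neck_diameter = 60,
                                    shape_class = "wide_cone",
                                    mesh_step = 1, flare_length = 30))
  sec <- section_series(k$mesh, k$base_point, k$axis, step = 1, range = 28)
  expect_true(all(diff(sec$table$area) > 0))

  # a 2-point line across the middle of the base spans the base opening
  V <- k$mesh$vertices
  base_ring <- V[abs(V[, 3]) < 1e-9 & abs(sqrt(rowSums(V[, 1:2]^2)) - 30) < 1e-6, ]
  p1 <- base_ring[which.max(base_ring[, 1]), ]
  p2 <- base_ring[which.min(base_ring[, 1]), ]
  expect_equal(two_point_width(p1, p2), 60, tolerance = 0.5)
})

test_that("jittered cone base widths stay within 2 nm of the nominal opening", {
  ws <- vapply(1:100, function(i) {
    k <- make_wide_cone(junction_spec(neck_diameter = 60,
                                      shape_class = "wide_cone",
                                      mesh_step = 1, flare_length = 6,
                                      jitter_sd = 0.5, seed = i))
    sec <- section_series(k$mesh, k$base_point, k$axis, step = 0.5,
                          range = 4, smooth_window = 5)
    with(sec$table[1, ], (rect_major + rect_minor) / 2)
  }, numeric(1))
  # first station sits ~0.5 nm above the base of a 45-degree cone, so the
  # nominal width there is 61 nm; the Monte-Carlo mean must stay within
  # 2 nm of the nominal opening and no single mesh may stray far
  expect_lt(abs(mean(ws) - 60), 2)
  expect_lt(max(abs(ws - 61)), 3)
})

test_that("envelope sheets carry analytic areas", {
  sh <- make_ne_sheet(10, 0.25)
  expect_equal(attr(sh, "true_area_um2"), 2.5)
  expect_equal(area_from_mesh(sh)$area_um2, 2.5, tolerance = 1e-6)

  # curved patch: area is arc length x depth
  shc <- make_ne_sheet(5, 0.2, curvature = 0.5)
  expect_equal(area_from_mesh(shc)$area_um2, 1.0, tolerance = 0.001)

  expect_error(make_ne_sheet(10, 0), "must be > 0")
  expect_error(make_ne_sheet(0, 1), "must be > 0")
})

test_that("nuclear masks match analytic ellipsoid volume", {
  mk <- make_nuclear_mask(c(5, 5, 5), 40)
  v_analytic <- 4 / 3 * pi * (5000 / 40)^3
  expect_lt(abs(sum(mk$mask) - v_analytic) / v_analytic, 0.02)

  expect_identical(make_nuclear_mask(c(1, 1, 1), 50)$mask,
                   make_nuclear_mask(c(1, 1, 1), 50)$mask)
  expect_error(make_nuclear_mask(c(0.03, 1, 1), 40), "exceed the voxel")
})

test_that("voxel masks round-trip through multi-page TIFF", {
  mk <- make_nuclear_mask(c(0.5, 0.4, 0.3), 40)
  p <- tempfile(fileext = ".tif")
  write_mask(mk, p)
  mk2 <- read_mask(p, 40)
  expect_identical(mk2$mask, mk$mask)
})

test_that("sample_population reproduces its generating distribution", {
  # empty scene
  s0 <- sample_population(0, scene_area_um2 = 10, make_meshes = FALSE)
  expect_equal(nrow(s0$annotations), 0)
  expect_equal(junction_frequency(s0$annotations,
                                  s0$scene_area_um2)$frequency_per_um2, 0)

  # law of large numbers on the generator
  s1 <- sample_population(100, width_mean = 17.4, width_sd = 5.0,
                          seed = 3, make_meshes = FALSE)
  se <- 5.0 / sqrt(100)
  expect_lt(abs(mean(s1$annotations$true_width_nm) - 17.4), 2 * se)
  expect_true(all(s1$annotations$true_width_nm >= 2))

  # determinism
  s2 <- sample_population(100, width_mean = 17.4, width_sd = 5.0,
                          seed = 3, make_meshes = FALSE)
  expect_identical(s1$annotations, s2$annotations)

  # class mix must be proportions
  expect_error(sample_population(5, class_mix = c(with_lumen = 0.5)),
               "sum to 1")
})

test_that("annotations round-trip through JSON", {
  sc <- sample_population(5, seed = 2, make_meshes = FALSE)
  p <- tempfile(fileext = ".json")
  write_annotations(sc$annotations, p)
  a2 <- read_annotations(p)
  expect_equal(a2$true_width_nm, sc$annotations$true_width_nm)
  expect_equal(a2$lumen_class, sc$annotations$lumen_class)
})
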