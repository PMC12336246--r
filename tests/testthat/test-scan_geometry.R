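test_that("contour_centroid is the vertex mean with translation equivariance", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(contour_centroid(sq), c(0.5, 0.5), ignore_attr = TRUE)
  expect_error(contour_centroid(sq[0, , drop = FALSE]), "empty")

  pts <- circle_points(25, center = c(10, -3), n = 360)
  expect_equal(contour_centroid(pts), c(10, -3), tolerance = 1e-9,
               ignore_attr = TRUE)

  set.seed(4)
  for (i in 1:10) {
    shift <- runif(2, -40, 40)
    expect_equal(contour_centroid(sweep(pts, 2, -shift)),
                 contour_centroid(pts) + shift, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("radial_profile measures distances along rays", {
  # circle: all radii equal R
  pts <- circle_points(50, center = c(7, 9), n = 1440)
  prof <- radial_profile(pts, c(7, 9), n_angles = 360)
  expect_lt(max(abs(prof$radii - 50)), 1e-6 * 50)

  # a single point at distance 5: the polygon through (3,4)-like offsets
  p34 <- circle_points(5, n = 360)
  expect_equal(radial_profile(p34, c(0, 0), 8)$radii, rep(5, 8),
               tolerance = 1e-4)

  # superellipse against its closed-form polar radius, 720 angles
  se <- superellipse(a = 60, b = 45, n = 3.5)
  prof <- radial_profile(se$points, c(0, 0), n_angles = 720)
  truth <- superellipse_radius(60, 45, 3.5, prof$angles)
  expect_lt(max(abs(prof$radii - truth) / truth), 1e-3)

  # centroid outside the polygon is refused
  expect_error(radial_profile(circle_points(10, c(0, 0), 90), c(50, 0)),
               "non-star-shaped")
})

test_that("rigid translation leaves the radial profile unchanged", {
  spec <- contour_spec(50, data.frame(k = c(2, 5), amplitude = c(4, 1.5),
                                      phase = c(0.2, 1.0)), n_vertices = 720)
  pts <- make_contour(spec)
  base <- cross_section_profile(pts, 3, "left", "control")
  set.seed(5)
  for (i in 1:5) {
    shift <- runif(2, -30, 30)
    moved <- cross_section_profile(sweep(pts, 2, -shift), 3, "left", "control")
    expect_equal(moved$radii, base$radii, tolerance = 1e-9)
  }
})

test_that("rotating a contour circularly shifts its radial profile", {
  n_ang <- 360
  spec <- contour_spec(50, data.frame(k = 3, amplitude = 4, phase = 0.5),
                       n_vertices = 1440)
  pts <- make_contour(spec)
  k <- 45L  # rotate by 45 grid steps
  alpha <- 2 * pi * k / n_ang
  rot <- cbind(cos(alpha) * pts[, 1] - sin(alpha) * pts[, 2],
               sin(alpha) * pts[, 1] + cos(alpha) * pts[, 2])
  p0 <- radial_profile(pts, c(0, 0), n_ang)
  p1 <- radial_profile(rot, c(0, 0), n_ang)
  # x = left->right, y = anterior: this rotation advances the contour's
  # anterior-referenced angle by alpha
  expect_equal(p1$radii, p0$radii[((seq_len(n_ang) - 1L - k) %% n_ang) + 1L],
               tolerance = 1e-6)
})

test_that("deformation_profile differences per angle with own centroids", {
  c1 <- cross_section_profile(circle_points(60, c(100, 100), 720), 4, "left",
                              "control")
  same <- cross_section_profile(circle_points(60, c(100, 100), 720), 4, "left",
                                "legging_1")
  d0 <- deformation_profile(c1, same)
  expect_equal(d0$mean, 0, tolerance = 1e-12)

  # offset garment circle: uniform 2 mm, displacement cancelled
  c2 <- cross_section_profile(circle_points(58, c(105, 105), 720), 4, "left",
                              "legging_1")
  d <- deformation_profile(c1, c2)
  expect_equal(d$per_angle, rep(2, 360), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(d$quadrants), rep(2, 4), tolerance = 1e-9)

  # bulge: garment radius > control radius -> negative deformation reported
  big <- cross_section_profile(circle_points(61, c(100, 100), 720), 4, "left",
                               "legging_2")
  expect_true(all(deformation_profile(c1, big)$per_angle < 0))

  # pairing rules
  other <- cross_section_profile(circle_points(60, c(100, 100), 720), 5,
                                 "left", "legging_1")
  expect_error(deformation_profile(c1, other), "pairing")
  grid <- cross_section_profile(circle_points(60, c(100, 100), 720), 4,
                                "left", "legging_1", n_angles = 180)
  expect_error(deformation_profile(c1, grid), "grids")
})

test_that("quadrant summaries follow the anatomical bins", {
  # k = 2 field: deformation concentrated along the anterior-posterior axis
  # (a k = 1 field is indistinguishable from rigid translation and is
  # deliberately cancelled by the centroid anchoring)
  ctrl <- make_contour(contour_spec(60, center = c(100, 100),
                                    n_vertices = 720))
  garm <- deform_contour(ctrl, function(th) 2 + 1.5 * cos(2 * th))
  p1 <- cross_section_profile(ctrl, 4, "left", "control")
  p2 <- cross_section_profile(garm, 4, "left", "legging_4")
  q <- deformation_profile(p1, p2)$quadrants
  # bin means of 2 + 1.5 cos(2 theta): 2 + 3/pi on the anterior/posterior
  # bins, 2 - 3/pi on the lateral/medial bins
  expect_equal(q[["anterior"]], 2 + 3 / pi, tolerance = 0.02)
  expect_equal(q[["posterior"]], 2 + 3 / pi, tolerance = 0.02)
  expect_equal(q[["lateral"]], 2 - 3 / pi, tolerance = 0.02)
  expect_equal(q[["medial"]], 2 - 3 / pi, tolerance = 0.02)
})

test_that("a pure k = 1 radial field is absorbed as rigid displacement", {
  # cos(theta) field == translation of a near-circle: the own-centroid
  # anchoring cancels it, leaving only the uniform component
  ctrl <- make_contour(contour_spec(60, center = c(100, 100),
                                    n_vertices = 720))
  garm <- deform_contour(ctrl, function(th) 2 + 1.5 * cos(th))
  p1 <- cross_section_profile(ctrl, 4, "left", "control")
  p2 <- cross_section_profile(garm, 4, "left", "legging_4")
  d <- deformation_profile(p1, p2)
  expect_equal(d$mean, 2, tolerance = 0.02)
  expect_lt(diff(range(d$per_angle)), 0.1)
  expect_equal(p2$centroid[[2]], 100 - 1.5, tolerance = 0.01)
})

test_that("extract_contour finds, orders and scales the marker boundary", {
  pts <- circle_points(100 * 0.5, center = c(128, 128), n = 720)
  img <- render_contour(pts, image_size = 512, pixel_scale = 0.5)
  got <- extract_contour(img, pixel_scale = 0.5)
  r <- sqrt(rowSums(sweep(got, 2, colMeans(got))^2))
  expect_equal(mean(r), 50, tolerance = 0.01)
  expect_equal(colMeans(got), c(128, 128), tolerance = 0.5 * 0.5,
               ignore_attr = TRUE)
  # counter-clockwise ordering about the centroid = positive enclosed area
  n <- nrow(got); j <- c(2:n, 1)
  expect_gt(sum(got[, 1] * got[j, 2] - got[j, 1] * got[, 2]) / 2, 0)

  # pixel-scale equivariance: doubling the scale doubles every mm quantity
  got2 <- extract_contour(img, pixel_scale = 1.0)
  expect_equal(got2, got * 2, tolerance = 1e-12)

  # all-black image errors
  expect_error(extract_contour(array(0, c(64, 64, 3))), "empty contour")

  # two disjoint blobs: only the larger one's boundary is returned
  img2 <- array(0, c(64, 64, 3))
  img2[10:40, 10:40, 1] <- 1; img2[10:40, 10:40, 2] <- 1   # ~961 px blob
  img2[50:52, 50:52, 1] <- 1; img2[50:52, 50:52, 2] <- 1   # 9 px blob
  b <- extract_contour(img2, pixel_scale = 1)
  expect_true(all(b[, 1] <= 41 & b[, 2] >= 64 - 41))
})

test_that("slice_mesh recovers analytic cross-sections", {
  # sphere-like loft: equatorial slice is a unit circle
  sph <- make_limb_mesh(lapply(seq(-0.95, 0.95, length.out = 41), function(z)
    list(z = z, spec = contour_spec(max(1e-3, sqrt(1 - z^2)), n_vertices = 120))))
  expect_gt(nrow(sph$faces), 5000)
  loops <- slice_mesh(sph, 0)
  expect_length(loops, 1)
  a <- abs(sum(loops[[1]][, 1] * loops[[1]][c(2:nrow(loops[[1]]), 1), 2] -
               loops[[1]][c(2:nrow(loops[[1]]), 1), 1] * loops[[1]][, 2]) / 2)
  expect_lt(abs(a - pi) / pi, 0.01)

  # two-cylinder legs: 2 loops labelled by lateral position
  legs <- make_limb_mesh(list(list(z = 0, spec = contour_spec(50, n_vertices = 90)),
                              list(z = 100, spec = contour_spec(50, n_vertices = 90))),
                         limb_offsets = list(c(-80, 0), c(80, 0)))
  l2 <- slice_mesh(legs, 50)
  expect_length(l2, 2)
  sides <- vapply(l2, attr, character(1), "side")
  cx <- vapply(l2, function(p) mean(p[, 1]), numeric(1))
  expect_equal(sides[which.min(cx)], "right")
  expect_equal(sides[which.max(cx)], "left")
  # flip flag swaps the labels
  l2f <- slice_mesh(legs, 50, flip_sides = TRUE)
  expect_equal(vapply(l2f, attr, character(1), "side")[which.min(cx)], "left")

  # plane above the mesh: empty list, not an error
  expect_length(slice_mesh(legs, 200), 0)
})

test_that("STL round trip preserves slicing geometry", {
  tap <- make_limb_mesh(list(list(z = 0, spec = contour_spec(60, n_vertices = 180)),
                             list(z = 100, spec = contour_spec(40, n_vertices = 180))))
  path <- tempfile(fileext = ".stl")
  write_stl_ascii(tap, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(tap$faces))
  mid <- slice_mesh(back, 50)[[1]]
  r <- sqrt(rowSums(sweep(mid, 2, colMeans(mid))^2))
  expect_lt(max(abs(r - 50)), 0.1)  # linear loft: 60 -> 40 tapers to 50
})

test_that("read_stl parses the binary layout too", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1L, 2L, 3L)))
  path <- tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(raw(80), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(0, 0, 1, t(tri$vertices)), con, size = 4, endian = "little")
  writeBin(raw(2), con)
  close(con)
  m <- read_stl(path)
  expect_equal(m$vertices, tri$vertices, ignore_attr = TRUE)
})

test_that("select_extreme_frames applies the first-occurrence tie rule", {
  # monotone ramp
  ramp <- vibration_sequence(0:9 / 10, 0:9, 10)
  ex <- select_extreme_frames(ramp)
  expect_equal(ex$index_high, 10L)
  expect_equal(ex$index_low, 1L)
  expect_equal(ex$displacement, 9)

  # two equal maxima: first occurrence wins
  twin <- vibration_sequence(0:4 / 10, c(0, 5, 0, 5, -1), 10)
  expect_equal(select_extreme_frames(twin)$index_high, 2L)

  # constant sequence warns and reports zero displacement
  flat <- vibration_sequence(0:3 / 10, rep(1, 4), 10)
  expect_warning(exf <- select_extreme_frames(flat), "degenerate")
  expect_equal(exf$displacement, 0)
})
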