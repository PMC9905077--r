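# Cochlear coordinate system: frame fitting, unwrapped angular positions,
# turn counting, overall dimensions, angular ranges, and the equivariance
# properties.

test_that("fitted frame recovers the ground-truth axis and zero direction", {
  ph <- test_phantom()
  fr <- test_frame()
  tr <- ph$frame
  axis_angle <- acos(min(1, abs(sum(fr$axis_dir * tr$axis_dir)))) * 180 / pi
  expect_lt(axis_angle, 2)
  zero_angle <- acos(min(1, sum(fr$zero_dir * tr$zero_dir))) * 180 / pi
  expect_lt(zero_angle, 3)
  expect_identical(fr$handedness, "left")
  # pre-aligned phantom: fitted axis essentially the grid z axis
  expect_gte(abs(fr$axis_dir[3]), 0.999)
})

test_that("frame fitting requires the round window and a lumen or modiolus", {
  ph <- test_phantom()
  no_rwm <- ph$labels
  no_rwm$data[no_rwm$data == no_rwm$label_map[["rwm"]]] <- 0L
  expect_error(fit_frame(no_rwm), "rwm")
})

test_that("angular positions recover the generation parameter", {
  ph <- test_phantom()
  fr <- test_frame()
  lm <- ph$labels$label_map
  # round window membrane centroid sits at the zero reference
  rwm_idx <- which(structure_mask(ph$labels, "rwm"))
  vox <- ph$labels$voxel_size_um / 1000
  rwm_c <- colMeans(cochleaCT:::voxel_world(rwm_idx, dim(ph$labels$data),
                                            vox))
  expect_lt(abs(angular_position(matrix(rwm_c, 1), fr)), 2)
  # voxels generated at parameter 370 report 370 within 3 degrees
  sel <- which(ph$labels$data == lm[["st"]] & abs(ph$theta - 370) < 1)
  th <- angular_position(sel, fr, labels = ph$labels)
  expect_lt(max(abs(th - ph$theta[sel])), 3)
  # unwrapping: adjacent-turn points differ by 360 within 3 degrees
  a <- which(ph$labels$data == lm[["st"]] & abs(ph$theta - 100) < 0.5)[1]
  b <- which(ph$labels$data == lm[["st"]] & abs(ph$theta - 460) < 0.5)[1]
  d <- diff(angular_position(c(a, b), fr, labels = ph$labels))
  expect_lt(abs(d - 360), 3)
})

test_that("points on the modiolar axis have undefined azimuth", {
  fr <- test_frame()
  expect_error(angular_position(matrix(fr$axis_point, 1), fr),
               "undefined azimuth")
})

test_that("turn counting recovers the generated number of turns", {
  ph <- test_phantom()
  fr <- test_frame()
  expect_equal(count_turns(ph$labels, fr), 2.8, tolerance = 0.05 / 2.8)
})

test_that("a half-turn phantom reports 0.5 turns", {
  ph <- generate_phantom(small_spec(turns = 0.5, height_mm = 2.6,
                                    ssl_range_deg = c(0, 120),
                                    rc_range_deg = c(0, 150)))
  fr <- fit_frame(ph$labels)
  expect_equal(count_turns(ph$labels, fr), 0.5, tolerance = 0.1)
})

test_that("turn count is invariant under a 90-degree rigid rotation", {
  ph <- test_phantom()
  rot <- rotate_labels_90(ph$labels)
  fr_rot <- fit_frame(rot)
  expect_equal(count_turns(rot, fr_rot),
               count_turns(ph$labels, test_frame()), tolerance = 0.02 / 2.8)
})

test_that("mirrored right-ear phantoms flip handedness but keep measurements", {
  left <- generate_phantom(small_spec())
  right <- generate_phantom(small_spec(handedness = "right"))
  fl <- fit_frame(left$labels)
  fr <- fit_frame(right$labels)
  expect_identical(fl$handedness, "left")
  expect_identical(fr$handedness, "right")
  expect_equal(count_turns(right$labels, fr),
               count_turns(left$labels, fl))
  expect_equal(angular_range(right$labels, "ssl", fr)[["end_deg"]],
               angular_range(left$labels, "ssl", fl)[["end_deg"]],
               tolerance = 3 / 572)
  dl <- measure_cochlea_dimensions(left$labels, fl)
  dr <- measure_cochlea_dimensions(right$labels, fr)
  expect_equal(dr$length_mm, dl$length_mm, tolerance = 0.02)
  expect_equal(dr$height_mm, dl$height_mm, tolerance = 0.02)
})

test_that("overall dimensions match the analytic bounding extents", {
  ph <- test_phantom()
  fr <- test_frame()
  d <- measure_cochlea_dimensions(ph$labels, fr)
  vox <- ph$labels$voxel_size_um / 1000
  expect_lt(abs(d$length_mm - truth_value(ph, "length_mm")), 2 * vox)
  expect_lt(abs(d$width_mm - truth_value(ph, "width_mm")), 2 * vox)
  expect_lt(abs(d$height_mm - truth_value(ph, "height_mm")), 2 * vox)
})

test_that("a sphere has equal length, width and height", {
  dims <- c(48L, 48L, 48L)
  vox_um <- 100
  cc <- coord_arrays(dims, vox_um / 1000, origin = rep(2.35, 3))
  sphere <- sqrt(cc$x^2 + cc$y^2 + cc$z^2) < 0.9 # diameter 1.8 mm
  lab <- array(0L, dims)
  lab[sphere] <- 4L
  lt <- cochlear_label_table()
  labels <- cect_labels(lab, setNames(lt$code, lt$name), vox_um)
  frame <- cochleaCT:::new_cochlear_frame(
    axis_point = rep(2.35, 3), axis_dir = c(0, 0, 1),
    zero_dir = c(1, 0, 0), handedness = "left",
    centerline = tibble::tibble(theta_deg = c(0, 360), r_mm = 1, z_mm = 0))
  d <- measure_cochlea_dimensions(labels, frame,
                                  exclude = "background")
  expect_equal(d$length_mm, 1.8, tolerance = 2 * vox_um / 1000 / 1.8)
  expect_equal(d$width_mm, d$length_mm, tolerance = 0.01)
  expect_equal(d$height_mm, d$length_mm, tolerance = 0.01)
})

test_that("a four-phantom cohort at the published dimensions measures within range", {
  cohort <- list(c(9.5, 6.8, 4.2, 2.8), c(8.9, 6.4, 3.7, 2.6),
                 c(8.8, 6.6, 3.6, 2.7), c(10.1, 7.2, 4.0, 2.6))
  vox <- 96 / 1000
  meas <- t(vapply(cohort, function(p) {
    ph <- generate_phantom(small_spec(length_mm = p[1], width_mm = p[2],
                                      height_mm = p[3], turns = p[4]))
    fr <- fit_frame(ph$labels)
    unlist(measure_cochlea_dimensions(ph$labels, fr))
  }, numeric(3)))
  # published ranges, allowing rasterization slack (the measured extent
  # includes the outermost voxels' footprint) of 1.5 voxels per side
  expect_true(all(meas[, 1] >= 8.8 - 1.5 * vox & meas[, 1] <= 10.1 + 1.5 * vox))
  expect_true(all(meas[, 2] >= 6.4 - 1.5 * vox & meas[, 2] <= 7.2 + 1.5 * vox))
  expect_true(all(meas[, 3] >= 3.6 - 1.5 * vox & meas[, 3] <= 4.2 + 1.5 * vox))
})

test_that("angular ranges recover generated structure extents", {
  ph <- test_phantom()
  fr <- test_frame()
  ssl <- angular_range(ph$labels, "ssl", fr)
  expect_lt(abs(ssl[["end_deg"]] - 572), 3)
  rwa <- angular_range(ph$labels, "rwa", fr)
  expect_lt(rwa[["end_deg"]], 90)
  sl <- angular_range(ph$labels, "sl", fr)
  expect_lt(abs(sl[["start_deg"]]), 3)
  # the apical spiral ligament tail is one voxel thin; the last rasterized
  # voxel can sit up to ~one angular voxel quantum short of the spec end
  vox_deg <- (ph$spec$voxel_size_um / 1000) /
    cochleaCT:::spiral_radius(ph$spec, 1008) * 180 / pi
  expect_lt(abs(sl[["end_deg"]] - 1008), 3 + vox_deg)
  expect_error(angular_range(ph$labels, "electrode", fr), "no voxels")
})
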