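# Synthetic cochlear phantom: spec validation, rasterization vs analytic
# ground truth, determinism, staining time-course, electrode insertion.

test_that("spec validation fails loudly on degenerate geometry", {
  expect_error(phantom_spec(turns = 0), "turns must be > 0")
  expect_error(phantom_spec(turns = -1), "turns must be > 0")
  expect_error(phantom_spec(bm_thickness_um = 30, voxel_size_um = 56),
               "thinner than one voxel.*bm")
  expect_error(phantom_spec(voxel_size_um = 56, duct_radius_um = 90),
               "apical scala duct")
  expect_error(phantom_spec(grid_dim = c(64, 64, 64), voxel_size_um = 56),
               "field of view")
})

test_that("ground-truth angular extent follows the spec turns", {
  spec <- test_spec()
  ph <- test_phantom()
  expect_equal(truth_value(ph, "turns"), 2.8)
  expect_equal(truth_value(ph, "angular_extent_deg"), 2.8 * 360)
  expect_equal(max(ph$frame$centerline$theta_deg), 1008)
})

test_that("labels partition the grid and cover every non-background grey voxel", {
  ph <- test_phantom()
  lt <- cochlear_label_table()
  present <- sort(unique(as.integer(ph$labels$data)))
  expect_true(all(present %in% lt$code))
  # all anatomy labels of the minimum vocabulary are present
  needed <- c("st", "sv", "sm", "capsule", "rwm", "bm", "osl", "sl", "ssl",
              "rwa", "rc")
  expect_true(all(lt$code[match(needed, lt$name)] %in% present))
  # grey voxels are exactly the labelled voxels (noiseless rendering)
  expect_identical(ph$grey$data > 0, ph$labels$data > 0L)
})

test_that("rasterized structure volumes agree with the continuous ground truth", {
  ph <- test_phantom()
  vox3 <- (ph$spec$voxel_size_um / 1000)^3
  lt <- cochlear_label_table()
  for (s in c("st", "sv", "sl", "osl", "ssl")) {
    raster <- sum(ph$labels$data == lt$code[lt$name == s]) * vox3
    truth <- truth_value(ph, paste0("volume_mm3.", s))
    expect_lt(abs(raster - truth) / truth, 0.05)
  }
})

test_that("regeneration with the same spec and seed is bit-identical", {
  spec <- small_spec(noise_sd = 0.004)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$labels$data, p2$labels$data)
  expect_identical(p1$grey$data, p2$grey$data)
  expect_identical(p1$truth, p2$truth)
})

test_that("staining uptake starts at zero, advances monotonically, and respects the front", {
  ph <- test_phantom()
  u0 <- stain_uptake(ph, 0)
  expect_equal(max(u0), 0)
  # voxelwise monotone in time
  prev <- u0
  for (t_h in c(12, 24, 48, 72)) {
    u <- stain_uptake(ph, t_h)
    expect_true(all(u - prev >= -1e-12))
    prev <- u
  }
  # uptake non-increasing with angular distance from the round window
  u <- stain_uptake(ph, 30)
  soft <- which(class_mask(ph$labels, "soft") &
                  !structure_mask(ph$labels, "rwm"))
  ord <- order(ph$theta[soft])
  expect_true(all(diff(u[soft][ord]) <= 1e-12))
  expect_error(stain_uptake(ph, -1), "time")
})

test_that("round window membrane is fully stained at three hours", {
  ph <- test_phantom()
  u <- stain_uptake(ph, 3)
  rwm <- structure_mask(ph$labels, "rwm")
  expect_equal(min(u[rwm]), 1)
  g <- simulate_staining(ph, 3)
  expect_equal(unique(g$data[rwm]), ph$spec$attenuation[["soft"]])
})

test_that("a 2.8-turn phantom at one turn per day is fully stained on day 3", {
  ph <- test_phantom()
  expect_identical(staining_completion_day(ph, rate = 1), 3L)
  # and not on day 2
  soft <- class_mask(ph$labels, "soft")
  u2 <- stain_uptake(ph, 48)
  expect_false(all(u2[soft] > 0.5))
  u3 <- stain_uptake(ph, 72)
  expect_true(all(u3[soft] > 0.5))
})

test_that("electrode insertion without lesions only adds the electrode label", {
  pre <- test_phantom()
  post <- insert_electrode(pre, 380)
  lm <- pre$labels$label_map
  changed <- which(pre$labels$data != post$labels$data)
  expect_true(all(post$labels$data[changed] == lm[["electrode"]]))
  expect_true(all(pre$labels$data[changed] == lm[["st"]]))
  # anatomy voxel counts conserved for every non-fluid structure
  for (s in c("bm", "osl", "sl", "ssl", "rwm", "capsule")) {
    expect_identical(sum(pre$labels$data == lm[[s]]),
                     sum(post$labels$data == lm[[s]]))
  }
  expect_identical(sum(pre$labels$data == lm[["st"]]),
                   sum(post$labels$data == lm[["st"]]) +
                     sum(post$labels$data == lm[["electrode"]]))
})

test_that("lesion bookkeeping records the generated fraction exactly", {
  pre <- test_phantom()
  post <- insert_electrode(pre, 380,
                           lesion("osl", "fracture", c(0, 380),
                                  fraction = 0.10))
  lm <- pre$labels$label_map
  n_pre <- sum(pre$labels$data == lm[["osl"]])
  n_in_range <- sum(pre$labels$data == lm[["osl"]] & pre$theta <= 380)
  expect_identical(post$lesions$removed_voxels,
                   as.integer(round(0.10 * n_in_range)))
  expect_equal(post$lesions$percent_of_pre,
               100 * round(0.10 * n_in_range) / n_pre)
})

test_that("electrode voxels stay below the requested insertion depth", {
  post <- test_post()
  depth <- max(post$theta[structure_mask(post$labels, "electrode")])
  expect_lt(abs(depth - 380), 2)
})

test_that("lesion validation errors are loud", {
  pre <- test_phantom()
  expect_error(insert_electrode(pre, 380,
                                lesion("osl", "fracture", c(100, 400))),
               "beyond electrode depth")
  expect_error(insert_electrode(pre, 380,
                                lesion("cochlea", "fracture", c(0, 90))),
               "unknown structure")
  expect_error(insert_electrode(pre, 2000), "depth")
  expect_error(insert_electrode(pre, 0), "depth")
})

test_that("membrane patch generator validates thickness against voxel size", {
  expect_error(generate_membrane_patch(thickness_mm = 0.004,
                                       voxel_size_um = 6.3),
               "thinner than one voxel")
})
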