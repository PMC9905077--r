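# Morphometry: structure volumes, centerline lengths, sphere-fitting local
# thickness (with a brute-force oracle), and thickness histograms.

sphere_labels <- function(radius_mm = 0.5, vox_um = 18.9) {
  n <- ceiling(2 * radius_mm * 1000 / vox_um) + 8L
  cc <- coord_arrays(rep(n, 3), vox_um / 1000,
                     origin = rep((n - 1) / 2 * vox_um / 1000, 3))
  lab <- array(0L, rep(n, 3))
  lab[sqrt(cc$x^2 + cc$y^2 + cc$z^2) <= radius_mm] <- 7L
  lt <- cochlear_label_table()
  cect_labels(lab, setNames(lt$code, lt$name), vox_um)
}

test_that("structure volume matches the analytic sphere volume", {
  labels <- sphere_labels(0.5, 18.9)
  v <- structure_volume(labels, "bm")
  expect_equal(v, 4 / 3 * pi * 0.5^3, tolerance = 0.02)
  expect_error(structure_volume(labels, "osl"), "no voxels")
  expect_error(structure_volume(labels, "nonsense"), "unknown structure")
})

test_that("structure volumes are additive over the label partition", {
  ph <- test_phantom()
  lt <- cochlear_label_table()
  present <- setdiff(unique(as.integer(ph$labels$data)), 0L)
  total <- sum(vapply(lt$name[match(present, lt$code)],
                      function(s) structure_volume(ph$labels, s),
                      numeric(1)))
  whole <- sum(ph$labels$data > 0L) * (ph$labels$voxel_size_um / 1000)^3
  expect_equal(total, whole)
})

test_that("centerline length measures a straight rod to 3%", {
  dims <- c(120L, 24L, 24L)
  vox_um <- 50
  cc <- coord_arrays(dims, vox_um / 1000)
  rod <- cc$x > 0.25 & cc$x < 5.25 &
    sqrt((cc$y - 0.6)^2 + (cc$z - 0.6)^2) < 0.2
  L <- centerline_length(rod, vox_um)
  expect_equal(as.numeric(L), 5, tolerance = 0.03)
  expect_identical(attr(L, "n_components"), 1L)
  expect_error(centerline_length(array(FALSE, c(4, 4, 4)), vox_um),
               "empty mask")
})

test_that("centerline length matches the closed-form helix arc length", {
  dims <- c(90L, 90L, 80L)
  vox_um <- 50
  cc <- coord_arrays(dims, vox_um / 1000,
                     origin = c(44.5, 44.5, 0) * vox_um / 1000)
  phi <- atan2(cc$y, cc$x)
  rho <- sqrt(cc$x^2 + cc$y^2)
  best <- array(Inf, dims)
  for (k in 0:2) {
    psi <- phi + 2 * pi * k
    d <- sqrt((rho - 1.5)^2 + (cc$z - (0.3 + psi / (2 * pi)))^2)
    d[psi < 0 | psi > 4 * pi] <- Inf
    best <- pmin(best, d)
  }
  helix <- best < 0.25
  L_true <- 2 * sqrt((2 * pi * 1.5)^2 + 1^2)
  L <- centerline_length(helix, vox_um)
  expect_equal(as.numeric(L), L_true, tolerance = 0.05)
})

test_that("disjoint components report the longest rod and the count", {
  dims <- c(120L, 30L, 30L)
  vox_um <- 50
  cc <- coord_arrays(dims, vox_um / 1000)
  rods <- (cc$x > 0.25 & cc$x < 5.25 &
             sqrt((cc$y - 0.5)^2 + (cc$z - 0.5)^2) < 0.15) |
    (cc$x > 0.25 & cc$x < 2.25 &
       sqrt((cc$y - 1.1)^2 + (cc$z - 1.1)^2) < 0.12)
  L <- centerline_length(rods, vox_um)
  expect_equal(as.numeric(L), 5, tolerance = 0.04)
  expect_identical(attr(L, "n_components"), 2L)
})

test_that("centerline length is rotation invariant within digitization error", {
  dims <- c(90L, 90L, 80L)
  ph <- test_phantom()
  st <- structure_mask(ph$labels, "st")
  L1 <- as.numeric(centerline_length(st, ph$labels$voxel_size_um))
  rot <- rotate_labels_90(ph$labels)
  L2 <- as.numeric(centerline_length(structure_mask(rot, "st"),
                                     ph$labels$voxel_size_um))
  expect_equal(L2, L1, tolerance = 0.05)
})

test_that("scala tympani centerline length matches the continuous truth", {
  ph <- test_phantom()
  st <- structure_mask(ph$labels, "st")
  L <- as.numeric(centerline_length(st, ph$labels$voxel_size_um))
  expect_equal(L, truth_value(ph, "centerline_length_mm.st"),
               tolerance = 0.05)
})

test_that("a curved membrane of 0.17 mm has modal thickness 0.17 mm at 6.3 um", {
  p <- generate_membrane_patch(thickness_mm = 0.17, voxel_size_um = 6.3,
                               patch_mm = 0.6)
  tm <- local_thickness(p$mask, step_voxels = 2,
                        voxel_size_um = p$voxel_size_um)
  expect_lt(abs(modal_thickness(tm) - 0.17), 6.3 / 1000 + 1e-9)
})

test_that("a rasterized sphere is its own fitting sphere", {
  vox_um <- 18.9
  labels <- sphere_labels(0.5, vox_um) # diameter 52.9 voxels
  mask <- labels$data > 0L
  tm <- local_thickness(mask, 2, vox_um)
  d_vox <- 2 * 0.5 / (vox_um / 1000)
  expect_lt(abs(max(tm$data) / (vox_um / 1000) - d_vox), 2 + 1)
  expect_error(local_thickness(array(FALSE, c(4, 4, 4)), 2, vox_um),
               "empty mask")
  expect_error(local_thickness(mask, 0, vox_um), "step_voxels")
})

test_that("local thickness agrees exactly with the brute-force oracle", {
  for (seed in c(3, 17, 29, 41, 53)) {
    dims <- c(24L, 24L, 24L)
    m <- random_blob(dims, seed)
    if (!any(m)) next
    fast <- local_thickness(m, 2, 1000)$data # 1 mm voxels: mm == voxels
    slow <- bf_thickness(m, 2)
    expect_identical(fast, slow)
  }
})

test_that("thickness is bounded below by the distance transform", {
  m <- random_blob(c(30L, 30L, 30L), 7)
  step <- 2
  tm <- local_thickness(m, step, 1000)
  e <- cochleaCT:::edt_to(!m)
  # sphere-fit thickness can fall below 2*(boundary distance) - 1 only by
  # the quantization step
  expect_true(all(tm$data[m] >= 2 * (e[m] - 0.5) - 1 - step))
  # equality on a slab
  slab <- array(FALSE, c(20L, 20L, 31L))
  slab[, , 3:29] <- TRUE # 27 layers
  ts <- local_thickness(slab, 2, 1000)
  expect_equal(unique(ts$data[slab]), 26)
})

test_that("thickness histograms have exact midpoints and conserve mass", {
  h <- thickness_histogram(c(0.06, 0.08, 0.09, 0.12), bin_width_mm = 0.038,
                           start_mm = 0.057)
  expect_equal(h$midpoint_mm[1], 0.076)
  expect_equal(h$midpoint_mm, (h$lo_mm + h$hi_mm) / 2)
  expect_equal(sum(h$percent), 100, tolerance = 1e-4)
  # a uniform slab lands in a single bin
  slab <- array(FALSE, c(12L, 12L, 20L))
  slab[, , 5:15] <- TRUE
  ts <- local_thickness(slab, 2, 100)
  hs <- thickness_histogram(ts, bin_width_mm = 0.05, start_mm = 0)
  expect_equal(max(hs$percent), 100)
  # mass conservation on random maps
  for (seed in c(5, 6)) {
    set.seed(seed)
    hr <- thickness_histogram(runif(500, 0.01, 0.4), bin_width_mm = 0.038,
                              start_mm = 0.057)
    expect_equal(sum(hr$percent), 100, tolerance = 1e-4)
  }
  expect_error(thickness_histogram(numeric(0), bin_width_mm = 0.01),
               "empty")
})
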