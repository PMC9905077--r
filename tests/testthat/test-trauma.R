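# Trauma quantification: label differencing, fractions, insertion depth,
# Eshraghi grading, and the end-to-end report round trip.

test_that("identical pre/post volumes yield empty trauma masks", {
  ph <- test_phantom()
  d <- diff_structures(ph$labels, ph$labels)
  expect_true(all(lengths(d) == 0L))
})

test_that("grid mismatches are rejected", {
  ph <- test_phantom()
  small <- cect_labels(ph$labels$data[1:10, 1:10, 1:10],
                       ph$labels$label_map, ph$labels$voxel_size_um)
  expect_error(diff_structures(ph$labels, small), "grid")
})

test_that("a known lesion is recovered exactly as its voxel set", {
  pre <- test_phantom()
  post <- test_post()
  lm <- pre$labels$label_map
  d <- diff_structures(pre$labels, post$labels)
  # the osl trauma mask is exactly the removed voxel set
  removed_osl <- which(pre$labels$data == lm[["osl"]] &
                         post$labels$data != lm[["osl"]])
  expect_identical(d$osl, removed_osl)
  expect_identical(length(d$osl), post$lesions$removed_voxels[1])
  # electrode through open scala: wall structures untouched
  clean <- insert_electrode(pre, 200)
  dc <- diff_structures(pre$labels, clean$labels)
  for (s in c("bm", "osl", "sl", "ssl", "rwm", "rm", "cpb_ooc"))
    expect_identical(length(dc[[s]]), 0L)
})

test_that("traumatized fractions are exact percentages of the pre volume", {
  pre <- test_phantom()
  post <- test_post()
  d <- diff_structures(pre$labels, post$labels)
  expect_identical(traumatized_fraction(pre$labels, integer(0), "osl"), 0)
  expect_equal(traumatized_fraction(pre$labels, d$osl, "osl"),
               post$lesions$percent_of_pre[1])
  full <- which(structure_mask(pre$labels, "rwa"))
  expect_identical(traumatized_fraction(pre$labels, full, "rwa"), 100)
  expect_error(traumatized_fraction(pre$labels, integer(0), "electrode"),
               "empty before insertion")
})

test_that("insertion depth is recovered at the generated value", {
  post <- test_post()
  fr <- fit_frame(post$labels)
  expect_lt(abs(insertion_depth(post$labels, fr) - 380), 3)
  expect_error(insertion_depth(test_phantom()$labels, fr), "no voxels")
})

test_that("a shallow electrode barely past the round window reports ~0 depth", {
  pre <- test_phantom()
  tip <- insert_electrode(pre, 12)
  expect_lt(insertion_depth(tip$labels, pre$frame), 13)
})

test_that("insertion depth is rotation-equivariant within 3 degrees", {
  post <- test_post()
  d0 <- insertion_depth(post$labels, fit_frame(post$labels))
  rot <- rotate_labels_90(post$labels)
  d1 <- insertion_depth(rot, fit_frame(rot))
  expect_lt(abs(d1 - d0), 3)
})

test_that("the Eshraghi scale maps descriptors to the published grades", {
  expect_identical(eshraghi_grade("OSL fracture"), 4L)
  expect_identical(eshraghi_grade("BM elevation"), 1L)
  expect_identical(eshraghi_grade("BM rupture"), 2L)
  expect_identical(eshraghi_grade("electrode in scala vestibuli"), 3L)
  expect_identical(eshraghi_grade("modiolus fracture"), 4L)
  expect_identical(eshraghi_grade("SL/stria tear"), 4L)
  expect_identical(eshraghi_grade(character(0)), 0L)
  expect_identical(eshraghi_grade("none"), 0L)
  # a set maps to its maximum grade
  expect_identical(eshraghi_grade(c("BM elevation", "OSL fracture")), 4L)
  expect_error(eshraghi_grade("membrane bruise"), "unknown")
})

test_that("the trauma report round-trips the generator's lesion table", {
  pre <- test_phantom()
  post <- test_post()
  rep <- build_trauma_report(pre, post)
  les <- post$lesions
  for (i in seq_len(nrow(les))) {
    row <- rep[rep$structure == les$structure[i], ]
    expect_equal(row$traumatized_mm3, les$removed_mm3[i],
                 tolerance = 0.02)
    expect_lt(abs(row$percent_of_pre - les$percent_of_pre[i]), 0.2)
    expect_lt(abs(row$theta_start - les$theta_start[i]), 3)
    expect_lt(abs(row$theta_end - les$theta_end[i]), 3)
    expect_identical(row$descriptor, les$descriptor[i])
    expect_identical(row$grade, eshraghi_grade(les$descriptor[i]))
  }
  expect_identical(attr(rep, "overall_grade"), 4L)
  expect_lt(abs(attr(rep, "insertion_depth_deg") - 380), 3)
})

test_that("untraumatized insertion reports all-zero rows", {
  pre <- test_phantom()
  clean <- insert_electrode(pre, 200)
  rep <- build_trauma_report(pre, clean)
  expect_true(all(rep$grade == 0L))
  expect_true(all(rep$percent_of_pre == 0))
  expect_identical(attr(rep, "overall_grade"), 0L)
})

test_that("sub-resolution membranes are flagged volume-unreliable", {
  pre <- test_phantom()
  post <- test_post()
  # flag rule: ground-truth thickness below two segmentation voxels; the
  # published case is a 25 um basilar membrane at 18.9 um segmentation
  rep <- build_trauma_report(pre$labels, post$labels, frame = pre$frame,
                             thickness_mm = c(bm = 0.025, osl = 0.3))
  expect_true(rep$volume_unreliable[rep$structure == "bm"])
  expect_false(rep$volume_unreliable[rep$structure == "osl"])
  # exactly two voxels thick is considered resolvable
  vox <- pre$labels$voxel_size_um / 1000
  rep2 <- build_trauma_report(pre$labels, post$labels, frame = pre$frame,
                              thickness_mm = c(bm = 2 * vox))
  expect_false(rep2$volume_unreliable[rep2$structure == "bm"])
})

test_that("adding a lesion never decreases a fraction or the overall grade", {
  pre <- test_phantom()
  one <- insert_electrode(pre, 380, list(lesion("bm", "elevation",
                                                c(200, 260), 0.8)))
  two <- insert_electrode(pre, 380, list(lesion("bm", "elevation",
                                                c(200, 260), 0.8),
                                         lesion("osl", "fracture",
                                                c(90, 180))))
  r1 <- build_trauma_report(pre, one)
  r2 <- build_trauma_report(pre, two)
  m <- merge(as.data.frame(r1)[c("structure", "percent_of_pre")],
             as.data.frame(r2)[c("structure", "percent_of_pre")],
             by = "structure")
  expect_true(all(m$percent_of_pre.y >= m$percent_of_pre.x - 1e-9))
  expect_gte(attr(r2, "overall_grade"), attr(r1, "overall_grade"))
})

test_that("scala-vestibuli translocation maps to grade 3", {
  pre <- test_phantom()
  post <- insert_electrode(pre, 380,
                           lesion("bm", "scala-vestibuli translocation",
                                  c(150, 210)))
  expect_identical(post$lesions$descriptor,
                   "electrode in scala vestibuli")
  rep <- build_trauma_report(pre, post)
  expect_gte(attr(rep, "overall_grade"), 3L)
})
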