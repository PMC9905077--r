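# Electrode insertion trauma: pre/post label differencing, traumatized
# fractions, insertion depth, Eshraghi grading, and the combined report.

anatomy_structures <- function(labels) {
  setdiff(names(labels$label_map)[labels$label_map %in%
                                    unique(as.integer(labels$data))],
          c("background", "electrode", "ref_bone", "ref_parafilm"))
}

#' Per-structure trauma masks from pre/post label volumes
#'
#' For each structure, the trauma mask is the set of voxels labelled as the
#' structure before insertion but not after, excluding voxels merely
#' overwritten by the electrode label (an electrode occupying open scala is
#' not trauma; only voxels lost from anatomy labels count).
#'
#' @param pre,post [cect_labels()] volumes on identical grids.
#' @param structures Structures to difference (default: all anatomy labels
#'   present pre-insertion).
#' @return Named list of voxel index vectors (empty integer vector = no
#'   trauma).
#' @export
diff_structures <- function(pre, post, structures = NULL) {
  stopifnot(inherits(pre, "cect_labels"), inherits(post, "cect_labels"))
  if (!identical(dim(pre$data), dim(post$data)) ||
      !identical(pre$voxel_size_um, post$voxel_size_um))
    stop("pre and post volumes must share grid and voxel size")
  if (is.null(structures)) structures <- anatomy_structures(pre)
  lm <- pre$label_map
  el <- lm[["electrode"]]
  out <- lapply(structures, function(s) {
    code <- lm[[s]]
    which(pre$data == code & post$data != code & post$data != el)
  })
  names(out) <- structures
  out
}

#' Traumatized fraction of a structure
#'
#' Percentage of the pre-insertion structure volume affected by trauma.
#'
#' @param pre Pre-insertion [cect_labels()].
#' @param trauma_mask Voxel index vector (from [diff_structures()]) or
#'   logical array.
#' @param structure Structure name.
#' @return Percentage in `[0, 100]`.
#' @export
traumatized_fraction <- function(pre, trauma_mask, structure) {
  n_pre <- sum(pre$data == pre$label_map[[structure]])
  if (n_pre == 0L) stop("structure '", structure,
                        "' empty before insertion")
  n_tr <- if (is.logical(trauma_mask)) sum(trauma_mask) else
    length(trauma_mask)
  100 * n_tr / n_pre
}

#' Angular insertion depth of the electrode
#'
#' Maximum unwrapped angular position over electrode voxels.
#'
#' @param labels Post-insertion [cect_labels()] containing an electrode
#'   label.
#' @param frame A `cochlear_frame`.
#' @return Depth in degrees.
#' @export
insertion_depth <- function(labels, frame) {
  idx <- which(structure_mask(labels, "electrode"))
  max(angular_position(idx, frame, labels = labels))
}

eshraghi_scale <- c("none" = 0L,
                    "BM elevation" = 1L,
                    "BM rupture" = 2L,
                    "electrode in scala vestibuli" = 3L,
                    "OSL fracture" = 4L,
                    "modiolus fracture" = 4L,
                    "SL/stria tear" = 4L)

#' Eshraghi trauma grade
#'
#' Ordinal 0-4 insertion-trauma grade: 0 no observable trauma, 1 elevation
#' of the basilar membrane, 2 rupture of the basilar membrane, 3 electrode
#' in the scala vestibuli, 4 severe trauma (fracture of the osseous spiral
#' lamina or modiolus, or tear of the stria vascularis within the spiral
#' ligament). A set of descriptors maps to the maximum grade present; the
#' empty set maps to 0.
#'
#' @param descriptors Character vector drawn from the controlled vocabulary
#'   `"none"`, `"BM elevation"`, `"BM rupture"`,
#'   `"electrode in scala vestibuli"`, `"OSL fracture"`,
#'   `"modiolus fracture"`, `"SL/stria tear"`.
#' @return Integer grade 0-4.
#' @export
eshraghi_grade <- function(descriptors) {
  descriptors <- descriptors[!is.na(descriptors)]
  if (!length(descriptors)) return(0L)
  unknown <- setdiff(descriptors, names(eshraghi_scale))
  if (length(unknown))
    stop("unknown trauma descriptor(s): ", paste(unknown, collapse = ", "))
  max(eshraghi_scale[descriptors])
}

#' Build a per-structure trauma report
#'
#' Differences the pre- and post-insertion label volumes and composes, per
#' non-fluid anatomical structure: traumatized volume, percentage of the
#' pre-insertion structure volume, angular range, frame-aligned bounding
#' dimensions, centerline length of the traumatized region, an Eshraghi
#' descriptor (removal vs displacement is told apart by whether displaced
#' structure voxels reappear elsewhere), and the per-structure grade.
#' Structures whose ground-truth thickness is below two voxels at the
#' working resolution are flagged volume-unreliable. Electrode voxels whose
#' pre-insertion label was scala vestibuli add the scala-vestibuli
#' descriptor.
#'
#' @param pre,post Pre/post [cect_labels()] volumes (or `cect_phantom`
#'   objects, in which case the frame and thickness truths are taken from
#'   the pre phantom unless given).
#' @param frame A `cochlear_frame`; defaults to the pre phantom's.
#' @param thickness_mm Optional named vector of ground-truth structure
#'   thicknesses (mm) driving the reliability flag.
#' @return A `trauma_report` tibble with one row per structure and
#'   attributes `insertion_depth_deg` and `overall_grade`.
#' @export
build_trauma_report <- function(pre, post, frame = NULL,
                                thickness_mm = NULL) {
  if (inherits(pre, "cect_phantom")) {
    if (is.null(frame)) frame <- pre$frame
    if (is.null(thickness_mm)) {
      tr <- pre$truth
      th <- tr$value[grepl("^thickness_mm\\.", tr$metric)]
      names(th) <- sub("^thickness_mm\\.", "", tr$metric[
        grepl("^thickness_mm\\.", tr$metric)])
      thickness_mm <- th
    }
    pre <- pre$labels
  }
  if (inherits(post, "cect_phantom")) post <- post$labels
  if (is.null(frame)) stop("a cochlear frame is required")
  vox <- pre$voxel_size_um / 1000
  dims <- dim(pre$data)
  masks <- diff_structures(pre, post)
  fluid <- names(pre$class_map)[pre$class_map == "fluid"]
  structures <- setdiff(names(masks), fluid)

  has_el <- "electrode" %in% names(post$label_map) &&
    any(post$data == post$label_map[["electrode"]])
  depth <- if (has_el) insertion_depth(post, frame) else NA_real_
  sv_descriptor <- has_el &&
    any(pre$data[post$data == post$label_map[["electrode"]]] ==
          pre$label_map[["sv"]])

  e2 <- pracma_cross(frame$axis_dir, frame$zero_dir)
  rows <- lapply(structures, function(s) {
    idx <- masks[[s]]
    n_pre <- sum(pre$data == pre$label_map[[s]])
    n_tr <- length(idx)
    if (n_tr) {
      th <- angular_position(idx, frame, labels = pre)
      p <- voxel_world(idx, dims, vox)
      dims_mm <- c(diff(range(p %*% frame$zero_dir)),
                   diff(range(p %*% e2)),
                   diff(range(p %*% frame$axis_dir))) + vox
      m <- array(FALSE, dims); m[idx] <- TRUE
      clen <- as.numeric(centerline_length(m, pre$voxel_size_um))
      gained <- sum(post$data == pre$label_map[[s]] &
                      pre$data != pre$label_map[[s]])
      displaced <- gained >= 0.5 * n_tr
      desc <- map_eshraghi_descriptor(s, if (displaced) "deformation" else
        "fracture", displaced)
    } else {
      th <- numeric(0); dims_mm <- c(NA_real_, NA_real_, NA_real_)
      clen <- NA_real_; desc <- NA_character_
    }
    unreliable <- !is.null(thickness_mm) && s %in% names(thickness_mm) &&
      thickness_mm[[s]] < 2 * vox
    tibble::tibble(
      structure = s,
      traumatized_mm3 = n_tr * vox^3,
      percent_of_pre = 100 * n_tr / n_pre,
      theta_start = if (n_tr) min(th) else NA_real_,
      theta_end = if (n_tr) max(th) else NA_real_,
      dim_length_mm = dims_mm[1], dim_width_mm = dims_mm[2],
      dim_height_mm = dims_mm[3],
      centerline_mm = clen,
      descriptor = desc,
      grade = eshraghi_grade(desc),
      volume_unreliable = unreliable)
  })
  out <- do.call(rbind, rows)
  overall <- max(c(0L, out$grade,
                   if (sv_descriptor)
                     eshraghi_grade("electrode in scala vestibuli")))
  attr(out, "insertion_depth_deg") <- depth
  attr(out, "overall_grade") <- overall
  attr(out, "sv_translocation") <- sv_descriptor
  class(out) <- c("trauma_report", class(out))
  out
}

#' @export
print.trauma_report <- function(x, ...) {
  cat(sprintf("<trauma_report> insertion depth %.0f deg, overall grade %d\n",
              attr(x, "insertion_depth_deg"), attr(x, "overall_grade")))
  NextMethod()
}
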