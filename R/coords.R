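# Cylindrical cochlear coordinate system: modiolar axis, basal plane, 0 deg
# at the round window membrane center, angles unwrapped base-to-apex.

new_cochlear_frame <- function(axis_point, axis_dir, zero_dir, handedness,
                               centerline) {
  axis_point <- unname(axis_point)
  axis_dir <- unname(axis_dir)
  zero_dir <- unname(zero_dir)
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  zero_dir <- zero_dir - sum(zero_dir * axis_dir) * axis_dir
  zero_dir <- zero_dir / sqrt(sum(zero_dir^2))
  structure(list(axis_point = axis_point, axis_dir = axis_dir,
                 zero_dir = zero_dir, handedness = handedness,
                 centerline = centerline),
            class = "cochlear_frame")
}

#' @export
print.cochlear_frame <- function(x, ...) {
  cat(sprintf("<cochlear_frame> %s ear\n", x$handedness))
  cat(sprintf("  axis point (%.2f, %.2f, %.2f) mm, axis (%.3f, %.3f, %.3f)\n",
              x$axis_point[1], x$axis_point[2], x$axis_point[3],
              x$axis_dir[1], x$axis_dir[2], x$axis_dir[3]))
  cat(sprintf("  centerline: %d points, 0-%.0f deg\n",
              nrow(x$centerline), max(x$centerline$theta_deg)))
  invisible(x)
}

frame_sense <- function(frame) if (frame$handedness == "left") 1 else -1

# world coordinates (mm) of voxel linear indices (voxel centers)
voxel_world <- function(idx, dims, vox_mm) {
  idx0 <- idx - 1L
  x <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  z <- idx0 %/% (dims[1] * dims[2])
  cbind(x, y, z) * vox_mm
}

#' Fit the cochlear coordinate frame from a label volume
#'
#' The modiolar axis is the principal axis of the modiolus label (or, when no
#' modiolus label exists, the minimum-variance principal direction of the
#' spiral lumen); the basal plane passes through the basal-turn centerline
#' centroid; the 0 deg reference points from the axis toward the centroid of
#' the round window membrane; handedness is inferred from the spiral's
#' rotation sense so that angles increase from base to apex for both ears.
#'
#' @param labels A [cect_labels()] volume containing at least a spiral lumen
#'   (scala tympani, `"st"`) and an `"rwm"` label; a `"modiolus"` label is
#'   used for the axis when present.
#' @param lumen Structure name of the spiral lumen used for the reference
#'   centerline.
#' @return A `cochlear_frame` with the fitted axis, zero direction,
#'   handedness and the unwrapped lumen centerline used to disambiguate
#'   multi-turn angles.
#' @export
fit_frame <- function(labels, lumen = "st") {
  stopifnot(inherits(labels, "cect_labels"))
  nm <- names(labels$label_map)
  present <- nm[labels$label_map %in% unique(as.integer(labels$data))]
  if (!"rwm" %in% present) stop("labels must contain an 'rwm' structure")
  if (!lumen %in% present && !"modiolus" %in% present)
    stop("labels must contain a 'modiolus' or spiral lumen structure")
  vox <- labels$voxel_size_um / 1000
  dims <- dim(labels$data)

  lumen_mask <- structure_mask(labels, lumen)
  if ("modiolus" %in% present) {
    pm <- voxel_world(which(structure_mask(labels, "modiolus")), dims, vox)
    pc <- prcomp(pm, center = TRUE)
    axis_dir <- pc$rotation[, 1]
    axis_base <- colMeans(pm)
  } else {
    pl <- voxel_world(which(lumen_mask), dims, vox)
    pc <- prcomp(pl, center = TRUE)
    axis_dir <- pc$rotation[, 3] # spiral spreads in-plane; axis = min variance
    axis_base <- colMeans(pl)
  }

  rwm_c <- colMeans(voxel_world(which(structure_mask(labels, "rwm")),
                                dims, vox))

  # lumen centerline, oriented base (round window) to apex
  cl <- mask_centerline_points(lumen_mask, vox)
  pts <- cl$centroids
  d_ends <- c(sum((pts[1, ] - rwm_c)^2), sum((pts[nrow(pts), ] - rwm_c)^2))
  if (d_ends[2] < d_ends[1]) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]

  # orient axis apex-ward
  if (sum((pts[nrow(pts), ] - pts[1, ]) * axis_dir) < 0) axis_dir <- -axis_dir

  # provisional azimuths about the axis, zero toward the RWM centroid
  zero_dir <- rwm_c - axis_base
  zero_dir <- zero_dir - sum(zero_dir * axis_dir) * axis_dir
  zero_dir <- zero_dir / sqrt(sum(zero_dir^2))
  e2 <- pracma_cross(axis_dir, zero_dir)
  rel <- sweep(pts, 2, axis_base)
  az <- atan2(rel %*% e2, rel %*% zero_dir) * 180 / pi
  un <- unwrap_deg(as.vector(az))
  handed <- if (un[length(un)] >= un[1]) "left" else "right"
  sense <- if (handed == "left") 1 else -1
  if (sense < 0) un <- -un

  # basal plane through the first-turn centerline centroid
  first_turn <- pts[un - un[1] <= 360, , drop = FALSE]
  basal_c <- colMeans(first_turn)
  axis_point <- axis_base +
    sum((basal_c - axis_base) * axis_dir) * axis_dir

  zeta <- as.vector(sweep(pts, 2, axis_point) %*% axis_dir)
  rho <- sqrt(rowSums((sweep(pts, 2, axis_point) -
                         outer(zeta, axis_dir))^2))
  # azimuths are measured from zero_dir, so the unwrapped sequence itself is
  # the centerline's angular coordinate (starting near 0 at the round window)
  theta <- un

  ord <- order(theta)
  new_cochlear_frame(axis_point, axis_dir, zero_dir, handed,
                     tibble::tibble(theta_deg = theta[ord],
                                    r_mm = rho[ord], z_mm = zeta[ord]))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

unwrap_deg <- function(az) {
  d <- wrap180(diff(az))
  cumsum(c(az[1], d))
}

azimuth_of <- function(p, axis_point, axis_dir, zero_dir, sense) {
  rel <- sweep(p, 2, axis_point)
  e2 <- pracma_cross(axis_dir, zero_dir) * sense
  atan2(rel %*% e2, rel %*% zero_dir) * 180 / pi
}

#' Unwrapped angular position of points in a cochlear frame
#'
#' Azimuth about the modiolar axis, measured from the 0 deg round-window
#' reference in the direction of increasing insertion (base to apex), and
#' unwrapped along the spiral so that second-turn points report 360-720 deg.
#' The frame's stored lumen centerline disambiguates the turn: for each
#' point, the 360 deg branch whose expected centerline radius/height best
#' matches the point is chosen.
#'
#' @param points Numeric matrix (n x 3) of world coordinates in mm, or a
#'   vector of voxel linear indices together with `labels`.
#' @param frame A `cochlear_frame`.
#' @param labels Optional [cect_labels()]; when given, `points` is
#'   interpreted as voxel indices into it.
#' @return Numeric vector of unwrapped angles (degrees).
#' @export
angular_position <- function(points, frame, labels = NULL) {
  stopifnot(inherits(frame, "cochlear_frame"))
  if (!is.null(labels))
    points <- voxel_world(points, dim(labels$data),
                          labels$voxel_size_um / 1000)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, frame$axis_point)
  zeta <- as.vector(rel %*% frame$axis_dir)
  inplane <- rel - outer(zeta, frame$axis_dir)
  rho <- sqrt(rowSums(inplane^2))
  if (any(rho < 1e-9)) stop("undefined azimuth: point on the modiolar axis")
  sense <- frame_sense(frame)
  az <- as.vector(azimuth_of(points, frame$axis_point, frame$axis_dir,
                             frame$zero_dir, sense))
  cl <- frame$centerline
  th_max <- max(cl$theta_deg)
  ks <- seq(-1, ceiling(th_max / 360))
  best <- rep(Inf, length(az))
  out <- az
  for (k in ks) {
    cand <- az + 360 * k
    ok <- cand >= min(cl$theta_deg) - 200 & cand <= th_max + 200
    r_hat <- approx(cl$theta_deg, cl$r_mm, cand, rule = 2)$y
    z_hat <- approx(cl$theta_deg, cl$z_mm, cand, rule = 2)$y
    cost <- (rho - r_hat)^2 + (zeta - z_hat)^2
    cost[!ok] <- Inf
    upd <- cost < best
    best[upd] <- cost[upd]
    out[upd] <- cand[upd]
  }
  out
}

#' Count cochlear turns
#'
#' Number of revolutions of the spiral lumen: the maximum unwrapped angular
#' position along the lumen centerline divided by 360, reported to 0.1
#' turns.
#'
#' @param labels A [cect_labels()] volume.
#' @param frame A `cochlear_frame` (fitted or ground truth).
#' @param lumen Lumen structure name.
#' @return Number of turns (single numeric, resolution 0.1).
#' @export
count_turns <- function(labels, frame, lumen = "st") {
  vox <- labels$voxel_size_um / 1000
  cl <- mask_centerline_points(structure_mask(labels, lumen), vox)
  th <- angular_position(cl$centroids, frame)
  round(max(th) / 360, 1)
}

#' Overall cochlear dimensions
#'
#' Length is the largest extent of the cochlea in the basal plane along the
#' line through the axis and the round window center (the 0 deg direction);
#' width the largest extent along the in-plane perpendicular; height the
#' extent along the modiolar axis. Extents include the full voxel footprint
#' (peak-to-peak voxel-center distance plus one voxel).
#'
#' @param labels A [cect_labels()] volume.
#' @param frame A `cochlear_frame`.
#' @param exclude Structures excluded from the cochlea mask.
#' @return One-row tibble with `length_mm`, `width_mm`, `height_mm`.
#' @export
measure_cochlea_dimensions <- function(labels, frame,
                                       exclude = c("background", "ref_bone",
                                                   "ref_parafilm",
                                                   "electrode")) {
  vox <- labels$voxel_size_um / 1000
  codes <- labels$label_map[setdiff(names(labels$label_map), exclude)]
  idx <- which(labels$data %in% codes)
  if (!length(idx)) stop("empty cochlea mask")
  p <- voxel_world(idx, dim(labels$data), vox)
  e2 <- pracma_cross(frame$axis_dir, frame$zero_dir)
  ext <- function(dir) diff(range(p %*% dir)) + vox
  tibble::tibble(length_mm = ext(frame$zero_dir),
                 width_mm = ext(e2),
                 height_mm = ext(frame$axis_dir))
}

#' Angular range occupied by a structure
#'
#' Minimum and maximum unwrapped angular position over the structure's
#' voxels.
#'
#' @param labels A [cect_labels()] volume.
#' @param structure Structure name.
#' @param frame A `cochlear_frame`.
#' @return Named numeric vector `c(start_deg, end_deg)`.
#' @export
angular_range <- function(labels, structure, frame) {
  idx <- which(structure_mask(labels, structure))
  th <- angular_position(idx, frame, labels = labels)
  c(start_deg = min(th), end_deg = max(th))
}
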