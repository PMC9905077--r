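# Grey-value conditioning: bit-depth windowing, two-reference affine
# normalization across datasets, block-mean downsampling, the
# reference-material contrast metric, and automated soft-tissue visibility
# grading.

#' Window a volume to 8-bit
#'
#' Linearly rescales grey values so the `lo_pct` percentile maps to 0 and
#' the `hi_pct` percentile to 255, clamping outside; the map is monotone.
#' Percentile (rather than min/max) windowing resists hot pixels.
#'
#' @param volume [cect_volume()] or 3D array.
#' @param lo_pct,hi_pct Window percentiles, `0 <= lo_pct < hi_pct <= 100`.
#' @return An 8-bit [cect_volume()].
#' @export
window_to_8bit <- function(volume, lo_pct = 0.1, hi_pct = 99.9) {
  arr <- as_volume_array(volume)
  vox <- if (inherits(volume, "cect_volume")) volume$voxel_size_um else 1
  if (lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct)
    stop("need 0 <= lo_pct < hi_pct <= 100")
  q <- quantile(arr, c(lo_pct, hi_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) stop("zero dynamic range")
  out <- pmin(pmax((arr - q[1]) / (q[2] - q[1]), 0), 1) * 255
  cect_volume(array(out, dim(arr)), vox, 8L)
}

#' Reference-material masks and target grey values
#'
#' @param mask_a,mask_b Logical arrays for reference material A (cortical
#'   bone of the capsule) and B (parafilm analog); non-empty and disjoint.
#' @param target_a,target_b Target grey values (8-bit scale).
#' @return A `reference_pair`.
#' @export
reference_pair <- function(mask_a, mask_b, target_a = 220, target_b = 60) {
  if (!any(mask_a) || !any(mask_b)) stop("reference masks must be non-empty")
  if (any(mask_a & mask_b)) stop("reference masks must be disjoint")
  structure(list(mask_a = mask_a, mask_b = mask_b,
                 target_a = target_a, target_b = target_b),
            class = "reference_pair")
}

#' Reference pair from phantom labels
#'
#' @param labels [cect_labels()] with `ref_bone` and `ref_parafilm` labels.
#' @param target_a,target_b Target grey values.
#' @return A `reference_pair`.
#' @export
reference_pair_from_labels <- function(labels, target_a = 220,
                                       target_b = 60) {
  reference_pair(structure_mask(labels, "ref_bone"),
                 structure_mask(labels, "ref_parafilm"),
                 target_a, target_b)
}

#' Normalize grey values to two reference materials
#'
#' Applies the unique affine map sending the mean grey over reference mask A
#' to `target_a` and the mean over mask B to `target_b`, matching grey
#' values across datasets acquired on different days. The map is
#' order-preserving whenever the target ordering matches the measured
#' ordering.
#'
#' @param volume [cect_volume()] or 3D array.
#' @param refs A [reference_pair()].
#' @return A normalized [cect_volume()] (8-bit scale).
#' @export
normalize_to_references <- function(volume, refs) {
  stopifnot(inherits(refs, "reference_pair"))
  arr <- as_volume_array(volume)
  vox <- if (inherits(volume, "cect_volume")) volume$voxel_size_um else 1
  mA <- mean(arr[refs$mask_a])
  mB <- mean(arr[refs$mask_b])
  if (isTRUE(all.equal(mA, mB))) stop("degenerate references")
  slope <- (refs$target_a - refs$target_b) / (mA - mB)
  out <- refs$target_b + (arr - mB) * slope
  cect_volume(array(out, dim(arr)), vox, 8L)
}

#' Downsample by block averaging
#'
#' Block-mean binning by an integer factor; the voxel size is multiplied by
#' the factor. Grids that are not exact multiples are cropped (with a
#' warning) to the largest multiple.
#'
#' @param volume [cect_volume()] or 3D array.
#' @param factor Integer >= 1.
#' @return A downsampled [cect_volume()].
#' @export
downsample <- function(volume, factor) {
  if (factor < 1 || factor != round(factor)) stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  arr <- as_volume_array(volume)
  vox <- if (inherits(volume, "cect_volume")) volume$voxel_size_um else 1
  bd <- if (inherits(volume, "cect_volume")) volume$bit_depth else 32L
  if (factor == 1L) return(cect_volume(arr, vox, bd))
  d <- dim(arr)
  m <- d %/% factor
  if (any(d %% factor != 0L)) {
    warning("grid not a multiple of factor; cropping to ",
            paste(m * factor, collapse = " x "))
    arr <- arr[seq_len(m[1] * factor), seq_len(m[2] * factor),
               seq_len(m[3] * factor), drop = FALSE]
  }
  a <- colMeans(matrix(arr, nrow = factor))
  a <- array(a, c(m[1], m[2] * factor, m[3] * factor))
  a <- aperm(a, c(2, 1, 3))
  a <- colMeans(matrix(a, nrow = factor))
  a <- array(a, c(m[2], m[1], m[3] * factor))
  a <- aperm(a, c(3, 2, 1))
  a <- colMeans(matrix(a, nrow = factor))
  a <- array(a, c(m[3], m[1], m[2]))
  a <- aperm(a, c(2, 3, 1))
  cect_volume(a, vox * factor, bd)
}

#' Contrast-to-noise ratio between the reference materials
#'
#' Absolute difference of the reference-material mean grey values divided by
#' their pooled standard deviation. Used as the per-dataset image-quality
#' metric.
#'
#' @param volume [cect_volume()] or 3D array.
#' @param refs A [reference_pair()].
#' @return CNR (dimensionless).
#' @export
reference_contrast <- function(volume, refs) {
  stopifnot(inherits(refs, "reference_pair"))
  arr <- as_volume_array(volume)
  a <- arr[refs$mask_a]
  b <- arr[refs$mask_b]
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) stop("zero pooled SD")
  abs(mean(a) - mean(b)) / sp
}

#' Grade soft-tissue visibility per structure and turn
#'
#' Automated proxy of the visual 0-3 grading: a structure voxel is visible
#' when its grey value exceeds the same-turn fluid mean by at least
#' `contrast_threshold`; transmodiolar assessment slices are azimuthal
#' sectors of width `sector_deg`; per slice the structure is "entire" when
#' at least `entire_frac` of its voxels are visible and "partial" when any
#' are. Grades: 3 = entire on all slices containing the structure, 2 =
#' partial on all slices, 1 = partial on some slices, 0 = not visible.
#'
#' @param volume Grey [cect_volume()] (same grid as `labels`).
#' @param labels [cect_labels()].
#' @param frame A `cochlear_frame`.
#' @param contrast_threshold Grey-value excess over fluid for visibility.
#' @param structures Soft-tissue structures to grade.
#' @param sector_deg Angular width of an assessment slice.
#' @param entire_frac Visible fraction for "entirely visible".
#' @return Tibble with columns `structure`, `turn`, `grade`, `n_slices`,
#'   and a list column `slice_fractions`.
#' @export
grade_visibility <- function(volume, labels, frame, contrast_threshold,
                             structures = c("bm", "sl", "rm", "cpb_ooc"),
                             sector_deg = 5, entire_frac = 0.95) {
  arr <- as_volume_array(volume)
  stopifnot(identical(dim(arr), dim(labels$data)))
  n_turns <- ceiling(max(frame$centerline$theta_deg) / 360)
  fluid_idx <- which(class_mask(labels, "fluid"))
  if (length(fluid_idx) > 2e5) {
    old <- .Random.seed_save()
    set.seed(1L)
    fluid_idx <- sample(fluid_idx, 2e5)
    .Random.seed_restore(old)
  }
  th_f <- angular_position(fluid_idx, frame, labels = labels)
  turn_f <- pmin(pmax(floor(th_f / 360) + 1, 1), n_turns)
  fluid_mean <- vapply(seq_len(n_turns), function(t) {
    v <- arr[fluid_idx[turn_f == t]]
    if (length(v)) mean(v) else mean(arr[fluid_idx])
  }, numeric(1))

  rows <- list()
  for (s in structures) {
    idx <- which(structure_mask(labels, s)) # errors when absent
    th <- angular_position(idx, frame, labels = labels)
    turn <- pmin(pmax(floor(th / 360) + 1, 1), n_turns)
    sector <- floor((th %% 360) / sector_deg)
    vis <- arr[idx] >= fluid_mean[turn] + contrast_threshold
    for (t in sort(unique(turn))) {
      in_t <- turn == t
      fr <- tapply(vis[in_t], sector[in_t], mean)
      grade <- if (all(fr >= entire_frac)) 3L
      else if (all(fr > 0)) 2L
      else if (any(fr > 0)) 1L
      else 0L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        structure = s, turn = t, grade = grade, n_slices = length(fr),
        slice_fractions = list(as.numeric(fr)))
    }
  }
  do.call(rbind, rows)
}
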