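# Desk-scale parallel-beam tomography: slice-wise forward projection and
# filtered backprojection (the parallel-beam specialization of the FDK
# reconstruction used on the scanner).

#' Forward projection (parallel beam, slice-wise)
#'
#' Computes, for every axial slice and view angle, the discretized line
#' integrals of attenuation over a detector row. Rays are sampled at
#' voxel-size steps with bilinear interpolation. The detector spacing
#' equals the voxel size; by default the detector is wide enough to cover
#' the in-plane diagonal, so no truncation occurs.
#'
#' @param volume A [cect_volume()] of attenuations (1/mm) or a 3D array
#'   with `voxel_size_um` supplied.
#' @param angles_deg View angles in degrees, unique, in `[0, 360)`.
#' @param n_det Number of detector bins (default: covers the diagonal).
#' @param noise_sd Additive Gaussian noise (attenuation * mm) applied to the
#'   line integrals with `seed`.
#' @param seed Seed for the noise.
#' @param voxel_size_um Voxel size when `volume` is a plain array.
#' @return A `projection_set`: sinogram array `[n_det, n_angles, n_slices]`
#'   (attenuation * mm), angles, detector spacing and geometry metadata,
#'   with a `truncated` flag when the detector is narrower than the
#'   diagonal.
#' @export
forward_project <- function(volume, angles_deg = seq(0, 359, by = 1),
                            n_det = NULL, noise_sd = 0, seed = 1L,
                            voxel_size_um = NULL) {
  arr <- as_volume_array(volume)
  vox_um <- if (inherits(volume, "cect_volume")) volume$voxel_size_um else
    voxel_size_um
  if (is.null(vox_um)) stop("voxel size required")
  if (anyNA(arr)) stop("volume contains NaN/NA values")
  if (any(duplicated(angles_deg))) stop("angles must be unique")
  if (any(angles_deg < 0 | angles_deg >= 360))
    stop("angles must lie in [0, 360)")
  d <- dim(arr)
  diag_need <- ceiling(sqrt(d[1]^2 + d[2]^2)) + 3L
  if (is.null(n_det)) n_det <- diag_need
  truncated <- n_det < diag_need
  sino <- cpp_forward_project(as.vector(arr), d[1], d[2], d[3],
                              angles_deg * pi / 180, as.integer(n_det), 1.0)
  sino <- array(sino * vox_um / 1000, c(n_det, length(angles_deg), d[3]))
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    sino <- sino + rnorm(length(sino), 0, noise_sd)
    .Random.seed_restore(old)
  }
  structure(list(data = sino, angles_deg = angles_deg,
                 detector_spacing_um = vox_um, voxel_size_um = vox_um,
                 vol_dim = d, truncated = truncated,
                 noise_sd = noise_sd, seed = seed),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<projection_set> %d detector bins x %d angles x %d slices @ %.3g um%s\n",
    d[1], d[2], d[3], x$detector_spacing_um,
    if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

# exact adjoint of the forward projector (used by FBP and in tests)
back_project <- function(sino_arr, angles_deg, vol_dim, step = 1.0) {
  bp <- cpp_back_project(as.vector(sino_arr), vol_dim[1], vol_dim[2],
                         vol_dim[3], angles_deg * pi / 180,
                         dim(sino_arr)[1], step)
  array(bp, vol_dim)
}

# ramp filter with Hann apodization, applied along detector rows
filter_sinogram <- function(slice_mat, spacing_mm, cutoff = 1) {
  n_det <- nrow(slice_mat)
  N <- 2^ceiling(log2(2 * n_det))
  fr <- c(0:(N / 2), -(N / 2 - 1):-1) / (N * spacing_mm) # cycles/mm
  fc <- cutoff / (2 * spacing_mm)
  H <- abs(fr) * ifelse(abs(fr) <= fc,
                        0.5 * (1 + cos(pi * fr / fc)), 0)
  P <- rbind(slice_mat, matrix(0, N - n_det, ncol(slice_mat)))
  Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / N
  Q[seq_len(n_det), , drop = FALSE]
}

#' Filtered backprojection reconstruction
#'
#' Slice-wise parallel-beam FBP: ramp filter with Hann apodization along
#' detector rows, then backprojection with the exact adjoint of the forward
#' projector. The operation is linear in the projections.
#'
#' @param projections A `projection_set`.
#' @param cutoff Relative frequency cutoff of the Hann window (1 = Nyquist).
#' @return A [cect_volume()] of attenuations on the original grid.
#' @export
reconstruct_fbp <- function(projections, cutoff = 1) {
  stopifnot(inherits(projections, "projection_set"))
  if (length(projections$angles_deg) < 2L)
    stop("insufficient angular sampling")
  d <- dim(projections$data)
  spacing_mm <- projections$detector_spacing_um / 1000
  filt <- projections$data
  for (z in seq_len(d[3]))
    filt[, , z] <- filter_sinogram(projections$data[, , z], spacing_mm,
                                   cutoff)
  vol <- back_project(filt, projections$angles_deg, projections$vol_dim)
  vol <- vol * pi / length(projections$angles_deg)
  cect_volume(vol, projections$voxel_size_um, 32L)
}
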