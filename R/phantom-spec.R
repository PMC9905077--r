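#' Cochlear phantom specification
#'
#' Defines the full parameterization of the synthetic cochlea: an elliptical
#' spiral duct (scala tympani + media + vestibuli sharing one duct
#' cross-section) whose radius decays exponentially with unwrapped angle,
#' intradutal membranes and laminae at absolute thicknesses, a bony capsule
#' and modiolus, Rosenthal's canal, the round window membrane and arch, and
#' two reference-material blocks. All linear sizes are micrometres, angular
#' ranges are degrees of unwrapped azimuth (0 deg at the round window
#' membrane center, increasing base to apex).
#'
#' The spiral is parameterized directly by azimuth: the centerline radius at
#' unwrapped angle psi is `exp(-lambda*psi) * e(psi)` where `e` is the radius
#' of an ellipse with semi-axes `a0` (toward the round window) and `b0`, and
#' `lambda = -log(1 - radius_decay) / 2pi`. `a0`, `b0` and the axial pitch
#' are solved so the generated cochlea has exactly the requested bounding
#' length, width and height.
#'
#' @param grid_dim Integer vector of 3 voxel counts.
#' @param voxel_size_um Isotropic voxel size (micrometres).
#' @param turns Number of spiral revolutions (> 0).
#' @param length_mm,width_mm,height_mm Target bounding dimensions of the
#'   cochlea (mm), measured as largest extent along the round-window line,
#'   its in-plane perpendicular, and the modiolar axis.
#' @param radius_decay Fraction of spiral radius lost per turn (0-1).
#' @param duct_radius_um Basal radius of the scalae duct cross-section; the
#'   duct radius decays with the same per-turn factor as the spiral radius.
#' @param rwm_thickness_um,bm_thickness_um,rm_thickness_um Membrane
#'   thicknesses (round window membrane, basilar membrane, Reissner
#'   membrane).
#' @param osl_thickness_um,ssl_thickness_um,rwa_thickness_um Bony lamina
#'   thicknesses (osseous spiral lamina, secondary spiral lamina, round
#'   window arch).
#' @param cpb_height_um Height of the cochlear partition bridge / organ of
#'   Corti block sitting on the basilar membrane.
#' @param sl_thickness_um Spiral ligament lining thickness (capped at 35% of
#'   the local duct radius so apical turns keep an open lumen).
#' @param capsule_thickness_um Bony capsule shell thickness.
#' @param modiolus_radius_um Radius of the central modiolar bone cylinder.
#' @param rc_radius_um,rc_offset_um Rosenthal's canal tube radius and its
#'   radial offset inward from the duct wall.
#' @param wall_min_um Minimum bone wall enforced between adjacent turns.
#' @param rwm_range_deg,rwa_range_deg,ssl_range_deg,rc_range_deg Angular
#'   ranges (degrees unwrapped) of the round window membrane window, round
#'   window arch, secondary spiral lamina and Rosenthal's canal.
#' @param attenuation Named numeric vector of attenuations (1/mm) per
#'   material class; must cover every class emitted.
#' @param reference_block_um Edge length of the two reference-material cubes.
#' @param noise_sd Gaussian grey-value texture noise (1/mm), applied with
#'   `seed`.
#' @param handedness `"left"` or `"right"`; right ears are mirror images.
#' @param seed Integer seed for any stochastic texture.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(grid_dim = c(192L, 192L, 192L),
                         voxel_size_um = 56,
                         turns = 2.8,
                         length_mm = 9.5,
                         width_mm = 6.8,
                         height_mm = 4.2,
                         radius_decay = 0.45,
                         duct_radius_um = 850,
                         rwm_thickness_um = 170,
                         bm_thickness_um = 90,
                         rm_thickness_um = 80,
                         osl_thickness_um = 140,
                         ssl_thickness_um = 160,
                         rwa_thickness_um = 220,
                         cpb_height_um = 160,
                         sl_thickness_um = 280,
                         capsule_thickness_um = 350,
                         modiolus_radius_um = 450,
                         rc_radius_um = 160,
                         rc_offset_um = 300,
                         wall_min_um = 120,
                         rwm_range_deg = c(-18, 18),
                         rwa_range_deg = c(0, 80),
                         ssl_range_deg = c(0, 572),
                         rc_range_deg = c(0, 990),
                         attenuation = default_attenuation(),
                         reference_block_um = 600,
                         noise_sd = 0,
                         handedness = c("left", "right"),
                         seed = 1L) {
  handedness <- match.arg(handedness)
  if (!is.numeric(turns) || length(turns) != 1L || !is.finite(turns) ||
      turns <= 0)
    stop("turns must be > 0")
  if (radius_decay <= 0 || radius_decay >= 1)
    stop("radius_decay must be in (0, 1)")
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3L || any(grid_dim < 16L))
    stop("grid_dim must be three integers >= 16")

  vox <- voxel_size_um
  thick <- c(rwm = rwm_thickness_um, bm = bm_thickness_um,
             rm = rm_thickness_um, osl = osl_thickness_um,
             ssl = ssl_thickness_um, rwa = rwa_thickness_um,
             cpb_ooc = cpb_height_um, sl = sl_thickness_um,
             capsule = capsule_thickness_um, rc = 2 * rc_radius_um)
  if (any(thick <= 0)) stop("all thicknesses must be > 0")
  sub <- names(thick)[thick < vox]
  if (length(sub))
    stop("structure(s) thinner than one voxel at ", vox, " um: ",
         paste(sub, collapse = ", "))

  lambda <- -log(1 - radius_decay) / (2 * pi)   # per radian of azimuth
  duct_apex_um <- duct_radius_um * (1 - radius_decay)^turns
  if (2 * duct_apex_um < vox)
    stop("structure(s) thinner than one voxel at ", vox,
         " um: apical scala duct")

  # solve the spiral ellipse semi-axes and pitch from the target dimensions;
  # the duct radius decays with angle, so the far-side envelope uses the
  # decayed duct radius (u = decay factor per quarter turn)
  u <- exp(-lambda * pi / 2)
  duct_mm0 <- duct_radius_um / 1000
  cap_mm0 <- capsule_thickness_um / 1000
  a0 <- (length_mm - 2 * cap_mm0) / (1 + u^2) - duct_mm0
  b0 <- (width_mm - 2 * cap_mm0) / (u + u^3) - duct_mm0
  if (a0 <= 0 || b0 <= 0)
    stop("target length/width too small for the duct and capsule radii")
  duct_mm <- duct_radius_um / 1000
  cap_mm <- capsule_thickness_um / 1000
  duct_apex_mm <- duct_apex_um / 1000
  pitch_mm <- (height_mm - duct_mm - duct_apex_mm - 2 * cap_mm) / turns
  if (pitch_mm <= 0)
    stop("target height too small for the duct and capsule radii")

  need_classes <- c("background", "fluid", "soft", "bone", "porous_bone",
                    "parafilm", "metal")
  if (!all(need_classes %in% names(attenuation)))
    stop("attenuation table missing classes: ",
         paste(setdiff(need_classes, names(attenuation)), collapse = ", "))

  # extent check: the rasterized cochlea must fit the grid
  R_out <- duct_mm0 + cap_mm0
  ext_x <- a0 * exp(lambda * abs(min(rwm_range_deg)) * pi / 180) + R_out +
    a0 * exp(-lambda * pi) + R_out
  ext_y <- 2 * (b0 * exp(-lambda * pi / 2) + R_out)
  fov <- grid_dim * vox / 1000
  if (ext_x > fov[1] || ext_y > fov[2] || height_mm > fov[3])
    stop("cochlea (", sprintf("%.1f x %.1f x %.1f", ext_x, ext_y, height_mm),
         " mm) does not fit the ", sprintf("%.1f", fov[1]), " mm field of view")

  spec0 <- list(
    grid_dim = grid_dim, voxel_size_um = vox, turns = turns,
    length_mm = length_mm, width_mm = width_mm, height_mm = height_mm,
    radius_decay = radius_decay, lambda = lambda,
    a0_mm = a0, b0_mm = b0, pitch_mm = pitch_mm,
    duct_radius_mm = duct_mm,
    thick_mm = c(rwm = rwm_thickness_um, bm = bm_thickness_um,
                 rm = rm_thickness_um, osl = osl_thickness_um,
                 ssl = ssl_thickness_um, rwa = rwa_thickness_um,
                 cpb_ooc = cpb_height_um, sl = sl_thickness_um,
                 capsule = capsule_thickness_um) / 1000,
    modiolus_radius_mm = modiolus_radius_um / 1000,
    rc_radius_mm = rc_radius_um / 1000,
    rc_offset_mm = rc_offset_um / 1000,
    wall_min_mm = wall_min_um / 1000,
    rwm_range_deg = rwm_range_deg, rwa_range_deg = rwa_range_deg,
    ssl_range_deg = pmin(ssl_range_deg, turns * 360),
    rc_range_deg = pmin(rc_range_deg, turns * 360),
    attenuation = attenuation,
    reference_block_um = reference_block_um,
    noise_sd = noise_sd, handedness = handedness, seed = as.integer(seed))
  class(spec0) <- "phantom_spec"
  # refine the analytic solve against the exact numeric envelope so the
  # generated bounding dimensions hit the targets to well below a voxel
  for (i in 1:4) {
    ext <- truth_extents(spec0)
    spec0$a0_mm <- spec0$a0_mm + (length_mm - ext[["length"]]) / (1 + u^2)
    spec0$b0_mm <- spec0$b0_mm + (width_mm - ext[["width"]]) / (u + u^3)
    spec0$pitch_mm <- spec0$pitch_mm +
      (height_mm - ext[["height"]]) / turns
    if (spec0$a0_mm <= 0 || spec0$b0_mm <= 0 || spec0$pitch_mm <= 0)
      stop("target dimensions infeasible for the duct and capsule radii")
  }
  spec0
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %.1f turns, %g x %g x %g mm, %s ear\n",
    x$turns, x$length_mm, x$width_mm, x$height_mm, x$handedness))
  cat(sprintf("  grid %d x %d x %d @ %.3g um, seed %d\n",
              x$grid_dim[1], x$grid_dim[2], x$grid_dim[3],
              x$voxel_size_um, x$seed))
  invisible(x)
}

# centerline radius (mm) at unwrapped azimuth psi (deg)
spiral_radius <- function(spec, psi_deg) {
  phi <- psi_deg * pi / 180
  ell <- spec$a0_mm * spec$b0_mm /
    sqrt((spec$b0_mm * cos(phi))^2 + (spec$a0_mm * sin(phi))^2)
  exp(-spec$lambda * phi) * ell
}

spiral_z <- function(spec, psi_deg) spec$pitch_mm * psi_deg / 360

duct_radius_at <- function(spec, psi_deg) {
  # the short basal vestibule (psi < 0, behind the round window) keeps the
  # basal duct radius
  spec$duct_radius_mm * exp(-spec$lambda * pmax(psi_deg, 0) * pi / 180)
}

# Cartesian centerline point(s); handedness handled by the caller
spiral_point <- function(spec, psi_deg) {
  r <- spiral_radius(spec, psi_deg)
  phi <- psi_deg * pi / 180
  cbind(x = r * cos(phi), y = r * sin(phi), z = spiral_z(spec, psi_deg))
}
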