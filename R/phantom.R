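# Synthetic cochlear phantom: rasterization, ground truth, rendering.
#
# The same continuous classifier (classify_duct_section) is evaluated on the
# voxel grid by generate_phantom() and on a fine quadrature grid by
# truth_measurements(), so the ground-truth table is independent of the
# raster but shares the single geometric definition.

# ---- continuous cross-section classifier ------------------------------------
# a: radial offset from duct centerline (mm, + outward); b: axial offset
# (mm, + apex-ward); psi: unwrapped azimuth (deg); R: local duct radius (mm).
# Returns label codes for points inside the duct (distance <= R); 0 outside.
classify_duct_section <- function(a, b, psi, R, spec) {
  t <- spec$thick_mm
  code <- integer(length(a))
  d <- sqrt(a^2 + b^2)
  inside <- d <= R
  mem <- psi >= 0  # membranes/laminae exist along the spiral proper
  t_part <- max(t[["osl"]], t[["bm"]])

  osl <- inside & mem & abs(b) <= t[["osl"]] / 2 & a <= -0.10 * R
  ssl <- inside & psi >= spec$ssl_range_deg[1] & psi <= spec$ssl_range_deg[2] &
    abs(b) <= t[["ssl"]] / 2 & a >= 0.62 * R
  bm <- inside & mem & abs(b) <= t[["bm"]] / 2 & a > -0.10 * R & a <= 0.38 * R
  cpb <- inside & mem & b > t[["bm"]] / 2 & b <= t[["bm"]] / 2 + t[["cpb_ooc"]] &
    a > -0.10 * R & a <= 0.22 * R
  rm <- inside & mem & abs(b - 0.38 * R) <= t[["rm"]] / 2 &
    a > -0.10 * R & a <= 0.60 * R
  # cap the ligament at 35% of the local duct radius so apical turns keep an
  # open lumen, but never below ~1.5 voxels so it rasterizes continuously
  t_sl <- pmin(t[["sl"]], pmax(0.35 * R, 1.5 * spec$voxel_size_um / 1000))
  sl <- inside & mem & (d >= R - t_sl) & a > 0.25 * R

  lm <- default_label_map()
  code[inside] <- ifelse(b[inside] <= 0, lm[["st"]],
                         ifelse(b[inside] < 0.38 * R[inside] - t[["rm"]] / 2 &
                                  a[inside] > -0.10 * R[inside],
                                lm[["sm"]], lm[["sv"]]))
  code[sl] <- lm[["sl"]]
  code[rm] <- lm[["rm"]]
  code[cpb] <- lm[["cpb_ooc"]]
  code[bm] <- lm[["bm"]]
  code[ssl] <- lm[["ssl"]]
  code[osl] <- lm[["osl"]]
  # keep the basal vestibule (psi < 0, behind the round window) open fluid
  code[inside & !mem] <- lm[["st"]]
  code
}

# ---- per-voxel duct geometry ------------------------------------------------
# Computes, for every voxel, the best (nearest) and second-best spiral-turn
# candidate margins plus the local duct coordinates of the best candidate.
duct_geometry <- function(spec) {
  nd <- spec$grid_dim
  vox <- spec$voxel_size_um / 1000
  cap <- spec$thick_mm[["capsule"]]

  # world coordinates (voxel centers, mm, origin at first voxel center)
  wx <- (seq_len(nd[1]) - 1) * vox
  wy <- (seq_len(nd[2]) - 1) * vox
  wz <- (seq_len(nd[3]) - 1) * vox
  ctr <- c((nd[1] - 1), (nd[2] - 1), (nd[3] - 1)) / 2 * vox

  # axis placement: center the cochlea's bounding interval in the grid
  psi_grid <- seq(min(spec$rwm_range_deg), spec$turns * 360, by = 2)
  r_g <- spiral_radius(spec, psi_grid)
  R_g <- duct_radius_at(spec, psi_grid) + cap
  phi_g <- psi_grid * pi / 180
  x_lo <- min((r_g - R_g) * cos(phi_g), (r_g + R_g) * cos(phi_g))
  x_hi <- max((r_g - R_g) * cos(phi_g), (r_g + R_g) * cos(phi_g))
  z_lo <- min(spiral_z(spec, psi_grid) - R_g)
  z_hi <- max(spiral_z(spec, psi_grid) + R_g)
  axis_xy <- c(ctr[1] - (x_lo + x_hi) / 2, ctr[2])
  z0 <- ctr[3] - (z_lo + z_hi) / 2  # world z of the psi = 0 centerline point

  sgn <- if (spec$handedness == "left") 1 else -1
  X <- rep(wx - axis_xy[1], times = nd[2] * nd[3])
  Y <- rep(rep(sgn * (wy - axis_xy[2]), each = nd[1]), times = nd[3])
  Z <- rep(wz - z0, each = nd[1] * nd[2])

  rho <- sqrt(X^2 + Y^2)
  phi <- atan2(Y, X) * 180 / pi
  phi <- phi %% 360
  base_r <- spec$a0_mm * spec$b0_mm /
    sqrt((spec$b0_mm * X / pmax(rho, 1e-9))^2 +
           (spec$a0_mm * Y / pmax(rho, 1e-9))^2)

  n <- length(X)
  m1 <- rep(Inf, n); m2 <- rep(Inf, n)
  psi1 <- numeric(n); dr1 <- numeric(n); dz1 <- numeric(n); R1 <- numeric(n)
  rcm <- rep(Inf, n); rcpsi <- numeric(n)
  psi_min <- min(spec$rwm_range_deg)
  psi_max <- spec$turns * 360
  for (k in -1:ceiling(spec$turns)) {
    psi <- phi + 360 * k
    valid <- psi >= psi_min & psi <= psi_max
    decay <- exp(-spec$lambda * psi * pi / 180)
    r_c <- decay * base_r
    z_c <- spec$pitch_mm * psi / 360
    Rk <- duct_radius_at(spec, psi)
    da <- rho - r_c
    db <- Z - z_c
    m <- sqrt(da^2 + db^2) - Rk
    m[!valid] <- Inf
    upd <- m < m1
    m2 <- pmin(m2, ifelse(upd, m1, m))
    m1[upd] <- m[upd]
    psi1[upd] <- psi[upd]; dr1[upd] <- da[upd]
    dz1[upd] <- db[upd]; R1[upd] <- Rk[upd]
    # Rosenthal's canal candidate for this turn
    rc_ok <- valid & psi >= spec$rc_range_deg[1] & psi <= spec$rc_range_deg[2]
    rc_r <- r_c - Rk - spec$rc_offset_mm
    mrc <- sqrt((rho - rc_r)^2 + db^2) - spec$rc_radius_mm
    mrc[!rc_ok | rc_r <= spec$modiolus_radius_mm] <- Inf
    updc <- mrc < rcm
    rcm[updc] <- mrc[updc]; rcpsi[updc] <- psi[updc]
  }
  list(psi = psi1, drad = dr1, dz = dz1, R = R1, m1 = m1, m2 = m2,
       rcm = rcm, rho = rho, Z = Z, dims = nd,
       axis_world = c(axis_xy, z0), sgn = sgn)
}

# ---- phantom generation -----------------------------------------------------

#' Generate a synthetic cochlear phantom
#'
#' Rasterizes the continuous cochlea model described by a [phantom_spec()]
#' into a grey-value volume and a label volume, and attaches the ground-truth
#' coordinate frame and measurement table computed from the continuous model
#' (independently of the raster). The grey volume is rendered fully stained;
#' use [simulate_staining()] for partially stained states.
#'
#' @param spec A [phantom_spec()].
#' @return A `cect_phantom` object with elements `grey` ([cect_volume()]),
#'   `labels` ([cect_labels()]), `frame` (ground-truth [cochlear_frame]),
#'   `truth` (tibble of ground-truth measurements), `theta` (per-voxel
#'   unwrapped angle, deg), `spec`, and internal geometry caches.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- duct_geometry(spec)
  nd <- g$dims
  n <- prod(nd)
  vox <- spec$voxel_size_um / 1000
  t <- spec$thick_mm
  cap <- t[["capsule"]]
  lm <- default_label_map()

  lab <- integer(n)

  # modiolus: central bone cone spanning the cochlea's axial extent
  z_bot <- -spec$duct_radius_mm - cap
  z_top <- spec$pitch_mm * spec$turns + duct_radius_at(spec, spec$turns * 360)
  lab[g$rho <= spec$modiolus_radius_mm & g$Z >= z_bot & g$Z <= z_top] <-
    lm[["modiolus"]]

  # capsule shell, with round window membrane / niche / arch overrides
  shell <- g$m1 > 0 & g$m1 <= cap
  lab[shell] <- lm[["capsule"]]
  outer_lower <- g$dz < 0 & g$drad > 0
  outer_upper <- g$dz >= 0 & g$drad > 0
  in_rwm <- g$psi >= spec$rwm_range_deg[1] & g$psi <= spec$rwm_range_deg[2]
  lab[shell & in_rwm & outer_lower & g$m1 <= t[["rwm"]]] <- lm[["rwm"]]
  lab[shell & in_rwm & outer_lower & g$m1 > t[["rwm"]]] <- 0L  # niche air
  in_rwa <- g$psi >= spec$rwa_range_deg[1] & g$psi <= spec$rwa_range_deg[2]
  lab[shell & in_rwa & outer_upper & g$m1 <= t[["rwa"]]] <- lm[["rwa"]]

  # Rosenthal's canal with a thin bone sheath
  lab[g$rcm > 0 & g$rcm <= spec$wall_min_mm & lab == 0L] <- lm[["capsule"]]
  lab[g$rcm <= 0] <- lm[["rc"]]

  # duct interior: nearest-turn classification with an inter-turn wall
  inner <- which(g$m1 <= 0)
  open_lumen <- inner[g$m2[inner] >= spec$wall_min_mm]
  wall <- inner[g$m2[inner] < spec$wall_min_mm]
  lab[wall] <- lm[["capsule"]]
  lab[open_lumen] <- classify_duct_section(
    g$drad[open_lumen], g$dz[open_lumen], g$psi[open_lumen],
    g$R[open_lumen], spec)

  # reference-material blocks near the low-y grid edge
  blk <- max(3L, round(spec$reference_block_um / spec$voxel_size_um))
  bx <- round(nd[1] / 2) + c(-2L * blk, 2L * blk)
  by <- 3L
  bz <- round(nd[3] / 2)
  ref_idx <- function(x0) {
    ii <- (x0):(x0 + blk - 1L); jj <- by:(by + blk - 1L)
    kk <- (bz):(bz + blk - 1L)
    as.vector(outer(outer(ii, (jj - 1L) * nd[1], "+"),
                    (kk - 1L) * nd[1] * nd[2], "+"))
  }
  ib <- ref_idx(bx[1]); ip <- ref_idx(bx[2])
  if (any(lab[c(ib, ip)] != 0L))
    stop("reference blocks would overlap anatomy; enlarge the grid")
  lab[ib] <- lm[["ref_bone"]]
  lab[ip] <- lm[["ref_parafilm"]]

  lab_arr <- array(lab, nd)
  labels <- cect_labels(lab_arr, lm, spec$voxel_size_um)
  theta <- array(g$psi, nd)
  grey <- render_phantom_grey(labels, spec, uptake = NULL)
  frame <- truth_frame(spec, g)
  truth <- truth_measurements(spec)

  structure(
    list(grey = grey, labels = labels, frame = frame, truth = truth,
         theta = theta, spec = spec,
         geom = list(psi = g$psi, drad = g$drad, dz = g$dz, R = g$R,
                     dims = nd),
         lesions = NULL, insertion_depth_deg = NULL),
    class = "cect_phantom")
}

#' @export
print.cect_phantom <- function(x, ...) {
  cat(sprintf("<cect_phantom> %.1f turns, %s ear, grid %s @ %.3g um\n",
              x$spec$turns, x$spec$handedness,
              paste(dim(x$labels$data), collapse = " x "),
              x$spec$voxel_size_um))
  if (!is.null(x$insertion_depth_deg))
    cat(sprintf("  electrode inserted to %.0f deg, %d lesion(s)\n",
                x$insertion_depth_deg,
                if (is.null(x$lesions)) 0L else nrow(x$lesions)))
  invisible(x)
}

# Render attenuation grey values from labels. `uptake` is a per-voxel
# contrast multiplier in [0,1] for soft tissue (NULL = fully stained).
render_phantom_grey <- function(labels, spec, uptake = NULL) {
  att <- spec$attenuation
  cls <- labels$class_map[match(labels$data, labels$label_map)]
  grey <- att[match(cls, names(att))]
  grey[is.na(grey)] <- 0
  soft <- which(cls == "soft")
  u <- if (is.null(uptake)) 1 else uptake[soft]
  grey[soft] <- att[["fluid"]] + u * (att[["soft"]] - att[["fluid"]])
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(spec$seed)
    grey <- grey + rnorm(length(grey), 0, spec$noise_sd)
    .Random.seed_restore(old)
  }
  cect_volume(array(grey, dim(labels$data)), spec$voxel_size_um, 32L)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# ---- ground truth -----------------------------------------------------------

# continuous cross-section quadrature: per-structure volume (mm^3) and the
# scala-tympani centroid track used for centerline-length truth
truth_quadrature <- function(spec, n_psi = 480, n_ab = 72) {
  psi_min <- min(spec$rwm_range_deg)
  psi <- seq(psi_min, spec$turns * 360, length.out = n_psi + 1)
  psi <- (psi[-1] + psi[-length(psi)]) / 2
  dphi <- ((spec$turns * 360 - psi_min) / n_psi) * pi / 180
  vol <- setNames(numeric(nrow(cochlear_label_table())),
                  cochlear_label_table()$name)
  st_cent <- matrix(0, n_psi, 2)
  lm <- default_label_map()
  for (i in seq_len(n_psi)) {
    R <- duct_radius_at(spec, psi[i])
    r_c <- spiral_radius(spec, psi[i])
    s <- seq(-R, R, length.out = n_ab + 1)
    s <- (s[-1] + s[-length(s)]) / 2
    da <- (2 * R / n_ab)^2
    ab <- expand.grid(a = s, b = s)
    code <- classify_duct_section(ab$a, ab$b, rep(psi[i], nrow(ab)),
                                  rep(R, nrow(ab)), spec)
    w <- (r_c + ab$a) * da * dphi
    for (cd in unique(code[code > 0])) {
      nm <- names(lm)[match(cd, lm)]
      vol[nm] <- vol[nm] + sum(w[code == cd])
    }
    stm <- code == lm[["st"]]
    st_cent[i, ] <- c(sum(ab$a[stm] * w[stm]) / sum(w[stm]),
                      sum(ab$b[stm] * w[stm]) / sum(w[stm]))
  }
  # round window membrane shell patch
  rw <- spec$rwm_range_deg
  psi_w <- seq(rw[1], rw[2], length.out = 60)
  psi_wm <- (psi_w[-1] + psi_w[-60]) / 2
  dphi_w <- diff(rw) / 59 * pi / 180
  v_rwm <- 0
  for (p in psi_wm) {
    R <- duct_radius_at(spec, p); r_c <- spiral_radius(spec, p)
    # lower-outer quadrant shell, thickness t_rwm
    ang <- seq(-pi / 2, 0, length.out = 40)
    angm <- (ang[-1] + ang[-40]) / 2
    dang <- (pi / 2) / 39
    rr <- seq(R, R + spec$thick_mm[["rwm"]], length.out = 12)
    rrm <- (rr[-1] + rr[-12]) / 2
    drr <- spec$thick_mm[["rwm"]] / 11
    gr <- expand.grid(u = rrm, v = angm)
    a <- gr$u * cos(gr$v)  # +outward
    w <- (r_c + a) * gr$u * drr * dang * dphi_w
    v_rwm <- v_rwm + sum(w)
  }
  vol[["rwm"]] <- v_rwm
  list(volumes = vol, psi = psi, st_centroid = st_cent)
}

arc_length <- function(x, y, z) sum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))

# centerline length of a curve riding at local duct offset (a(psi), b(psi))
offset_curve_length <- function(spec, psi, a_off, b_off) {
  r <- spiral_radius(spec, psi) + a_off
  phi <- psi * pi / 180
  arc_length(r * cos(phi), r * sin(phi), spiral_z(spec, psi) + b_off)
}

# continuous bounding extents of the whole cochlea (length/width/height, mm)
truth_extents <- function(spec) {
  psi <- seq(min(spec$rwm_range_deg), spec$turns * 360, by = 0.5)
  r <- spiral_radius(spec, psi)
  Rc <- duct_radius_at(spec, psi) + spec$thick_mm[["capsule"]]
  phi <- psi * pi / 180
  x_all <- c((r - Rc) * cos(phi), (r + Rc) * cos(phi))
  y_all <- c((r - Rc) * sin(phi), (r + Rc) * sin(phi))
  z_all <- c(spiral_z(spec, psi) - Rc, spiral_z(spec, psi) + Rc)
  c(length = diff(range(x_all)), width = diff(range(y_all)),
    height = diff(range(z_all)))
}

truth_measurements <- function(spec) {
  q <- truth_quadrature(spec)
  ext <- truth_extents(spec)
  duct_len <- offset_curve_length(spec, q$psi, 0, 0)
  st_len <- arc_length(
    (spiral_radius(spec, q$psi) + q$st_centroid[, 1]) * cos(q$psi * pi / 180),
    (spiral_radius(spec, q$psi) + q$st_centroid[, 1]) * sin(q$psi * pi / 180),
    spiral_z(spec, q$psi) + q$st_centroid[, 2])
  vols <- q$volumes[q$volumes > 0]
  tibble::tibble(
    metric = c("turns", "angular_extent_deg",
               "length_mm", "width_mm", "height_mm",
               paste0("volume_mm3.", names(vols)),
               "centerline_length_mm.duct", "centerline_length_mm.st",
               "thickness_mm.bm", "thickness_mm.rwm", "thickness_mm.rm",
               "ssl_end_deg", "rwa_end_deg", "rc_end_deg"),
    value = c(spec$turns, spec$turns * 360,
              ext[["length"]], ext[["width"]], ext[["height"]],
              unname(vols),
              duct_len, st_len,
              spec$thick_mm[["bm"]], spec$thick_mm[["rwm"]],
              spec$thick_mm[["rm"]],
              spec$ssl_range_deg[2], spec$rwa_range_deg[2],
              spec$rc_range_deg[2]))
}

#' Look up one ground-truth metric of a phantom
#'
#' @param phantom A `cect_phantom`.
#' @param metric Metric name as it appears in `phantom$truth$metric` (e.g.
#'   `"turns"`, `"volume_mm3.st"`, `"ssl_end_deg"`).
#' @return The ground-truth value.
#' @export
truth_value <- function(phantom, metric) {
  tr <- phantom$truth
  v <- tr$value[tr$metric == metric]
  if (!length(v)) stop("no ground-truth metric '", metric, "'")
  v
}

# ground-truth coordinate frame (known exactly from the generation geometry)
truth_frame <- function(spec, g) {
  psi <- seq(0, spec$turns * 360, by = 2)
  new_cochlear_frame(
    axis_point = c(g$axis_world[1], g$axis_world[2], g$axis_world[3]),
    axis_dir = c(0, 0, 1),
    zero_dir = c(1, 0, 0),
    handedness = spec$handedness,
    centerline = tibble::tibble(
      theta_deg = psi,
      r_mm = spiral_radius(spec, psi),
      z_mm = spiral_z(spec, psi)))
}

# ---- high-resolution curved membrane patch ----------------------------------

#' Generate a curved membrane patch at high resolution
#'
#' Rasterizes a spherically curved membrane of uniform thickness (a shell
#' between two concentric spheres, windowed to a patch), emulating the
#' round window membrane at scan resolution for thickness-mapping tests.
#'
#' @param thickness_mm Membrane thickness (default the 0.17 mm upper bound of
#'   the round window membrane's central thickness).
#' @param voxel_size_um Voxel size; default 6.3 (scan resolution).
#' @param curvature_radius_mm Radius of the shell mid-surface.
#' @param patch_mm Lateral extent of the rasterized patch.
#' @return List with `mask` (logical 3D array), `voxel_size_um`, and
#'   `thickness_mm` (ground truth).
#' @export
generate_membrane_patch <- function(thickness_mm = 0.17,
                                    voxel_size_um = 6.3,
                                    curvature_radius_mm = 1.5,
                                    patch_mm = 0.9) {
  if (thickness_mm < voxel_size_um / 1000)
    stop("structure thinner than one voxel: membrane")
  vox <- voxel_size_um / 1000
  R <- curvature_radius_mm
  nxy <- ceiling(patch_mm / vox)
  # shell sag over the patch corners sets the required slab height
  sag <- R - sqrt(R^2 - 2 * (patch_mm / 2)^2)
  nz <- ceiling(thickness_mm / vox) + ceiling(sag / vox) + 12L
  xs <- (seq_len(nxy) - (nxy + 1) / 2) * vox
  zs <- (seq_len(nz) - 1) * vox
  # sphere center below the slab; the shell's top surface sits 6 voxels
  # under the top face
  cz <- (nz - 6) * vox - thickness_mm / 2 - R
  X <- rep(xs, times = nxy * nz)
  Y <- rep(rep(xs, each = nxy), times = nz)
  Z <- rep(zs - cz, each = nxy * nxy)
  d <- sqrt(X^2 + Y^2 + Z^2)
  mask <- abs(d - R) <= thickness_mm / 2
  list(mask = array(mask, c(nxy, nxy, nz)), voxel_size_um = voxel_size_um,
       thickness_mm = thickness_mm)
}
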