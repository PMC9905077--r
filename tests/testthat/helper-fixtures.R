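# Shared fixtures, memoized so expensive phantoms are generated once per
# test run. Problem sizes are desk scale: 144^3 at 75 um for the reference
# phantom, smaller grids for secondary phantoms.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

test_spec <- function(...) {
  phantom_spec(grid_dim = c(144L, 144L, 144L), voxel_size_um = 75,
               seed = 11L, ...)
}

test_phantom <- function() memo("phantom", generate_phantom(test_spec()))

test_frame <- function() memo("frame", fit_frame(test_phantom()$labels))

test_lesions <- function() {
  list(lesion("osl", "fracture", c(90, 180)),
       lesion("bm", "elevation", c(200, 260), fraction = 0.8))
}

test_post <- function() {
  memo("post", insert_electrode(test_phantom(), 380, test_lesions()))
}

# coarser spec for phantoms generated more than once (mirror, cohort, ...)
small_spec <- function(...) {
  phantom_spec(grid_dim = c(120L, 120L, 120L), voxel_size_um = 96,
               bm_thickness_um = 150, rm_thickness_um = 150,
               osl_thickness_um = 200, ssl_thickness_um = 200,
               rwa_thickness_um = 250, rwm_thickness_um = 250,
               cpb_height_um = 200, seed = 11L, ...)
}

# world coordinate arrays for hand-built masks
coord_arrays <- function(dims, vox_mm, origin = c(0, 0, 0)) {
  xs <- (seq_len(dims[1]) - 1) * vox_mm - origin[1]
  ys <- (seq_len(dims[2]) - 1) * vox_mm - origin[2]
  zs <- (seq_len(dims[3]) - 1) * vox_mm - origin[3]
  list(x = array(rep(xs, times = dims[2] * dims[3]), dims),
       y = array(rep(rep(ys, each = dims[1]), times = dims[3]), dims),
       z = array(rep(zs, each = dims[1] * dims[2]), dims))
}

# single-slice disc phantom for projection tests (attenuation 1/mm)
disc_slice <- function(n = 128, vox_um = 50, discs) {
  xs <- (1:n - (n + 1) / 2) * vox_um / 1000
  X <- outer(xs, rep(1, n))
  Y <- outer(rep(1, n), xs)
  sl <- matrix(0, n, n)
  for (d in discs) {
    r <- sqrt((X - d$x)^2 + (Y - d$y)^2)
    sl[r < d$r] <- d$mu
  }
  cect_volume(array(sl, c(n, n, 1)), vox_um)
}

# slice phantom with fluid + bone ring + optional metal, plus region masks
mar_phantom <- function(n = 128, vox_um = 50, with_metal = TRUE) {
  xs <- (1:n - (n + 1) / 2) * vox_um / 1000
  X <- outer(xs, rep(1, n))
  Y <- outer(rep(1, n), xs)
  r <- sqrt(X^2 + Y^2)
  sl <- ifelse(r < 2.2, 0.02, 0)
  sl[r > 1.9 & r < 2.2] <- 0.30
  metal <- sqrt((X - 0.6)^2 + Y^2) < 0.25
  fluid <- array(sl == 0.02 & !metal, c(n, n, 1))
  if (with_metal) sl[metal] <- 3.0
  list(volume = cect_volume(array(sl, c(n, n, 1)), vox_um),
       metal = array(metal, c(n, n, 1)), fluid = fluid)
}

# 90-degree rotation of a label volume about the z axis (exact, no
# resampling): x' = y, y' = -x
rotate_labels_90 <- function(labels) {
  a <- aperm(labels$data, c(2, 1, 3))
  a <- a[dim(a)[1]:1, , , drop = FALSE]
  cect_labels(a, labels$label_map, labels$voxel_size_um, labels$class_map)
}

# brute-force local-thickness oracle (independent pairwise-distance path);
# returns thickness in voxels
bf_thickness <- function(mask, step) {
  dims <- dim(mask)
  idx <- which(mask)
  p <- arrayInd(idx, dims)
  # candidate nearest background voxels: background 26-adjacent to the mask
  bg <- which(!mask)
  pb <- arrayInd(bg, dims)
  keep <- rep(FALSE, length(bg))
  for (k in seq_along(bg)) {
    w <- pb[k, ]
    lo <- pmax(w - 1, 1)
    hi <- pmin(w + 1, dims)
    keep[k] <- any(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }
  pb <- pb[keep, , drop = FALSE]
  # borders of the array also bound the structure
  d2 <- outer(p[, 1], pb[, 1], "-")^2 + outer(p[, 2], pb[, 2], "-")^2 +
    outer(p[, 3], pb[, 3], "-")^2
  e <- sqrt(apply(d2, 1, min))
  dvox <- step * floor((2 * e - 1) / step - 1e-9)
  dvox[dvox < 1] <- 1
  dd <- outer(p[, 1], p[, 1], "-")^2 + outer(p[, 2], p[, 2], "-")^2 +
    outer(p[, 3], p[, 3], "-")^2
  th <- numeric(length(idx))
  for (i in seq_along(idx)) {
    covered <- sqrt(dd[i, ]) <= dvox / 2 + 0.5 + 1e-9
    th[i] <- max(dvox[covered])
  }
  out <- array(0, dims)
  out[idx] <- th
  out
}

random_blob <- function(dims, seed, n_ellipsoids = 3) {
  set.seed(seed)
  cc <- coord_arrays(dims, 1)
  m <- array(FALSE, dims)
  for (i in seq_len(n_ellipsoids)) {
    ctr <- runif(3, dims * 0.3, dims * 0.7)
    ax <- runif(3, 2.5, dims * 0.22)
    m <- m | (((cc$x - ctr[1]) / ax[1])^2 + ((cc$y - ctr[2]) / ax[2])^2 +
                ((cc$z - ctr[3]) / ax[3])^2 <= 1)
  }
  # keep the blob off the array faces so boundaries are real background
  m[c(1, dims[1]), , ] <- FALSE
  m[, c(1, dims[2]), ] <- FALSE
  m[, , c(1, dims[3])] <- FALSE
  m
}
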