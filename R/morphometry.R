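# 3D morphometry on label volumes: volumes, centerline lengths,
# sphere-fitting local thickness, thickness histograms.

#' Structure volume
#'
#' Voxel count times voxel volume.
#'
#' @param labels A [cect_labels()] volume.
#' @param structure Structure name (must be present and non-empty).
#' @param voxel_size_um Override of the voxel size carried by `labels`.
#' @return Volume in mm^3.
#' @export
structure_volume <- function(labels, structure, voxel_size_um = NULL) {
  m <- structure_mask(labels, structure) # errors loudly when empty
  vox <- (if (is.null(voxel_size_um)) labels$voxel_size_um else
            voxel_size_um) / 1000
  sum(m) * vox^3
}

# Euclidean distance (voxel units) from every voxel to nearest TRUE voxel
edt_to <- function(feature) {
  d <- dim(feature)
  array(cpp_edt(as.vector(feature), d[1], d[2], d[3]), d)
}

# ---- centerline -------------------------------------------------------------

# Ordered centerline of a tubular mask: Dijkstra geodesic distances over the
# 26-connected voxel graph (steps 1 / sqrt2 / sqrt3), endpoints by a double
# farthest-point sweep, centerline = per-geodesic-bin voxel centroids.
mask_centerline_points <- function(mask, vox_mm, bin_voxels = 3,
                                   component = NULL) {
  d <- dim(mask)
  comp <- array(cpp_components(as.vector(mask), d[1], d[2], d[3]), d)
  ncomp <- max(comp)
  if (ncomp == 0L) stop("empty mask")
  if (is.null(component)) {
    sizes <- tabulate(comp[comp > 0L], ncomp)
    component <- which.max(sizes)
  }
  m <- comp == component
  mv <- as.vector(m)
  seed <- which(mv)[1]
  d0 <- cpp_geodesic(mv, d[1], d[2], d[3], seed - 1L)
  e0 <- which.max(d0)
  d1 <- cpp_geodesic(mv, d[1], d[2], d[3], e0 - 1L)
  idx <- which(mv)
  gd <- d1[idx]
  bins <- floor(gd / bin_voxels)
  p <- voxel_world(idx, d, vox_mm)
  cx <- rowsum(p, bins)
  cnt <- as.vector(rowsum(rep(1, length(bins)), bins))
  cent <- cx / cnt
  ord <- order(as.numeric(rownames(cx)))
  cent <- cent[ord, , drop = FALSE]
  list(centroids = cent, n_components = ncomp,
       length_mm = arc_length(cent[, 1], cent[, 2], cent[, 3]))
}

#' Centerline length of a binary structure
#'
#' Length of the structure's central path: geodesic distances are computed
#' over the 26-connected voxel graph with step weights 1, sqrt(2), sqrt(3)
#' times the voxel size, the two mutually farthest voxels define the
#' endpoints, and the centerline is the polyline through the centroids of
#' consecutive geodesic-distance bins. For disconnected masks the longest
#' component's length is reported and the component count attached.
#'
#' @param mask Logical 3D array.
#' @param voxel_size_um Voxel size in micrometres.
#' @param bin_voxels Geodesic bin width (voxels) for the centroid path.
#' @return Length in mm, with attribute `n_components`.
#' @export
centerline_length <- function(mask, voxel_size_um, bin_voxels = 3) {
  if (!any(mask)) stop("empty mask")
  vox <- voxel_size_um / 1000
  d <- dim(mask)
  comp <- array(cpp_components(as.vector(mask), d[1], d[2], d[3]), d)
  ncomp <- max(comp)
  lens <- vapply(seq_len(ncomp), function(k) {
    mask_centerline_points(mask, vox, bin_voxels, component = k)$length_mm
  }, numeric(1))
  structure(max(lens), n_components = ncomp)
}

# ---- local thickness --------------------------------------------------------

#' Sphere-fitting local thickness map
#'
#' Local thickness at a voxel is the diameter of the largest sphere that
#' fits entirely inside the structure and contains the voxel, with tested
#' sphere diameters quantized to multiples of `step_voxels` voxels (the
#' largest fitting tested sphere is kept). A sphere of diameter d (voxels)
#' centered at voxel w fits when every voxel center within Euclidean
#' distance d/2 + 1/2 of w belongs to the mask (the half voxel accounts for
#' the voxel footprint), and it contains voxel v when `||v - w|| <= d/2 +
#' 1/2`. Computed exactly via the Euclidean distance transform: per
#' candidate diameter (descending), the set of admissible centers is
#' dilated by its radius using a second distance transform.
#'
#' @param mask Logical 3D array (structure mask).
#' @param step_voxels Diameter quantization step in voxels (the scan
#'   protocol's "steps of 2 voxels" by default).
#' @param voxel_size_um Voxel size in micrometres.
#' @return A `thickness_map`: list with `data` (mm, 0 outside the mask),
#'   `voxel_size_um`, `step_voxels`.
#' @export
local_thickness <- function(mask, step_voxels = 2, voxel_size_um) {
  if (!any(mask)) stop("empty mask")
  if (step_voxels < 1) stop("step_voxels must be >= 1")
  e <- edt_to(!mask)           # distance to nearest background voxel center
  q <- (2 * e - 1) / step_voxels
  dvox <- step_voxels * floor(q - 1e-9)  # largest tested diameter that fits
  dvox[mask & dvox < 1] <- 1             # sub-step structures: one voxel
  dvox[!mask] <- 0
  th <- array(0, dim(mask))
  for (dd in sort(unique(dvox[mask]), decreasing = TRUE)) {
    centers <- dvox == dd
    reach <- edt_to(centers)
    hit <- mask & th == 0 & reach <= dd / 2 + 0.5 + 1e-9
    th[hit] <- dd
  }
  structure(list(data = th * voxel_size_um / 1000,
                 voxel_size_um = voxel_size_um,
                 step_voxels = step_voxels),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$data[x$data > 0]
  cat(sprintf(
    "<thickness_map> %d voxels @ %.3g um, step %d; range %.4g-%.4g mm\n",
    length(v), x$voxel_size_um, x$step_voxels, min(v), max(v)))
  invisible(x)
}

#' Modal thickness of a map
#'
#' Most frequent non-zero thickness value (mm).
#'
#' @param map A `thickness_map`.
#' @return Modal thickness in mm.
#' @export
modal_thickness <- function(map) {
  v <- map$data[map$data > 0]
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])
}

#' Thickness histogram
#'
#' Percentage of structure voxels per thickness range. Bins are
#' `[start + k*bin_width, start + (k+1)*bin_width)` and extend below `start`
#' if the map contains smaller values, so percentages always total 100.
#' Midpoints are exactly `(lo + hi) / 2`.
#'
#' @param map A `thickness_map` (or numeric vector of thicknesses in mm).
#' @param bin_width_mm Bin width; default 2 voxels at the map resolution.
#' @param start_mm First bin's lower edge.
#' @return A `thickness_histogram` tibble with columns `lo_mm`, `hi_mm`,
#'   `midpoint_mm`, `percent`.
#' @export
thickness_histogram <- function(map, bin_width_mm = NULL, start_mm = 0) {
  v <- if (inherits(map, "thickness_map")) map$data[map$data > 0] else
    map[map > 0]
  if (!length(v)) stop("empty thickness map")
  if (is.null(bin_width_mm)) {
    if (!inherits(map, "thickness_map"))
      stop("bin_width_mm required for plain numeric input")
    bin_width_mm <- map$step_voxels * map$voxel_size_um / 1000
  }
  if (bin_width_mm <= 0) stop("bin_width_mm must be > 0")
  k <- floor((v - start_mm) / bin_width_mm)
  ks <- seq(min(k), max(k))
  cnt <- tabulate(k - min(k) + 1L, length(ks))
  lo <- start_mm + ks * bin_width_mm
  hi <- lo + bin_width_mm
  out <- tibble::tibble(lo_mm = lo, hi_mm = hi,
                        midpoint_mm = (lo + hi) / 2,
                        percent = 100 * cnt / length(v))
  class(out) <- c("thickness_histogram", class(out))
  out
}
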