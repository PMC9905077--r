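#' Grey-value volume
#'
#' A `cect_volume` is a 3D numeric array of grey values (attenuation in 1/mm
#' for simulated data, or dimensionless grey levels after windowing) with an
#' isotropic voxel size in micrometres and bit-depth metadata.
#'
#' @param data 3D numeric array (x, y, z; x fastest).
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @param bit_depth Nominal bit depth of the stored values (8, 16 or 32).
#'   32 denotes floating-point attenuation data.
#' @return A `cect_volume` object.
#' @export
cect_volume <- function(data, voxel_size_um, bit_depth = 32) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  if (!bit_depth %in% c(8L, 16L, 32L))
    stop("unsupported bit depth: ", bit_depth)
  structure(
    list(data = data, voxel_size_um = voxel_size_um,
         bit_depth = as.integer(bit_depth)),
    class = "cect_volume")
}

#' @export
print.cect_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cect_volume> %d x %d x %d voxels @ %.3g um, %d-bit\n",
              d[1], d[2], d[3], x$voxel_size_um, x$bit_depth))
  cat(sprintf("  grey range: [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.cect_volume <- function(x) dim(x$data)

as_volume_array <- function(x) {
  if (inherits(x, "cect_volume")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a cect_volume or 3D array")
}

voxel_mm <- function(x) {
  if (inherits(x, "cect_volume") || inherits(x, "cect_labels"))
    x$voxel_size_um / 1000
  else stop("object carries no voxel size")
}

#' Labelled structure volume
#'
#' A `cect_labels` object assigns each voxel an integer code naming one
#' cochlear structure or material class. The code-to-name map and the
#' name-to-material-class map travel with the object.
#'
#' @param data 3D integer array of label codes (0 = background).
#' @param label_map Named integer vector mapping structure name to code.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param class_map Named character vector mapping structure name to material
#'   class (one of `"background"`, `"fluid"`, `"soft"`, `"bone"`,
#'   `"porous_bone"`, `"parafilm"`, `"metal"`).
#' @return A `cect_labels` object.
#' @export
cect_labels <- function(data, label_map, voxel_size_um,
                        class_map = default_class_map()) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.null(names(label_map))) stop("`label_map` must be named")
  structure(
    list(data = data, label_map = label_map, class_map = class_map,
         voxel_size_um = voxel_size_um),
    class = "cect_labels")
}

#' @export
print.cect_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cect_labels> %d x %d x %d voxels @ %.3g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  present <- sort(unique(as.integer(x$data)))
  nm <- names(x$label_map)[match(present, x$label_map)]
  cat("  labels present:", paste(nm, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cect_labels <- function(x) dim(x$data)

#' Voxel mask of one named structure
#'
#' @param labels A `cect_labels` object.
#' @param structure Structure name (must exist in the label map).
#' @param allow_empty Return an all-`FALSE` mask instead of erroring when the
#'   structure has no voxels.
#' @return Logical 3D array.
#' @export
structure_mask <- function(labels, structure, allow_empty = FALSE) {
  stopifnot(inherits(labels, "cect_labels"))
  if (!structure %in% names(labels$label_map))
    stop("unknown structure: ", structure)
  m <- labels$data == labels$label_map[[structure]]
  if (!allow_empty && !any(m))
    stop("structure '", structure, "' has no voxels")
  m
}

#' Voxel mask of one material class
#'
#' @param labels A `cect_labels` object.
#' @param class Material class name (e.g. `"fluid"`, `"soft"`).
#' @return Logical 3D array.
#' @export
class_mask <- function(labels, class) {
  stopifnot(inherits(labels, "cect_labels"))
  nm <- names(labels$class_map)[labels$class_map %in% class]
  codes <- labels$label_map[names(labels$label_map) %in% nm]
  array(labels$data %in% codes, dim(labels$data))
}

#' Canonical structure label table
#'
#' The label vocabulary used by the phantom generator: per-structure integer
#' code and material class. Fluid compartments (`st`, `sv`, `sm`) are the
#' scala tympani, vestibuli and media; membranes and laminae follow the usual
#' cochlear abbreviations (RWM, BM, RM, CPB-OoC, OSL, SL, SSL, RWA, RC).
#'
#' @return A tibble with columns `name`, `code`, `class`.
#' @export
cochlear_label_table <- function() {
  tibble::tibble(
    name = c("background", "st", "sv", "sm", "capsule", "modiolus", "rwm",
             "bm", "rm", "cpb_ooc", "osl", "sl", "ssl", "rwa", "rc",
             "ref_bone", "ref_parafilm", "electrode"),
    code = 0:17,
    class = c("background", "fluid", "fluid", "fluid", "bone", "bone",
              "soft", "soft", "soft", "soft", "bone", "soft", "porous_bone",
              "bone", "soft", "bone", "parafilm", "metal"))
}

default_label_map <- function() {
  tb <- cochlear_label_table()
  setNames(tb$code, tb$name)
}

default_class_map <- function() {
  tb <- cochlear_label_table()
  setNames(tb$class, tb$name)
}

#' Default material attenuation table
#'
#' Linear attenuation coefficients (1/mm) per material class used when
#' rendering phantom grey values. The ordering mirrors contrast-enhanced
#' microCT: stained soft tissue sits between fluid and bone, the porous
#' secondary spiral lamina below cortical bone, and electrode metal dominates
#' everything.
#'
#' @return Named numeric vector of attenuations by material class.
#' @export
default_attenuation <- function() {
  c(background = 0, fluid = 0.02, soft = 0.12, bone = 0.30,
    porous_bone = 0.18, parafilm = 0.05, metal = 3.0)
}
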