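# Electrode insertion into the scala tympani, with configurable trauma
# lesions and exact ground-truth bookkeeping.

lesion_types <- c("fracture", "tear", "deformation", "elevation",
                  "scala-vestibuli translocation")

#' Describe a trauma lesion for electrode insertion
#'
#' @param structure Name of the traumatized structure (label vocabulary).
#' @param type One of `"fracture"`, `"tear"`, `"deformation"`,
#'   `"elevation"`, `"scala-vestibuli translocation"`.
#' @param theta_range Angular range (degrees unwrapped) affected.
#' @param fraction Fraction of the structure's voxels inside `theta_range`
#'   that are affected (contiguous from the basal end of the range).
#' @return A `lesion_spec` list.
#' @export
lesion <- function(structure, type, theta_range, fraction = 1) {
  type <- match.arg(type, lesion_types)
  if (length(theta_range) != 2L || theta_range[1] >= theta_range[2])
    stop("theta_range must be (start, end) with start < end")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  structure(list(structure = structure, type = type,
                 theta_range = theta_range, fraction = fraction),
            class = "lesion_spec")
}

map_eshraghi_descriptor <- function(structure, type, displaced) {
  if (type == "scala-vestibuli translocation")
    return("electrode in scala vestibuli")
  switch(structure,
         bm = if (displaced) "BM elevation" else "BM rupture",
         osl = "OSL fracture",
         modiolus = "modiolus fracture",
         sl = "SL/stria tear",
         NA_character_)
}

#' Insert an electrode into a phantom
#'
#' Traces a tapered electrode tube along the scala tympani centerline from
#' the round window to `depth_deg` of unwrapped angle (the tube is clipped
#' at the `depth_deg` cross-section, so its most apical voxels sit at the
#' requested depth), overwriting only open scala tympani fluid. Lesions
#' remove or displace voxels from named structures and are recorded in an
#' exact ground-truth lesion table.
#'
#' @param phantom A `cect_phantom` (pre-insertion).
#' @param depth_deg Insertion depth in degrees of unwrapped angle.
#' @param lesions List of [lesion()] specifications.
#' @param electrode_radius_um Basal electrode radius; the tube tapers to at
#'   most 33% of the local duct radius.
#' @return A new `cect_phantom` (post-insertion) whose `lesions` element is
#'   the ground-truth lesion table and whose `insertion_depth_deg` is set.
#' @export
insert_electrode <- function(phantom, depth_deg, lesions = list(),
                             electrode_radius_um = 220) {
  stopifnot(inherits(phantom, "cect_phantom"))
  extent <- phantom$spec$turns * 360
  if (depth_deg <= 0 || depth_deg > extent)
    stop("depth must be in (0, ", extent, "] degrees")
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  lm <- phantom$labels$label_map
  g <- phantom$geom
  lab <- as.vector(phantom$labels$data)
  pre_lab <- lab
  nd <- g$dims

  r_e <- pmin(electrode_radius_um / 1000, 0.33 * g$R)
  elec <- g$psi >= 0 & g$psi <= depth_deg & lab == lm[["st"]] &
    sqrt(g$drad^2 + (g$dz + 0.55 * g$R)^2) <= r_e
  lab[elec] <- lm[["electrode"]]

  rows <- list()
  for (ls in lesions) {
    if (!inherits(ls, "lesion_spec")) stop("lesions must be lesion() specs")
    if (!ls$structure %in% names(lm))
      stop("unknown structure: ", ls$structure)
    if (ls$theta_range[2] > depth_deg)
      stop("lesion angular range beyond electrode depth")
    code <- lm[[ls$structure]]
    pre_n <- sum(pre_lab == code)
    if (pre_n == 0L) stop("structure '", ls$structure, "' has no voxels")
    sel <- which(lab == code & g$psi >= ls$theta_range[1] &
                   g$psi <= ls$theta_range[2])
    if (!length(sel)) stop("lesion range contains no '", ls$structure,
                           "' voxels")
    sel <- sel[order(g$psi[sel])]
    take <- sel[seq_len(round(ls$fraction * length(sel)))]
    displaced <- ls$type %in% c("deformation", "elevation")
    gained <- integer(0)
    lab[take] <- lm[["st"]]
    if (displaced) {
      # displace the affected voxels apex-ward into the first open fluid
      # position (2-6 voxels up)
      fluid_codes <- c(lm[["st"]], lm[["sm"]], lm[["sv"]])
      left <- take
      for (off in 2:6) {
        tgt <- left + off * nd[1] * nd[2]
        ok <- tgt <= length(lab) & lab[pmin(tgt, length(lab))] %in%
          fluid_codes
        lab[tgt[ok]] <- code
        gained <- c(gained, tgt[ok])
        left <- left[!ok]
        if (!length(left)) break
      }
    }
    if (ls$type == "scala-vestibuli translocation") {
      # the electrode transgresses: mark its voxels in this range as lying
      # in the scala vestibuli by rerouting them upward
      seg <- which(lab == lm[["electrode"]] & g$psi >= ls$theta_range[1] &
                     g$psi <= ls$theta_range[2])
      up <- which(lab == lm[["sv"]] & g$psi >= ls$theta_range[1] &
                    g$psi <= ls$theta_range[2] &
                    sqrt(g$drad^2 + (g$dz - 0.55 * g$R)^2) <= r_e)
      lab[seg] <- lm[["st"]]
      lab[up] <- lm[["electrode"]]
    }
    vox <- phantom$spec$voxel_size_um / 1000
    rows[[length(rows) + 1L]] <- tibble::tibble(
      structure = ls$structure, type = ls$type,
      descriptor = map_eshraghi_descriptor(ls$structure, ls$type, displaced),
      theta_start = min(g$psi[take]), theta_end = max(g$psi[take]),
      removed_voxels = length(take), gained_voxels = length(gained),
      removed_mm3 = length(take) * vox^3,
      percent_of_pre = 100 * length(take) / pre_n)
  }

  post <- phantom
  post$labels$data <- array(lab, nd)
  post$grey <- render_phantom_grey(post$labels, post$spec, uptake = NULL)
  post$lesions <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(structure = character(), type = character(),
                   descriptor = character(), theta_start = numeric(),
                   theta_end = numeric(), removed_voxels = integer(),
                   gained_voxels = integer(), removed_mm3 = numeric(),
                   percent_of_pre = numeric())
  post$insertion_depth_deg <- depth_deg
  post
}
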