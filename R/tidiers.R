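# broom-style tidiers for the package's composite objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phantom: its ground-truth measurement table
#'
#' @param x A `cect_phantom`.
#' @param ... Unused.
#' @return Tibble with `metric`, `value`.
#' @export
tidy.cect_phantom <- function(x, ...) x$truth

#' One-row phantom summary
#'
#' @param x A `cect_phantom`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.cect_phantom <- function(x, ...) {
  tibble::tibble(
    turns = x$spec$turns,
    voxel_size_um = x$spec$voxel_size_um,
    n_voxels = prod(dim(x$labels$data)),
    n_structures = length(unique(as.integer(x$labels$data))) - 1L,
    handedness = x$spec$handedness,
    electrode = !is.null(x$insertion_depth_deg))
}

#' Tidy a trauma report (drop attributes, keep the table)
#'
#' @param x A `trauma_report`.
#' @param ... Unused.
#' @return Plain tibble.
#' @export
tidy.trauma_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "trauma_report")
  attr(out, "insertion_depth_deg") <- NULL
  attr(out, "overall_grade") <- NULL
  attr(out, "sv_translocation") <- NULL
  out
}

#' One-row trauma summary
#'
#' @param x A `trauma_report`.
#' @param ... Unused.
#' @return One-row tibble with insertion depth, overall grade and the
#'   number of traumatized structures.
#' @export
glance.trauma_report <- function(x, ...) {
  tibble::tibble(
    insertion_depth_deg = attr(x, "insertion_depth_deg"),
    overall_grade = attr(x, "overall_grade"),
    n_structures_traumatized = sum(x$traumatized_mm3 > 0))
}
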