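# Volume I/O: TIFF slice stacks (multi-page or numbered single-page files)
# with a JSON sidecar for voxel size and bit depth; frame serialization.

sidecar_path <- function(path) {
  if (dir.exists(path) || !grepl("\\.tiff?$", path, ignore.case = TRUE))
    file.path(path, "stack.json")
  else paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".json")
}

#' Save a volume as a TIFF stack
#'
#' Writes a [cect_volume()] either as one multi-page TIFF or as numbered
#' single-page slices in a directory, plus a JSON sidecar carrying voxel
#' size and bit depth. 8- and 16-bit volumes are stored as integers
#' (lossless round trip); 32-bit volumes as float samples.
#'
#' @param volume A [cect_volume()].
#' @param path Output file (`.tif`) for multi-page, or directory for
#'   numbered slices.
#' @param layout `"multipage"` or `"slices"`.
#' @return `path`, invisibly.
#' @export
save_stack <- function(volume, path, layout = c("multipage", "slices")) {
  stopifnot(inherits(volume, "cect_volume"))
  layout <- match.arg(layout)
  arr <- volume$data
  bd <- volume$bit_depth
  scale <- switch(as.character(bd), "8" = 255, "16" = 65535, "32" = 1)
  if (bd %in% c(8L, 16L)) {
    if (any(arr < 0 | arr > scale))
      stop("values out of range for ", bd, "-bit storage")
    arr <- round(arr)
  } else {
    # float samples must sit in [0,1] for the TIFF writer; keep the scale
    # in the sidecar
    scale <- max(abs(arr), 1)
    if (min(arr) < 0) stop("negative values not supported in float stacks")
  }
  slices <- lapply(seq_len(dim(arr)[3]),
                   function(z) t(arr[, , z]) / scale)
  if (layout == "multipage") {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(slices, path, bits.per.sample = bd,
                    reduce = FALSE)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (z in seq_along(slices))
      tiff::writeTIFF(slices[[z]],
                      file.path(path, sprintf("slice_%04d.tif", z)),
                      bits.per.sample = bd, reduce = FALSE)
  }
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size_um, bit_depth = bd,
         dim = dim(volume$data), layout = layout,
         scale = if (bd == 32L) scale else NULL),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a TIFF stack
#'
#' Reads a multi-page TIFF or a directory of numbered single-page slices
#' (written by [save_stack()] or any tool honoring the same layout).
#' Slices must agree in shape and bit depth.
#'
#' @param path TIFF file or directory of slices.
#' @return A [cect_volume()].
#' @export
load_stack <- function(path) {
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, info = TRUE))
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("inconsistent slice shapes: ", paste(unique(shapes), collapse = ", "))
  bits <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1))
  if (length(unique(bits)) != 1L)
    stop("mixed bit depths in one stack: ",
         paste(unique(bits), collapse = ", "))
  bd <- bits[1]
  if (!bd %in% c(8L, 16L, 32L)) stop("unsupported bit depth: ", bd)
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) # undo row-major
  if (bd %in% c(8L, 16L)) {
    arr <- round(arr * if (bd == 8L) 255 else 65535)
  } else if (!is.null(meta$scale)) {
    arr <- arr * meta$scale
  }
  vox <- if (!is.null(meta)) meta$voxel_size_um else 1
  cect_volume(arr, vox, bd)
}

#' Serialize a cochlear frame to JSON
#'
#' @param frame A `cochlear_frame`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  stopifnot(inherits(frame, "cochlear_frame"))
  jsonlite::write_json(
    list(axis_point = frame$axis_point, axis_dir = frame$axis_dir,
         zero_dir = frame$zero_dir, handedness = frame$handedness,
         centerline = as.list(frame$centerline)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cochlear frame from JSON
#'
#' @param path JSON path written by [write_frame_json()].
#' @return A `cochlear_frame`.
#' @export
read_frame_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_cochlear_frame(j$axis_point, j$axis_dir, j$zero_dir, j$handedness,
                     tibble::as_tibble(j$centerline))
}
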