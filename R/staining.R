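# Contrast staining time-course: a logistic angular front advancing from the
# round window toward the apex at a fixed number of turns per day.

#' Per-voxel contrast uptake under the staining front model
#'
#' Uptake at unwrapped angle theta after `time_h` hours of submersion is
#' `max(0, 2*(plogis((front - theta)/front_width) - 0.5))` with
#' `front = rate * time_h/24 * 360` degrees, i.e. 0 everywhere at time 0,
#' monotonically non-decreasing in time, and non-increasing in angular
#' distance from the round window. The round window membrane is treated as
#' fully stained once `time_h >= 3` (it faces the staining bath directly).
#'
#' @param phantom A `cect_phantom`.
#' @param time_h Hours since submersion (>= 0).
#' @param rate Front speed in turns per day (> 0).
#' @param front_width_deg Softness of the front transition.
#' @return Numeric array of uptake in `[0, 1]` (defined for all voxels;
#'   meaningful for soft tissue).
#' @export
stain_uptake <- function(phantom, time_h, rate = 1, front_width_deg = 30) {
  stopifnot(inherits(phantom, "cect_phantom"))
  if (time_h < 0) stop("time must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  front <- rate * (time_h / 24) * 360
  # the basal vestibule (theta < 0) sits at the round window: angular
  # distance from the contrast entry is 0 there
  theta <- pmax(phantom$theta, 0)
  u <- pmax(0, 2 * (stats::plogis((front - theta) / front_width_deg) - 0.5))
  if (time_h >= 3) {
    rwm <- structure_mask(phantom$labels, "rwm", allow_empty = TRUE)
    u[rwm] <- 1
  }
  array(u, dim(phantom$labels$data))
}

#' Simulate a partially stained grey volume
#'
#' Renders the phantom's grey values with soft-tissue attenuation
#' interpolated between fluid level (unstained) and the fully stained
#' soft-tissue attenuation according to [stain_uptake()]. Bone, fluid and
#' reference materials are unaffected.
#'
#' @inheritParams stain_uptake
#' @return A [cect_volume()] of attenuations (1/mm).
#' @export
simulate_staining <- function(phantom, time_h, rate = 1,
                              front_width_deg = 30) {
  u <- stain_uptake(phantom, time_h, rate, front_width_deg)
  render_phantom_grey(phantom$labels, phantom$spec, uptake = as.vector(u))
}

#' First whole day of complete soft-tissue staining
#'
#' Evaluates the staining front at the end of each whole day of submersion
#' and reports the first day at which every soft-tissue voxel's uptake
#' exceeds `threshold`.
#'
#' @inheritParams stain_uptake
#' @param threshold Uptake level above which a voxel counts as stained.
#' @param max_days Give up (with `NA`) after this many days.
#' @return First day (integer) of full staining.
#' @export
staining_completion_day <- function(phantom, rate = 1, front_width_deg = 30,
                                    threshold = 0.5, max_days = 14) {
  soft <- class_mask(phantom$labels, "soft")
  for (day in seq_len(max_days)) {
    u <- stain_uptake(phantom, day * 24, rate, front_width_deg)
    if (all(u[soft] > threshold)) return(day)
  }
  NA_integer_
}
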