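#' RSVP timing configuration
#'
#' Bundles the presentation timing of one RSVP stream: each image is shown
#' for `image_duration_ms` and followed by a blank of `blank_duration_ms`,
#' giving a constant stimulus-onset asynchrony (SOA) of
#' `1000 / presentation_rate_hz` milliseconds.  The inter-sequence gaps are
#' drawn uniformly from `gap_min_images:gap_max_images` distractor images,
#' one gap preceding every repetition sequence; a fixed tail of
#' `tail_images` distractors closes the stream.
#'
#' Event onsets are computed as `index * soa_ms` with `soa_ms` stored at
#' full floating-point precision, so no rounding drift accumulates over a
#' stream; the duration fields keep the conventional screen-refresh values
#' (58.3 and 8.3 ms at a 120 Hz refresh).
#'
#' @param image_duration_ms Image presentation time in milliseconds.
#' @param blank_duration_ms Blank interval after each image, milliseconds.
#' @param presentation_rate_hz Image presentation rate in Hz.
#' @param gap_min_images,gap_max_images Bounds (inclusive, in images) of the
#'   uniform inter-sequence gap.
#' @param tail_images Number of distractors appended after the final
#'   repetition sequence.
#'
#' @return An object of class `"timing_config"`.
#' @examples
#' timing_config()
#' @export
timing_config <- function(image_duration_ms = 58.3,
                          blank_duration_ms = 8.3,
                          presentation_rate_hz = 15,
                          gap_min_images = 37L,
                          gap_max_images = 52L,
                          tail_images = 22L) {
  if (image_duration_ms <= 0 || blank_duration_ms <= 0) {
    stopf("image and blank durations must be positive")
  }
  if (presentation_rate_hz <= 0) stopf("presentation rate must be positive")
  soa <- 1000 / presentation_rate_hz
  if (abs(image_duration_ms + blank_duration_ms - soa) > 0.1) {
    stopf("image + blank duration (%.4f ms) must equal 1000/rate (%.4f ms) within 0.1 ms",
          image_duration_ms + blank_duration_ms, soa)
  }
  if (!is_count(gap_min_images) || !is_count(gap_max_images) ||
      gap_min_images <= 0 || gap_max_images < gap_min_images) {
    stopf("gap bounds must be positive integers with gap_min <= gap_max")
  }
  if (!is_count(tail_images) || tail_images < 0) {
    stopf("tail_images must be a non-negative integer")
  }
  structure(
    list(
      image_duration_ms = image_duration_ms,
      blank_duration_ms = blank_duration_ms,
      presentation_rate_hz = presentation_rate_hz,
      soa_ms = soa,
      gap_min_images = as.integer(gap_min_images),
      gap_max_images = as.integer(gap_max_images),
      tail_images = as.integer(tail_images)
    ),
    class = "timing_config"
  )
}

#' @export
print.timing_config <- function(x, ...) {
  cat(sprintf("RSVP timing: %.1f ms image + %.1f ms blank (%.4g Hz, SOA %.4f ms)\n",
              x$image_duration_ms, x$blank_duration_ms,
              x$presentation_rate_hz, x$soa_ms))
  cat(sprintf("inter-sequence gaps: %d-%d images; tail: %d images\n",
              x$gap_min_images, x$gap_max_images, x$tail_images))
  invisible(x)
}
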