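#' Construct an audio clip
#'
#' The basic container passed between every stage of the pipeline: a mono
#' sample vector in `[-1, 1]` together with its sampling rate.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (the pipeline operates at 16000).
#' @param source_path Optional provenance path.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate = 16000L, source_path = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples))) {
    stop("audio_clip: samples must be finite")
  }
  structure(
    list(samples = samples,
         sample_rate = as.integer(sample_rate),
         source_path = source_path),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %d samples @ %d Hz (%.3f s), peak %.4f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

#' Clip duration in seconds
#' @param clip An [audio_clip()].
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

stopifnot_clip <- function(clip) {
  if (!inherits(clip, "audio_clip")) stop("expected an 'audio_clip' object")
  invisible(clip)
}
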