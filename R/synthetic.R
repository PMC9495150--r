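## Synthetic bird-call corpus generator.
##
## Each species is a harmonic chirp "voice": syllables are linear-chirp
## harmonic stacks (fundamental confined to a species-specific band) under a
## Hann amplitude envelope, separated by species-typical silent gaps, over
## optional white Gaussian background noise.  This captures exactly the
## structure the preprocessing chain assumes — tonal events of 50-500 ms,
## silences, variable clip lengths — without attempting realistic birdsong.

#' Define acoustically separated synthetic species
#'
#' Draws `n_species` species "voices" whose fundamental-frequency bands are
#' mutually separated by at least 200 Hz (center to center) so the resulting
#' classification task is well-posed: a clip's dominant spectral band
#' identifies its species.  Harmonic counts are capped so every partial stays
#' below the 8 kHz Nyquist limit of 16 kHz audio.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of `species_spec` objects with fields `species_id`,
#'   `f0_range`, `n_harmonics`, `syllable_dur_range`,
#'   `inter_syllable_gap_range`, `chirp_slope`, `amplitude_jitter`.
#' @export
make_species_specs <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("make_species_specs: n_species must be >= 2")
  half_width <- 80                       # half-width of each f0 band, Hz
  lo_center <- 400; hi_center <- 3600    # keeps 2nd harmonic under 7.9 kHz
  max_fit <- floor((hi_center - lo_center) / 200) + 1
  if (n_species > max_fit) {
    stop(sprintf(paste0("make_species_specs: cannot place %d non-overlapping ",
                        "f0 bands with 200 Hz separation below Nyquist ",
                        "(max %d)"), n_species, max_fit))
  }
  centers <- seq(lo_center, hi_center, length.out = n_species)
  with_seed(seed, {
    lapply(seq_len(n_species), function(i) {
      f0_low <- centers[i] - half_width
      f0_high <- centers[i] + half_width
      n_h <- min(3L, max(1L, floor(7900 / f0_high)))
      dur_lo <- stats::runif(1, 0.06, 0.15)
      dur_hi <- stats::runif(1, 0.2, 0.45)
      gap_lo <- stats::runif(1, 0.1, 0.3)
      gap_hi <- gap_lo + stats::runif(1, 0.1, 0.4)
      structure(list(
        species_id = sprintf("species_%02d", i),
        f0_range = c(f0_low, f0_high),
        n_harmonics = n_h,
        syllable_dur_range = c(dur_lo, dur_hi),
        inter_syllable_gap_range = c(gap_lo, gap_hi),
        chirp_slope = stats::runif(1, -1, 1) * 150,   # Hz/s sweep
        amplitude_jitter = 0.2
      ), class = "species_spec")
    })
  })
}

#' Synthesize one bird-call clip
#'
#' Fills `duration_s` seconds with syllables drawn from the species voice:
#' each syllable is a linear chirp whose fundamental stays inside
#' `spec$f0_range`, with `spec$n_harmonics` partials of amplitude `1/h`, a
#' Hann envelope, and per-syllable amplitude jitter.  White Gaussian noise is
#' added at `noise_db` decibels relative to the syllable peak
#' (`-Inf` = noise-free).  The clip is peak-scaled to 0.9 to leave headroom
#' for 16-bit quantization.
#'
#' @param spec A `species_spec` from [make_species_specs()].
#' @param duration_s Clip length in seconds (> 0.05).
#' @param noise_db Noise level, dB relative to syllable peak; `-Inf` for none.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An [audio_clip()] with attribute `syllables`, a data frame of
#'   ground-truth `start_s`/`end_s` syllable boundaries.
#' @export
synthesize_call <- function(spec, duration_s = 10, noise_db = -30, seed = 1L) {
  if (duration_s <= 0.05) stop("synthesize_call: duration_s must exceed 0.05 s")
  sr <- 16000L
  n <- round(duration_s * sr)
  with_seed(seed, {
    x <- numeric(n)
    onsets <- numeric(0); offsets <- numeric(0)
    # lead-in gap, then alternate syllable / gap until the clip is full
    t_cur <- stats::runif(1, 0.05, spec$inter_syllable_gap_range[2])
    f0r <- spec$f0_range
    repeat {
      dur <- stats::runif(1, spec$syllable_dur_range[1], spec$syllable_dur_range[2])
      if (t_cur + dur > duration_s - 0.01) break
      sweep <- spec$chirp_slope * dur
      f_start <- if (sweep >= 0) {
        stats::runif(1, f0r[1], max(f0r[1], f0r[2] - sweep))
      } else {
        stats::runif(1, min(f0r[2], f0r[1] - sweep), f0r[2])
      }
      m <- round(dur * sr)
      tt <- (seq_len(m) - 1) / sr
      phase <- 2 * pi * (f_start * tt + 0.5 * spec$chirp_slope * tt^2)
      syl <- numeric(m)
      for (h in seq_len(spec$n_harmonics)) syl <- syl + sin(h * phase) / h
      env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))   # Hann
      amp <- 1 - stats::runif(1, 0, spec$amplitude_jitter)
      syl <- amp * env * syl / max(abs(syl))
      i0 <- round(t_cur * sr) + 1
      x[i0:(i0 + m - 1)] <- x[i0:(i0 + m - 1)] + syl
      onsets <- c(onsets, t_cur); offsets <- c(offsets, t_cur + dur)
      t_cur <- t_cur + dur +
        stats::runif(1, spec$inter_syllable_gap_range[1],
                     spec$inter_syllable_gap_range[2])
    }
    peak <- max(abs(x))
    if (peak == 0) {  # clip too short for any syllable: emit one tiny tone
      m <- round(0.05 * sr)
      tt <- (seq_len(m) - 1) / sr
      x[seq_len(m)] <- sin(2 * pi * mean(f0r) * tt)
      onsets <- 0; offsets <- 0.05
      peak <- 1
    }
    if (is.finite(noise_db)) {
      x <- x + stats::rnorm(n, sd = peak * 10^(noise_db / 20))
    }
    x <- 0.9 * x / max(abs(x))
    clip <- audio_clip(x, sr)
    attr(clip, "syllables") <- data.frame(start_s = onsets, end_s = offsets)
    attr(clip, "species_id") <- spec$species_id
    clip
  })
}

#' Build a labelled synthetic corpus on disk
#'
#' Writes `clips_per_species` WAV clips (16-bit mono, 16 kHz) for each
#' species, with clip durations drawn uniformly from `duration_range_s`
#' (default 6-14 s so the 10 s standardizer must both pad and crop), and
#' returns the manifest.  The manifest is also written as
#' `manifest.csv` (`wav_path,species_id,duration_s`) in `out_dir`, together
#' with a flat key-value `generator.cfg` recording the generation settings.
#'
#' @param specs List of `species_spec` from [make_species_specs()].
#' @param clips_per_species Clips per species (>= 2, so stratified 4:1
#'   splitting stays possible).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; corpus is bit-reproducible given the seed.
#' @param noise_db Background noise level in dB relative to syllable peak.
#' @param duration_range_s Min/max clip duration in seconds.
#' @return A `dataset_manifest`: list with `records` (data frame),
#'   `seed`, `n_species`.
#' @export
build_dataset <- function(specs, clips_per_species, out_dir, seed = 1L,
                          noise_db = -30, duration_range_s = c(6, 14)) {
  if (clips_per_species < 2) stop("build_dataset: clips_per_species must be >= 2")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("build_dataset: cannot create out_dir: ", out_dir)
  rows <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    for (j in seq_len(clips_per_species)) {
      sj <- derive_seed(seed, i, j)
      dur <- with_seed(derive_seed(sj, 1),
                       stats::runif(1, duration_range_s[1], duration_range_s[2]))
      clip <- synthesize_call(spec, dur, noise_db, seed = sj)
      fn <- file.path(out_dir, sprintf("%s_%03d.wav", spec$species_id, j))
      write_wav(clip, fn)
      rows[[length(rows) + 1]] <- data.frame(
        wav_path = fn, species_id = spec$species_id,
        duration_s = clip_duration(clip), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  utils::write.csv(records, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  cfg <- c(seed = seed, n_species = length(specs),
           clips_per_species = clips_per_species, noise_db = noise_db,
           duration_min_s = duration_range_s[1],
           duration_max_s = duration_range_s[2])
  writeLines(paste(names(cfg), unname(cfg), sep = " = "),
             file.path(out_dir, "generator.cfg"))
  structure(list(records = records, seed = as.integer(seed),
                 n_species = length(specs)),
            class = "dataset_manifest")
}

#' Read a corpus manifest CSV
#' @param path Path to a `manifest.csv` with columns
#'   `wav_path,species_id,duration_s`.
#' @return A `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wav_path", "species_id", "duration_s")
  if (!all(need %in% names(records))) {
    stop("read_manifest: manifest must have columns ", paste(need, collapse = ","))
  }
  structure(list(records = records, seed = NA_integer_,
                 n_species = length(unique(records$species_id))),
            class = "dataset_manifest")
}
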