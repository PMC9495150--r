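sine_clip <- function(freq, dur = 2, sr = 16000, amp = 1) {
  audio_clip(amp * sin(2 * pi * freq * (0:(dur * sr - 1)) / sr), sr)
}

gain_db <- function(out, input) {
  20 * log10(sqrt(mean(out^2)) / sqrt(mean(input^2)))
}

test_that("high-pass removes the 0-150 Hz band and passes the rest", {
  dc <- audio_clip(rep(0.5, 32000), 16000)
  expect_lte(sqrt(mean(high_pass(dc)$samples^2)),
             1e-3 * sqrt(mean(dc$samples^2)))

  s1k <- sine_clip(1000)
  expect_lt(abs(gain_db(high_pass(s1k)$samples, s1k$samples)), 1)

  s100 <- sine_clip(100)
  expect_lte(gain_db(high_pass(s100)$samples, s100$samples), -40)

  expect_equal(length(high_pass(s1k)$samples), length(s1k$samples))
  expect_error(high_pass(s1k, cutoff_hz = 9000), "cutoff")
})

test_that("noise gate zeroes quiet frames and leaves loud ones untouched", {
  sr <- 16000
  x <- numeric(2 * sr)
  burst <- 0.9 * sin(2 * pi * 2000 * (0:(0.2 * sr - 1)) / sr)
  x[sr:(sr + length(burst) - 1)] <- burst
  gated <- noise_gate(audio_clip(x, sr), -40)
  expect_true(all(gated$samples[1:(0.9 * sr)] == 0))
  expect_identical(gated$samples[sr:(sr + length(burst) - 1)], burst)

  # an impossibly low gate changes nothing
  noisy <- audio_clip(withr::with_seed(1, stats::rnorm(sr, sd = 0.1)), sr)
  expect_identical(noise_gate(noisy, -200)$samples, noisy$samples)

  # gating reduces the noise floor when the floor sits below the gate
  spec <- make_species_specs(3, seed = 2)[[1]]
  clip <- synthesize_call(spec, 4, noise_db = -40, seed = 6)
  gated2 <- noise_gate(clip, -30)
  syl <- attr(clip, "syllables")
  # a known noise-only span: from the last syllable end to the clip end
  i0 <- ceiling((max(syl$end_s) + 0.05) * sr); i1 <- length(clip$samples)
  expect_lt(sqrt(mean(gated2$samples[i0:i1]^2)),
            sqrt(mean(clip$samples[i0:i1]^2)))

  expect_error(noise_gate(clip, 3), "negative")
  silent <- audio_clip(numeric(1000), sr)
  expect_identical(noise_gate(silent)$samples, silent$samples)
})

test_that("syllable detection finds events with frame-level boundaries", {
  sr <- 16000
  expect_equal(nrow(detect_syllables(audio_clip(numeric(sr), sr))), 0)

  # one 200 ms syllable at 1.0 s
  x <- numeric(3 * sr)
  m <- 0.2 * sr
  env <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  x[(sr + 1):(sr + m)] <- env * sin(2 * pi * 1500 * (0:(m - 1)) / sr)
  seg <- detect_syllables(audio_clip(x, sr))
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$start_s - 1.0), 0.03)
  expect_lt(abs(seg$end_s - 1.2), 0.03)

  # two syllables separated by 1 s of silence
  x2 <- numeric(4 * sr)
  x2[(sr + 1):(sr + m)] <- x[(sr + 1):(sr + m)]
  x2[(2.2 * sr + 1):(2.2 * sr + m)] <- x[(sr + 1):(sr + m)]
  expect_equal(nrow(detect_syllables(audio_clip(x2, sr))), 2)
})

test_that("the 50-500 ms validity rule is enforced", {
  none <- data.frame(start_s = numeric(0), end_s = numeric(0))
  expect_false(is_valid_clip(none))
  expect_true(is_valid_clip(data.frame(start_s = 1, end_s = 1.2)))
  expect_false(is_valid_clip(data.frame(start_s = 0, end_s = 2)))
  # a long segment plus one conforming syllable is valid
  expect_true(is_valid_clip(data.frame(start_s = c(0, 3),
                                       end_s = c(2, 3.1))))
})

test_that("silence trimming keeps rhythm but drops long silence", {
  sr <- 16000
  # a clip that is one continuous syllable passes through unchanged
  tone <- sine_clip(1200, dur = 0.4)
  seg_all <- data.frame(start_s = 0, end_s = 0.4)
  expect_identical(trim_silence(tone, seg_all)$samples, tone$samples)

  # 10 s clip with syllables only in the first 2 s -> at most 3 s remain
  x <- numeric(10 * sr)
  m <- 0.3 * sr
  x[1:m] <- sin(2 * pi * 1000 * (0:(m - 1)) / sr)
  x[(1.5 * sr + 1):(1.5 * sr + m)] <- x[1:m]
  segs <- data.frame(start_s = c(0, 1.5), end_s = c(0.3, 1.8))
  trimmed <- trim_silence(audio_clip(x, sr), segs)
  expect_lte(clip_duration(trimmed), 3)

  # short gaps (0.3 s) are preserved verbatim
  x3 <- numeric(2 * sr)
  x3[1:m] <- sin(2 * pi * 900 * (0:(m - 1)) / sr)
  x3[(0.6 * sr + 1):(0.6 * sr + m)] <- x3[1:m]
  seg3 <- data.frame(start_s = c(0, 0.6), end_s = c(0.3, 0.9))
  t3 <- trim_silence(audio_clip(x3, sr), seg3)
  expect_equal(clip_duration(t3), 0.9, tolerance = 1e-6)

  expect_error(trim_silence(tone, none <- data.frame(start_s = numeric(0),
                                                     end_s = numeric(0))),
               "segments")
})

test_that("standardization yields exactly 10 s at 0 dBFS peak", {
  half <- sine_clip(700, dur = 5, amp = 0.3)
  std <- standardize(half)
  expect_length(std$samples, 160000)
  expect_equal(max(abs(std$samples)), 1.0)
  # tiling: the two 5 s halves are identical
  expect_identical(std$samples[1:80000], std$samples[80001:160000])

  long <- sine_clip(700, dur = 14, amp = 0.2)
  stdl <- standardize(long)
  expect_length(stdl$samples, 160000)
  expect_equal(max(abs(stdl$samples)), 1.0)

  expect_error(standardize(audio_clip(numeric(1000), 16000)), "silence")
})

test_that("the full chain accepts valid clips and rejects degenerate ones", {
  cp <- shared_corpus()
  res <- preprocess_clip(cp$manifest$records$wav_path[1], gate_db = -20)
  expect_true(res$accepted)
  expect_length(res$clip$samples, 160000)
  expect_equal(max(abs(res$clip$samples)), 1.0)

  # residual sub-100 Hz energy is >= 40 dB below total energy
  mag2 <- Mod(stats::fft(res$clip$samples))^2
  hz <- (seq_along(mag2) - 1) * 16000 / length(mag2)
  low <- sum(mag2[hz <= 100 | hz >= 15900])
  expect_lte(10 * log10(low / sum(mag2)), -40)

  # pure noise: no syllable structure -> rejected
  noise <- audio_clip(withr::with_seed(2, stats::rnorm(80000, sd = 0.3)),
                      16000)
  resn <- preprocess_clip(noise)
  expect_false(resn$accepted)
  expect_equal(resn$reason, "no_valid_syllable")

  # pure mains hum is annihilated by the high-pass
  hum <- sine_clip(60, dur = 5, amp = 0.8)
  resh <- preprocess_clip(hum)
  expect_false(resh$accepted)
})

test_that("preprocessing is idempotent up to gate-frame rounding", {
  cp <- shared_corpus()
  res1 <- preprocess_clip(cp$manifest$records$wav_path[2], gate_db = -20)
  res2 <- preprocess_clip(res1$clip, gate_db = -20)
  expect_true(res2$accepted)
  expect_length(res2$clip$samples, 160000)
  expect_equal(max(abs(res2$clip$samples)), 1.0)
  # the second pass must not meaningfully alter the signal; boundary
  # re-rounding onto the 12.5 ms gate-frame grid shifts the re-tiled copy
  # by a few hundred samples, so agreement is high but not exact
  expect_gt(stats::cor(res1$clip$samples, res2$clip$samples), 0.95)
})

test_that("manifest-level preprocessing writes accepted clips and rejections", {
  cp <- shared_corpus()
  out <- cp$pp
  expect_true(all(file.exists(out$records$wav_path)))
  expect_true(file.exists(file.path(dirname(out$records$wav_path[1]),
                                    "rejections.csv")))
  expect_equal(unique(out$records$duration_s), 10)
})
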