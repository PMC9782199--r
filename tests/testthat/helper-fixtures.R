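# Shared fixture builders. Everything is generated in code: no stored data.

# n beats at a fixed rate (default 60 bpm starting at 0.5 s)
make_schedule <- function(n = 10, period = 1, start = 0.5)
  beat_schedule(start + (seq_len(n) - 1) * period)

# the standard 72-sensor test grid
make_grid72 <- function() generate_sensor_layout(8, 9, 40, c(120, 120))

# single source roughly over the cardiac area of the grid
make_source <- function(layout, ...) {
  co <- layout$coords
  source_spec(c(min(co[, 1]) + 0.6 * diff(range(co[, 1])),
                min(co[, 2]) + 0.45 * diff(range(co[, 2]))), ...)
}

# empirical SNR of a noisy signal against its known clean version, in dB
snr_vs_clean <- function(noisy, clean)
  10 * log10(mean(clean^2) / mean((noisy - clean)^2))

# add white noise at a target SNR (dB) relative to the clean signal
add_noise_at_snr <- function(clean, snr_target_db, seed) {
  p_noise <- mean(clean^2) / 10^(snr_target_db / 10)
  set.seed(seed)
  clean + stats::rnorm(length(clean), sd = sqrt(p_noise))
}
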