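# shared fixtures: all built in code, no stored data

bands <- hippocampal_bands()

# theta- and slow-gamma phase series from one white-noise session,
# edge-trimmed; the workhorse fixture for chance-level tests
wn_phases <- function(duration_s, seed, fs = 1000,
                      theta = bands$theta, gamma = bands$gamma_slow) {
  x <- gen_white_noise(duration_s + 1, fs, seed = seed)
  list(theta = trim_edges(band_phase(x, theta)),
       gamma = trim_edges(band_phase(x, gamma)))
}

# R_1:5 values over consecutive disjoint epochs of a phase-series pair
epoch_rnm <- function(pt, pg, epoch_len_s, n_epochs, n = 1, m = 5) {
  vapply(seq_len(n_epochs) - 1, function(k) {
    rnm(phase_difference(epoch_window(pt, k * epoch_len_s, epoch_len_s),
                         epoch_window(pg, k * epoch_len_s, epoch_len_s),
                         n = n, m = m))
  }, numeric(1))
}

# dominant frequencies of a signal by raw periodogram
top_spectral_peaks <- function(x, k = 1) {
  sp <- spec.pgram(stats::ts(x$value, frequency = signal_fs(x)),
                   plot = FALSE, taper = 0, detrend = TRUE)
  sp$freq[order(sp$spec, decreasing = TRUE)[seq_len(k)]]
}

# cycle lengths of a sawtooth from its falling edges, in samples
sawtooth_cycle_lengths <- function(x, drop_thresh = 0.4) {
  edges <- which(diff(x$value) < -drop_thresh)
  diff(edges)
}
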