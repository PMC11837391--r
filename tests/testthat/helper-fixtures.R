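# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small mixed cohort (3 + 3, 40 s, 12 channels), prepared for modelling
small_cohort <- function() cached("small_cohort", function() {
  co <- gen_cohort(3, seed = 42, duration_s = 40, n_channels = 12)
  list(raw = co, prep = prepare_subjects(co))
})

# one noise-free-ish subject for high-precision checks
clean_subject <- function() cached("clean_subject", function() {
  p <- preset_td(phase_kappa = 1e9, peak_jitter_ms = 0, snr_jitter_db = 0,
                 snr_db = 30)
  s <- gen_subject(p, duration_s = 40, n_channels = 12, seed = 5,
                   streams = "eeg_only")
  list(subj = s, prep = prepare_subjects(list(s))[[1]])
})

# quick EEG recording constructor for preprocessing tests
toy_eeg <- function(data, rate_hz = 1000, montage = NULL) {
  if (is.null(montage)) montage <- make_montage(nrow(data))
  structure(list(data = data, rate_hz = rate_hz,
                 positions = montage$positions,
                 adjacency = montage$adjacency, labels = montage$labels,
                 bad_channels = integer(0), interpolated = integer(0),
                 artifact_mask = rep(TRUE, ncol(data))),
            class = "eeg_recording")
}
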