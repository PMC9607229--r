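# Shared fixtures, generated in code. Short protocols and reduced sampling
# rates keep unit tests fast; the full-length protocol is exercised in the
# acceptance tests.

short_protocol <- function(speeds = c(0.22, 0.44))
  protocol_spec(stand_duration = 60, walk_duration = 120, recover_duration = 60,
                speeds = speeds)

# processing settings matched to the reduced 25 Hz / 250 Hz rates
short_proc_config <- function()
  proc_config(emg_band = c(20, 110), ss_window = 45)

.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 4 subjects x 2 speeds x 2 conditions, short protocol, reduced rates
small_raw_trials <- function() cached_fixture("raw4", {
  co <- make_cohort(4, seed = 101)
  simulate_cohort_trials(co, short_protocol(), seed = 101,
                         imu_rate = 25, emg_rate = 250)
})

small_processed_trials <- function() cached_fixture("proc4", {
  lapply(small_raw_trials(), process_trial, config = short_proc_config())
})

# one zero-noise trial at reduced rates, full-length protocol
zero_noise_trial <- function() cached_fixture("zn", {
  co <- make_cohort(2, seed = 55)
  simulate_trial(co[1, ], 0.33, FALSE, protocol_spec(),
                 noise_cv = 0, outlier_rate = 0,
                 imu_rate = 25, emg_rate = 250, seed = 56)
})
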