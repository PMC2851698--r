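# fixtures are simulated once per test run and shared across files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- expr
  .fixture_cache[[name]]
}

# quiet rest, no phasic events: the resting-model source
rest_recording <- function() cached("rest", {
  simulate_recording(scenario_config(block = "A", spontaneous_rate_per_min = 0,
                                     seed = 101L))
})

rest_cardio <- function() cached("rest_cardio", cardio_series(rest_recording()))

rest_curves <- function() cached("rest_curves", corr_curves(rest_cardio()))

# resting model at a reduced bootstrap size for unit tests
rest_model <- function() cached("rest_model", {
  fit_resting_model(rest_curves(), n_boot = 300, seed = 42L)
})

calibration_rec <- function() cached("cal", make_calibration_recording(seed = 1L))

fixture_suite <- function() cached("suite", make_fixture_suite(seed = 1L))

# noiseless physiology for deterministic detector tests
quiet_params <- function() {
  physio_params(noise_sd = c(eda = 0, resp = 0, bvp = 0))
}

curves_matrix <- edrclass:::curves_matrix
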