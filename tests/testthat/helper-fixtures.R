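# Shared fixtures, memoised so expensive synthetic sessions are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_session <- function(seed = 3) {
  fixture(paste0("session_", seed), function()
    generate_session(synth_config(seed = seed)))
}

quiet_session <- function(seed = 9) {
  fixture(paste0("quiet_", seed), function()
    generate_session(synth_config(
      seed = seed, counts = c(shot = 0),
      background = c(standing = 1, walking = 0, running = 0))))
}

# a short random window with plausible kick structure, for feature oracles
random_window <- function() {
  w <- matrix(stats::rnorm(400 * 6, sd = 0.2), 400, 6)
  colnames(w) <- IMU_CHANNELS
  w
}
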