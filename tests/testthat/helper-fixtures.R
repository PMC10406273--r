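# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# An 8-network study on a reduced grid with no group effects: the routine
# fixture for the statistics modules.
null_study_small <- function() {
  fixture("null_study_small", function() {
    cfg <- synth_config(grid_dims = c(20L, 22L, 20L), n_networks = 8L,
                        n_timepoints = 40L, n_control = 6L, n_patient = 6L,
                        noise_sd = 0.05, seed = 42L)
    simulate_study(cfg)
  })
}

# A tiny model spec that keeps unit tests fast; the full-width default spec
# is exercised by the architecture-accounting tests.
tiny_spec <- function() {
  model_spec(stem_channels = 4L, encoder_channels = c(3L, 2L, 1L),
             decoder_channels = c(2L, 3L, 4L), dropout_rate = 0)
}

tiny_model <- function(seed = 1L) {
  build_model(tiny_spec(), c(15L, 15L, 15L), init_seed = seed)
}

random_map4d <- function(dims, seed = 1L) {
  set.seed(seed)
  array(runif(prod(dims)), dim = dims)
}

# strip map3d/fnc attributes down to a plain array for value comparisons
vals <- function(m) array(as.vector(m), dim = dim(m))
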