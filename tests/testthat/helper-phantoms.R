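# Shared phantom fixtures, memoised so expensive runs are computed once per
# test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noisy phantom for unit tests
small_phantom <- function(seed = 9) {
  memo(paste0("small_", seed),
       generate_phantom(phantom_spec(shape = c(64, 64, 64)), seed = seed))
}

# exactly piecewise-constant phantom (no noise, no point-spread blur)
constant_phantom <- function(seed = 3) {
  memo(paste0("const_", seed), {
    spec <- phantom_spec(shape = c(64, 64, 64),
                         hu_parenchyma = c(-750, 0), hu_vessel = c(30, 0),
                         hu_background = c(40, 0), psf_sigma_mm = 0)
    generate_phantom(spec, seed = seed)
  })
}

phantom_config <- function() pipeline_config(min_component_ml = 1)

# full pipeline on the small noisy phantom
small_run <- function(seed = 9) {
  memo(paste0("small_run_", seed), {
    ph <- small_phantom(seed)
    run_pipeline(ph$volume, ph$truth$seeds, phantom_config())
  })
}

# full pipeline on the default 128^3 phantom (the expensive shared fixture)
default_run <- function(seed = 1) {
  memo(paste0("default_run_", seed), {
    ph <- generate_phantom(phantom_spec(), seed = seed)
    list(phantom = ph,
         result = run_pipeline(ph$volume, ph$truth$seeds, phantom_config()))
  })
}

per_lobe_dice <- function(labels, truth_labels) {
  vapply(1:6, function(l) dice(labels$data == l, truth_labels$data == l), 0)
}
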