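# Shared fixture builders. The mid-size geometry keeps unit tests fast;
# acceptance tests use the package default (64 x 64 x 256).

mid_geometry <- function(...) {
  eye_geometry_config(n_bscans = 32L, n_ascans = 32L, depth_px = 160L, ...)
}

# analytic phantom (no undulation) for construction checks
analytic_geometry <- function(...) {
  mid_geometry(surface_undulation_um = 0, ...)
}

# a rendered + enhanced default-geometry volume, cached per test run
default_enhanced <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- generate_eye(eye_geometry_config(), seed = 42)
      vol <- render_volume(truth, noise_config(seed = 7))
      cache <<- list(truth = truth, vol = vol, enh = enhance_volume(vol))
    }
    cache
  }
})
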