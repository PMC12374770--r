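# Shared fixtures: the standard two-layer study medium and lazily computed,
# cached Monte Carlo runs (expensive runs are shared across test blocks).

std_medium <- function() {
  two_layer_medium(maternal_layer(), optical_layer(0.09333, 9.551))
}

std_mc_layers <- function(medium = std_medium(), g = 0.9) {
  list(as_mc_layer(medium$top, g = g), as_mc_layer(medium$bottom, g = g))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# moderate-size homogeneous MC run used by several transport tests
mc_homog_small <- function() {
  cached("mc_homog_small", run_layered_mc(
    list(mc_layer(mua = 0.1, mus = 100, g = 0.9, n = 1.4)),
    mc_config(n_photons = 2e5, seed = 7, rho = 2, max_time = 5, n_bins = 50)))
}

# moderate-size two-layer MC run (standard medium)
mc_two_layer_small <- function() {
  cached("mc_two_layer_small", run_layered_mc(
    std_mc_layers(),
    mc_config(n_photons = 3e5, seed = 2, rho = 2, max_time = 5, n_bins = 50)))
}

# the full-size two-layer MC run for the diffusion-equivalence and
# depth-monotonicity checks
mc_two_layer_full <- function() {
  cached("mc_two_layer_full", run_layered_mc(
    std_mc_layers(),
    mc_config(n_photons = 1e7, seed = 20260921, rho = 2, max_time = 5,
              n_bins = 50)))
}
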