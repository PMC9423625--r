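# Shared fixtures, built in code.  Expensive datasets are memoised for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small random frame set suitable for cost-function oracles:
# 11 x 11 frames, window 3, sub-pixel widths, N = 2
cost_fixture <- function(seed = 41) {
  set.seed(seed)
  H <- 11L
  sample <- array(runif(H * H * 2, 0.5, 2), dim = c(H, H, 2))
  reference <- array(runif(H * H * 2, 0.5, 2), dim = c(H, H, 2))
  speckle_frame_set(sample, reference)
}

# uniform single-kernel phantom dataset (the "standard phantom")
uniform_phantom_ds <- function(H = 96, noise = FALSE, n_positions = 25,
                               mean_counts = 1e4,
                               axes = c(2, 1, 30), Tval = 0.8,
                               u = c(0.6, -0.4), seed = 7, noise_seed = 11) {
  labels <- matrix(1L, H, H)
  regions <- data.frame(label = 1, T = Tval, ux = u[1], uy = u[2],
                        sigma_major = axes[1], sigma_minor = axes[2],
                        theta = axes[3])
  ph <- phantom_spec(labels, regions)
  synthesize_dataset(
    pattern_spec(c(H, H), mean_counts = mean_counts, seed = seed), ph,
    acquisition_spec(n_positions = n_positions, noise = noise,
                     seed = noise_seed))
}
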