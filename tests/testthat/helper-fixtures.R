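# Shared in-code fixtures: rendered Gaussian traces and small populations.

gauss_on_grid <- function(grid, mean_bp, sigma_bp, amplitude) {
  amplitude * exp(-0.5 * ((grid - mean_bp) / sigma_bp)^2)
}

# noiseless render of one or more Gaussians as a trace
render_gaussians <- function(means, sigmas, amps, step = 0.5, pad = 30) {
  grid <- seq(min(means) - pad, max(means) + pad, by = step)
  y <- numeric(length(grid))
  for (i in seq_along(means))
    y <- y + gauss_on_grid(grid, means[[i]], sigmas[[i]], amps[[i]])
  cag_trace(grid, y)
}

# render config used whenever a test compares against generator truth
clean_render <- function(...) trace_render_config(attenuation = 1, ...)

expect_population_equal <- function(a, b) {
  expect_identical(a$repeats, b$repeats)
  expect_identical(a$event_counts, b$event_counts)
}
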