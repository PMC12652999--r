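# Shared fixture builders, all deterministic.

flat_spectrum <- function(value = 1, grid = 380:600) {
  spectrum(grid, rep(value, length(grid)))
}

gauss_spectrum <- function(peak = 451, sd = 15, amplitude = 100,
                           grid = 380:600) {
  spectrum(grid, amplitude * exp(-0.5 * ((grid - peak) / sd)^2))
}

delta_irf <- function(grid) {
  r <- numeric(length(grid))
  r[1] <- 1
  irf(grid, r)
}

trace_grid <- function(t_max = 80, bin = 0.4) seq(0, t_max, by = bin)

noiseless_cells_cfg <- function(seed = 1, ec50 = 594e-9, slope = -0.46,
                                preparation = "cell") {
  sim_config(seed = seed,
             cells = list(ec50 = ec50, slope = slope, noise_sigma = 0,
                          max_quench_sd = 0, ec50_cv = 0,
                          preparation = preparation))
}
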