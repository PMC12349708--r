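# Shared fixtures: hand-built containers and synthetic signals used
# across test files.

# a spike_record built directly from a spike table
make_record <- function(neuron_id, time, sizes = c(Pyr = 4L, PV = 2L, SOM = 2L, VIP = 2L),
                        duration = 3000) {
  structure(list(
    spikes = data.frame(neuron_id = as.integer(neuron_id), time = as.numeric(time)),
    class_of = rep.int(1:4, sizes),
    sizes = sizes,
    duration = duration,
    trial_seed = NA_integer_
  ), class = "spike_record")
}

# a psth object from a plain numeric vector (2 ms bins by default)
make_psth <- function(x, bin_width = 2) {
  structure(as.numeric(x), bin_width = bin_width,
            window = c(0, length(x) * bin_width), class_label = "Pyr",
            fs = 1000 / bin_width, class = "psth")
}

# synthetic power spectrum: power-law aperiodic plus log10-domain
# Gaussian bumps, on the frequency grid of an n-sample signal at fs Hz
make_spectrum <- function(exponent = 2, offset = 1, bumps = list(),
                          n = 1250, fs = 500) {
  freq <- (0:(n %/% 2)) * fs / n
  lp <- offset - exponent * log10(pmax(freq, freq[2]))
  for (b in bumps)  # b = c(center_hz, height_log10, sd_hz)
    lp <- lp + b[2] * exp(-(freq - b[1])^2 / (2 * b[3]^2))
  structure(list(freq = freq, power = 10^lp, n_trials = 1),
            class = "power_spectrum")
}

# small control-like network for dynamics tests (fractional scale)
small_network <- function(scale = 0.05, seed = 99) {
  sizes <- scale_sizes(control_counts(), scale)
  build_network(sizes, seed = seed,
                n_ff_fibers = max(1L, round(500 * scale)))
}
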