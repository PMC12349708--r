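# Trial simulation: configuration, compiled-network preparation, the
# integrate_trial() front end to the C++ core, and rate summaries.

#' Simulation configuration
#'
#' @param dt Integration time step (ms); the membrane equation is
#'   integrated by classical fourth-order Runge-Kutta.
#' @param duration Trial length (ms).
#' @param stimulus_onset Time at which feedforward (stimulus) fibers
#'   start firing (ms).
#' @param discard Initial transient excluded from all analyses (ms).
#' @param n_trials Number of independent trials per condition.
#' @param scale Network scale factor: multiplies all population counts
#'   and the feedforward fiber count. Probabilities and weights are not
#'   rescaled, so reduced-scale dynamics receive proportionally less
#'   recurrent input; scales below 1 are meant for tests and desk runs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.1, duration = 3000, stimulus_onset = 100,
                              discard = 500, n_trials = 50, scale = 1) {
  stopifnot(dt > 0, duration > 0, discard < duration, stimulus_onset >= 0,
            n_trials >= 1, scale > 0)
  structure(list(dt = dt, duration = duration,
                 stimulus_onset = stimulus_onset, discard = discard,
                 n_trials = as.integer(n_trials), scale = scale),
            class = "simulation_config")
}

#' Homogeneous Poisson spike train
#'
#' @param rate Firing rate (Hz); must be non-negative.
#' @param duration Train length (ms).
#' @param seed Optional seed set before drawing.
#' @return Sorted numeric vector of spike times in (0, duration) ms.
#' @export
poisson_train <- function(rate, duration, seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || duration <= 0) return(numeric(0))
  times <- numeric(0)
  t <- 0
  chunk <- max(16L, ceiling(rate * duration / 1000 * 1.2))
  repeat {
    gaps <- stats::rexp(chunk, rate = rate / 1000)
    times <- c(times, t + cumsum(gaps))
    t <- times[length(times)]
    if (t >= duration) break
  }
  times[times < duration]
}

#' Exponential synaptic gate update over one time step
#'
#' The gate decays exactly exponentially between presynaptic arrivals;
#' each arrival (a delta input integrating to unity) increments it by 1.
#'
#' @param s Gate value(s) at the start of the step (non-negative).
#' @param tau Decay time constant (ms), positive.
#' @param dt Step length (ms).
#' @param n_arrivals Number of presynaptic arrivals at the end of the
#'   step (default 0).
#' @return Updated gate value(s).
#' @export
update_gate <- function(s, tau, dt, n_arrivals = 0) {
  stopifnot(all(s >= 0), tau > 0, dt >= 0)
  s * exp(-dt / tau) + n_arrivals
}

#' Total synaptic current through a set of afferents
#'
#' `I = sum_j g_j * (V - E_rev_j) * s_j`, in pA when conductances are in
#' nS and potentials in mV. Positive values (V above the reversal
#' potential) drive the membrane toward the reversal potential, i.e. the
#' current enters the membrane equation with a hyperpolarizing sign.
#'
#' @param V Membrane potential (mV).
#' @param s Gate values, one per afferent.
#' @param g Conductances (nS), aligned with `s`.
#' @param E_rev Reversal potential(s) (mV): 0 for excitatory/external
#'   synapses, -70 for inhibitory.
#' @return Current (pA).
#' @export
synaptic_current <- function(V, s, g, E_rev) {
  stopifnot(length(s) == length(g))
  sum(g * (V - E_rev) * s)
}

# Build the per-pair synaptic decay constant table tau_syn[channel, post
# class]: channels 1..4 are presynaptic classes, channel 5 the external
# AMPA drive. Pairs that never connect get a placeholder of 1 ms (never
# receives input).
tau_syn_table <- function(rules = connectivity_rules()) {
  classes <- neuron_classes()
  tau <- matrix(1, nrow = 5, ncol = 4,
                dimnames = list(c(classes, "ext"), classes))
  for (i in seq_len(nrow(rules)))
    tau[rules$pre[i], rules$post[i]] <- rules$tau_decay[i]
  tau["ext", ] <- background_input_spec()$tau_d
  tau
}

#' Compile a network for simulation
#'
#' Converts the edge lists of a [build_network()] object into the
#' compressed sparse row layout and grid-rounded delays used by the
#' compiled integrator. Delays are rounded to the nearest multiple of
#' `dt`, with a minimum of one step.
#'
#' @param net A `microcircuit_network`.
#' @param dt Integration step (ms).
#' @return An object of class `compiled_network`.
#' @export
compile_network <- function(net, dt = 0.1) {
  stopifnot(inherits(net, "microcircuit_network"), dt > 0)
  n <- sum(net$sizes)
  o <- order(net$edges$pre)
  pre <- net$edges$pre[o]
  counts <- tabulate(pre, nbins = n)
  edge_ptr <- c(0L, cumsum(counts))

  nf <- net$n_ff_fibers
  of <- order(net$ff$fiber)
  fcounts <- tabulate(net$ff$fiber[of], nbins = nf)
  ff_ptr <- c(0L, cumsum(fcounts))

  np <- neuron_params()
  bg <- background_input_spec()
  ff_spec <- feedforward_input_spec()

  structure(list(
    n_neurons = n,
    sizes = net$sizes,
    class_of = as.integer(net$class_of),
    edge_ptr = as.integer(edge_ptr),
    edge_target = as.integer(net$edges$post[o] - 1L),
    edge_weight = net$edges$weight[o],
    edge_delay = pmax(1L, as.integer(round(net$edges$delay[o] / dt))),
    n_fibers = as.integer(nf),
    ff_ptr = as.integer(ff_ptr),
    ff_target = as.integer(net$ff$target[of] - 1L),
    ff_weight = net$ff$weight[of],
    ff_delay = pmax(1L, as.integer(round(net$ff$delay[of] / dt))),
    tau_m = np$tau_m,
    tau_ref = np$tau_ref,
    C_m = np$C_m[1], E_l = np$E_l[1], V_thr = np$V_thr[1],
    V_reset = np$V_reset[1],
    tau_syn = tau_syn_table(net$rules),
    E_rev = c(0, -70, -70, -70, 0),
    bg_rate = unname(bg$rates[neuron_classes()][net$class_of]),
    bg_g = bg$g,
    ff_rate = ff_spec$rate,
    dt = dt
  ), class = "compiled_network")
}

#' Simulate one trial of network activity
#'
#' Integrates the conductance-based LIF network with RK4 at step
#' `config$dt`, with per-neuron Poisson background drive active
#' throughout and feedforward fibers firing from
#' `config$stimulus_onset`. All randomness derives from `trial_seed`,
#' so identical inputs give identical spike records.
#'
#' @param net A `microcircuit_network` or `compiled_network`.
#' @param config A [simulation_config()].
#' @param trial_seed Integer seed for this trial.
#' @param record_v Optional neuron id (1-based) whose membrane potential
#'   trajectory is recorded each step.
#' @param const_g_ext Constant external conductance clamp (nS, reversal
#'   0 mV) applied to every neuron; used for integrator validation
#'   against the closed-form response.
#' @return An object of class `spike_record`: list with `spikes`
#'   (data.frame `neuron_id`, `time`), `class_of`, `sizes`, `duration`,
#'   `trial_seed`, and optionally `v_trace`.
#' @export
integrate_trial <- function(net, config = simulation_config(), trial_seed,
                            record_v = NULL, const_g_ext = 0) {
  if (inherits(net, "microcircuit_network")) net <- compile_network(net, config$dt)
  stopifnot(inherits(net, "compiled_network"))
  if (!isTRUE(all.equal(net$dt, config$dt)))
    stop("network was compiled for dt = ", net$dt,
         " ms; recompile with compile_network(net, dt = ", config$dt, ")")
  n_steps <- as.integer(round(config$duration / config$dt))
  set.seed(as.integer(trial_seed))
  res <- simulate_trial_cpp(
    n_neurons = net$n_neurons, class_of = net$class_of,
    edge_ptr = net$edge_ptr, edge_target = net$edge_target,
    edge_weight = net$edge_weight, edge_delay = net$edge_delay,
    n_fibers = net$n_fibers, ff_ptr = net$ff_ptr,
    ff_target = net$ff_target, ff_weight = net$ff_weight,
    ff_delay = net$ff_delay,
    tau_m = net$tau_m, tau_ref_steps = as.integer(round(net$tau_ref / config$dt)),
    C_m = net$C_m, E_l = net$E_l, V_thr = net$V_thr, V_reset = net$V_reset,
    tau_syn = net$tau_syn, E_rev = net$E_rev,
    bg_rate = net$bg_rate, bg_g = net$bg_g,
    ff_rate = net$ff_rate, onset_ms = config$stimulus_onset,
    dt = config$dt, n_steps = n_steps,
    const_g_ext = const_g_ext,
    record_v = if (is.null(record_v)) -1L else as.integer(record_v) - 1L
  )
  rec <- list(
    spikes = data.frame(neuron_id = res$neuron_id, time = res$time),
    class_of = net$class_of,
    sizes = net$sizes,
    duration = config$duration,
    trial_seed = trial_seed
  )
  if (!is.null(record_v)) rec$v_trace <- res$v_trace
  rec$v_final <- res$v_final
  structure(rec, class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("spike_record:", nrow(x$spikes), "spikes from", sum(x$sizes),
      "neurons over", x$duration, "ms (trial seed", x$trial_seed, ")\n")
  invisible(x)
}

#' Mean population firing rate per neuron class
#'
#' Total class spikes in the window divided by the number of class
#' members and the window length.
#'
#' @param rec A `spike_record`.
#' @param window Length-2 numeric `[lo, hi)` in ms; defaults to the
#'   post-transient analysis window `[500, duration]`.
#' @return Named numeric vector of rates (Hz), one per class.
#' @export
compute_rates <- function(rec, window = c(500, rec$duration)) {
  stopifnot(inherits(rec, "spike_record"), length(window) == 2,
            window[1] >= 0, window[2] <= rec$duration, window[1] < window[2])
  classes <- neuron_classes()
  sel <- rec$spikes$time >= window[1] & rec$spikes$time < window[2]
  cls <- rec$class_of[rec$spikes$neuron_id[sel]]
  counts <- tabulate(cls, nbins = 4)
  n_class <- as.numeric(rec$sizes[classes])
  if (any(n_class == 0))
    warning("empty class(es): ", paste(classes[n_class == 0], collapse = ", "))
  rate <- ifelse(n_class > 0,
                 counts / n_class / ((window[2] - window[1]) / 1000), 0)
  names(rate) <- classes
  rate
}

#' Export a spike record as TSV
#'
#' @param rec A `spike_record`.
#' @param path Output path.
#' @param trial Trial index recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_spikes_tsv <- function(rec, path, trial = 1L) {
  classes <- neuron_classes()
  df <- data.frame(trial = trial,
                   neuron_id = rec$spikes$neuron_id,
                   class = classes[rec$class_of[rec$spikes$neuron_id]],
                   time_ms = rec$spikes$time)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
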