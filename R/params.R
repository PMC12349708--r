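# Canonical parameter tables for the layers-2/3 V1 microcircuit.
#
# All defaults reproduce the published model: four neuron classes
# (excitatory pyramidal plus PV, SOM and VIP inhibitory interneurons),
# class-pair connection probabilities with subtype weighting factors,
# Gaussian / log-normal synaptic conductance laws, per-pair decay time
# constants, and Poisson background / feedforward drive.

#' Neuron class labels used throughout the package
#'
#' @return Character vector `c("Pyr", "PV", "SOM", "VIP")`. The order is
#'   significant: neuron ids are assigned contiguously per class in this
#'   order, and integer class codes follow it.
#' @export
neuron_classes <- function() c("Pyr", "PV", "SOM", "VIP")

#' Membrane parameters for each neuron class
#'
#' Leaky integrate-and-fire parameters. The membrane time constant is
#' class-specific (PV cells are fast-spiking, with a much shorter time
#' constant); capacitance, leak reversal, threshold and reset are shared.
#'
#' @return A data.frame with one row per class and columns `class`,
#'   `tau_m` (membrane time constant, ms), `tau_ref` (absolute refractory
#'   period, ms), `C_m` (membrane capacitance, pF), `E_l` (leak reversal
#'   potential, mV), `V_thr` (spike threshold, mV), and `V_reset`
#'   (post-spike reset potential, mV).
#' @export
neuron_params <- function() {
  data.frame(
    class   = neuron_classes(),
    tau_m   = c(10.5, 3.1, 11.8, 10.9),
    tau_ref = c(2.0, 1.0, 1.0, 1.0),
    C_m     = 200,
    E_l     = -70,
    V_thr   = -50,
    V_reset = -60,
    stringsAsFactors = FALSE
  )
}

#' Class-level connection probabilities and subtype weighting factors
#'
#' Base probabilities are defined at the level of excitatory/inhibitory
#' classes; subtype-specific weighting factors multiply the base
#' probability of the corresponding class pair.
#'
#' @return A list with elements `p_ee`, `p_ei`, `p_ie`, `p_ii` (base
#'   probabilities for excitatory-to-excitatory, excitatory-to-inhibitory,
#'   inhibitory-to-excitatory and inhibitory-to-inhibitory connections)
#'   and `weighting` (named numeric vector of subtype factors, names
#'   `"pre->post"`).
#' @export
connection_probabilities <- function() {
  list(
    p_ee = 0.1009,
    p_ei = 0.1346,
    p_ie = 0.1689,
    p_ii = 0.1371,
    weighting = c(
      "PV->Pyr"  = 1,
      "SOM->Pyr" = 1,
      "PV->PV"   = 1,
      "SOM->PV"  = 0.857,
      "VIP->SOM" = 0.625,
      "SOM->VIP" = 1
    )
  )
}

#' Synaptic connectivity rules for all allowed class pairs
#'
#' One row per allowed ordered (presynaptic class, postsynaptic class)
#' pair; pairs absent from the table are never connected (e.g. VIP cells
#' never contact Pyr or PV cells). The effective connection probability
#' already includes the subtype weighting factor. Pyr-to-Pyr conductances
#' follow a long-tailed log-normal law (see
#' [lognormal_weight_params()]); every other pair is Gaussian with a 10%
#' coefficient of variation, truncated to positive values.
#'
#' @return A data.frame with columns `pre`, `post`, `probability`,
#'   `weight_law` (`"log_normal"` or `"gaussian"`), `g_mean` and `g_sd`
#'   (synaptic conductance, nS; `NA` for the log-normal pair), and
#'   `tau_decay` (postsynaptic decay time constant, ms).
#' @export
connectivity_rules <- function() {
  cp <- connection_probabilities()
  w <- cp$weighting
  rules <- data.frame(
    pre  = c("Pyr", "Pyr",  "Pyr",  "Pyr",  "PV",  "SOM", "PV",  "SOM", "VIP", "SOM"),
    post = c("Pyr", "PV",   "SOM",  "VIP",  "Pyr", "Pyr", "PV",  "PV",  "SOM", "VIP"),
    probability = c(
      cp$p_ee,
      cp$p_ei, cp$p_ei, cp$p_ei,
      cp$p_ie * w[["PV->Pyr"]],
      cp$p_ie * w[["SOM->Pyr"]],
      cp$p_ii * w[["PV->PV"]],
      cp$p_ii * w[["SOM->PV"]],
      cp$p_ii * w[["VIP->SOM"]],
      cp$p_ii * w[["SOM->VIP"]]
    ),
    weight_law = c("log_normal", rep("gaussian", 9)),
    g_mean = c(NA, 0.95, 0.29, 0.27, 4.32, 1.26, 3.51, 1.22, 0.32, 1.18),
    g_sd   = c(NA, 0.095, 0.029, 0.027, 0.432, 0.126, 0.351, 0.122, 0.032, 0.118),
    tau_decay = c(2.0, 2.0, 2.0, 2.0, 6.4, 13.1, 4.6, 5.2, 13.1, 10.2),
    stringsAsFactors = FALSE
  )
  rules
}

#' Parameters of the log-normal excitatory-to-excitatory weight law
#'
#' Pyr-to-Pyr synaptic conductances follow a log-normal distribution with
#' log-scale standard deviation `sigma` and log-scale mean
#' `mu = sigma^2 + log(epsp_scale)`, i.e. the median conductance is
#' `epsp_scale * exp(sigma^2)` nS.
#'
#' @param sigma Log-scale standard deviation (dimensionless); default 1.0.
#' @param epsp_scale Scale constant of the constraint
#'   `sigma^2 = mu - log(epsp_scale)`; default 0.10.
#' @return A list with elements `mu` and `sigma`.
#' @export
lognormal_weight_params <- function(sigma = 1.0, epsp_scale = 0.10) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  list(mu = sigma^2 + log(epsp_scale), sigma = sigma)
}

#' Synaptic delay parameters by presynaptic class
#'
#' Delays are Gaussian with mean `d0` and variance `d0/10`, truncated to
#' strictly positive values: `d0 = 2.0` ms for excitatory (Pyr)
#' presynaptic neurons and `d0 = 1.0` ms for all inhibitory subtypes.
#'
#' @param pre_class One of `"Pyr"`, `"PV"`, `"SOM"`, `"VIP"`.
#' @return A list with elements `mean` (ms) and `var` (ms^2).
#' @export
delay_params <- function(pre_class) {
  pre_class <- match.arg(pre_class, neuron_classes())
  d0 <- if (pre_class == "Pyr") 2.0 else 1.0
  list(mean = d0, var = d0 / 10)
}

#' Background input specification
#'
#' Every neuron receives one independent Poisson spike train at a
#' class-specific rate through an AMPA-type synapse (reversal 0 mV),
#' active for the entire trial. This drive generates spontaneous
#' activity.
#'
#' @return A list with `rates` (Hz, named by class), `g` (conductance,
#'   nS) and `tau_d` (decay time constant, ms).
#' @export
background_input_spec <- function() {
  list(
    rates = c(Pyr = 190, PV = 770, SOM = 100, VIP = 150),
    g = 10.0,
    tau_d = 2.0
  )
}

#' Feedforward (stimulus) input specification
#'
#' The visual stimulus is carried by a pool of Poisson fibers firing at
#' a common rate from stimulus onset onward. Each fiber contacts each
#' neuron independently with a class-specific probability (an order of
#' magnitude denser onto Pyr cells), through AMPA-type synapses.
#'
#' @return A list with `n_fibers`, `rate` (Hz), `g` (nS), `tau_d` (ms)
#'   and `connection_probability` (named by class).
#' @export
feedforward_input_spec <- function() {
  list(
    n_fibers = 500,
    rate = 25,
    g = 2.5,
    tau_d = 2.0,
    connection_probability = c(Pyr = 0.1, PV = 0.01, SOM = 0.01, VIP = 0.01)
  )
}

#' Total neuron count and fixed interneuron counts of the reference model
#'
#' The control circuit has 10341 Pyr, 1341 PV, 875 SOM and 700 VIP
#' neurons (13257 in total, E/I ratio ~= 3.5).
#'
#' @return A named integer vector with elements `Pyr`, `PV`, `SOM`,
#'   `VIP`.
#' @export
control_counts <- function() {
  c(Pyr = 10341L, PV = 1341L, SOM = 875L, VIP = 700L)
}
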