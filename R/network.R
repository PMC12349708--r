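# Network construction: connectivity sampling, synaptic weight and delay
# sampling, and the microcircuit_network container consumed by the
# integrator.

#' Sample log-normal excitatory-to-excitatory synaptic weights
#'
#' Pyr-to-Pyr conductances are drawn i.i.d. from a log-normal
#' distribution with log-scale mean `params$mu` and log-scale SD
#' `params$sigma` (see [lognormal_weight_params()]). All draws are
#' strictly positive by construction.
#'
#' @param n Number of weights to draw.
#' @param params List with `mu` and `sigma` as returned by
#'   [lognormal_weight_params()].
#' @return Numeric vector of `n` conductances (nS).
#' @export
sample_excitatory_weights <- function(n, params = lognormal_weight_params()) {
  stopifnot(n >= 0)
  if (!is.numeric(params$sigma) || params$sigma <= 0)
    stop("log-normal sigma must be positive")
  stats::rlnorm(n, meanlog = params$mu, sdlog = params$sigma)
}

#' Sample Gaussian synaptic weights, truncated to positive values
#'
#' Non-positive draws are redrawn rather than clipped; at the 10%
#' coefficients of variation used here redraws are vanishingly rare, so
#' the stated mean is preserved to first order.
#'
#' @param n Number of weights.
#' @param mean,sd Gaussian mean and SD (nS); `mean` must be positive,
#'   `sd` non-negative.
#' @return Numeric vector of `n` strictly positive conductances (nS).
#' @export
sample_gaussian_weights <- function(n, mean, sd) {
  stopifnot(n >= 0, mean > 0, sd >= 0)
  w <- stats::rnorm(n, mean, sd)
  bad <- which(w <= 0)
  while (length(bad)) {
    w[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[w[bad] <= 0]
  }
  w
}

#' Sample synaptic transmission delays
#'
#' Delays are Gaussian with mean `d0` and variance `d0/10` (`d0 = 2.0`
#' ms for excitatory presynaptic neurons, 1.0 ms for inhibitory
#' subtypes), truncated to strictly positive values by redrawing.
#'
#' @param pre_class Presynaptic class (`"Pyr"`, `"PV"`, `"SOM"`,
#'   `"VIP"`).
#' @param n Number of delays.
#' @return Numeric vector of `n` strictly positive delays (ms).
#' @export
sample_delays <- function(pre_class, n) {
  stopifnot(n >= 0)
  p <- delay_params(pre_class)
  d <- stats::rnorm(n, p$mean, sqrt(p$var))
  bad <- which(d <= 0)
  while (length(bad)) {
    d[bad] <- stats::rnorm(length(bad), p$mean, sqrt(p$var))
    bad <- bad[d[bad] <= 0]
  }
  d
}

# Sample `m` distinct ordered (pre, post) index pairs uniformly from the
# N_pre x N_post grid, excluding the diagonal when pre and post ranges
# coincide (no autapses). Returns a list(pre, post) of 1-based indices
# within each population.
sample_pairs <- function(n_pre, n_post, p, same_class) {
  n_cells <- as.double(n_pre) * n_post - if (same_class) n_pre else 0
  if (n_cells <= 0 || p <= 0) return(list(pre = integer(0), post = integer(0)))
  m <- stats::rbinom(1L, size = n_cells, prob = p)
  if (m == 0L) return(list(pre = integer(0), post = integer(0)))
  k <- sample.int(n_cells, m) - 1  # 0-based linear indices
  if (same_class) {
    # row i (0-based) holds the n_pre - 1 off-diagonal targets of cell i
    pre <- k %/% (n_pre - 1)
    r <- k %% (n_pre - 1)
    post <- r + (r >= pre)
  } else {
    pre <- k %% n_pre
    post <- k %/% n_pre
  }
  list(pre = as.integer(pre) + 1L, post = as.integer(post) + 1L)
}

#' Build a microcircuit network
#'
#' Samples the full synaptic graph for the given population sizes:
#' each allowed ordered class pair is connected independently with its
#' effective probability, weights are drawn from the pair's conductance
#' law (log-normal for Pyr-to-Pyr, truncated Gaussian otherwise), and
#' each synapse receives a Gaussian transmission delay. Autapses are
#' excluded. Feedforward stimulus fibers are Bernoulli-connected with
#' class-specific probability and carry fixed conductance.
#'
#' Neuron ids are assigned contiguously per class in the order Pyr, PV,
#' SOM, VIP.
#'
#' @param sizes Named integer vector or `population_sizes` object with
#'   counts for `Pyr`, `PV`, `SOM`, `VIP`.
#' @param seed Integer seed; the build is bit-reproducible given the
#'   seed.
#' @param rules Connectivity rule table, see [connectivity_rules()].
#' @param lognorm Log-normal weight parameters for the Pyr-to-Pyr pair.
#' @param n_ff_fibers Number of feedforward fibers (default 500; scale
#'   proportionally when running reduced-scale networks).
#' @param ff_spec Feedforward input specification, see
#'   [feedforward_input_spec()].
#' @return An object of class `microcircuit_network`: a list with
#'   `sizes`, `class_of` (integer codes 1-4 per neuron), `edges`
#'   (list of vectors `pre`, `post`, `weight`, `delay`), `ff` (fiber
#'   edge list `fiber`, `target`, `weight`, `delay`), `n_ff_fibers`,
#'   `rules` and `seed`.
#' @export
build_network <- function(sizes, seed,
                          rules = connectivity_rules(),
                          lognorm = lognormal_weight_params(),
                          n_ff_fibers = feedforward_input_spec()$n_fibers,
                          ff_spec = feedforward_input_spec()) {
  classes <- neuron_classes()
  sizes <- as.integer(sizes[classes])
  names(sizes) <- classes
  stopifnot(all(sizes >= 0), length(seed) == 1L)
  offset <- c(0L, cumsum(sizes))[1:4]
  names(offset) <- classes
  n_total <- sum(sizes)
  class_of <- rep.int(seq_along(classes), sizes)

  set.seed(as.integer(seed))

  pre_l <- list(); post_l <- list(); w_l <- list(); d_l <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    np <- sizes[[r$pre]]; nq <- sizes[[r$post]]
    pr <- sample_pairs(np, nq, r$probability, same_class = r$pre == r$post)
    m <- length(pr$pre)
    if (m == 0L) next
    w <- if (r$weight_law == "log_normal") {
      sample_excitatory_weights(m, lognorm)
    } else {
      sample_gaussian_weights(m, r$g_mean, r$g_sd)
    }
    pre_l[[i]]  <- pr$pre + offset[[r$pre]]
    post_l[[i]] <- pr$post + offset[[r$post]]
    w_l[[i]] <- w
    d_l[[i]] <- sample_delays(r$pre, m)
  }
  edges <- list(
    pre    = unlist(pre_l, use.names = FALSE),
    post   = unlist(post_l, use.names = FALSE),
    weight = unlist(w_l, use.names = FALSE),
    delay  = unlist(d_l, use.names = FALSE)
  )
  if (is.null(edges$pre)) edges <- list(pre = integer(0), post = integer(0),
                                        weight = numeric(0), delay = numeric(0))

  # feedforward fibers: Bernoulli connections per target class, fixed g,
  # excitatory-type delays
  ff_pre <- list(); ff_post <- list()
  for (ci in seq_along(classes)) {
    p <- ff_spec$connection_probability[[classes[ci]]]
    pr <- sample_pairs(n_ff_fibers, sizes[[ci]], p, same_class = FALSE)
    ff_pre[[ci]] <- pr$pre
    ff_post[[ci]] <- pr$post + offset[[ci]]
  }
  ff_fiber <- unlist(ff_pre, use.names = FALSE)
  ff_target <- unlist(ff_post, use.names = FALSE)
  if (is.null(ff_fiber)) { ff_fiber <- integer(0); ff_target <- integer(0) }
  ff <- list(
    fiber = ff_fiber,
    target = ff_target,
    weight = rep.int(ff_spec$g, length(ff_fiber)),
    delay = sample_delays("Pyr", length(ff_fiber))
  )

  structure(
    list(sizes = sizes, class_of = class_of, edges = edges, ff = ff,
         n_ff_fibers = as.integer(n_ff_fibers), rules = rules, seed = seed,
         lognorm = lognorm),
    class = "microcircuit_network"
  )
}

#' @export
print.microcircuit_network <- function(x, ...) {
  cat("microcircuit_network:", sum(x$sizes), "neurons,",
      length(x$edges$pre), "synapses,", x$n_ff_fibers, "feedforward fibers\n")
  print(x$sizes)
  invisible(x)
}

#' Count edges per ordered class pair
#'
#' @param net A `microcircuit_network`.
#' @return A 4x4 matrix of edge counts, rows = presynaptic class,
#'   columns = postsynaptic class.
#' @export
edge_count_matrix <- function(net) {
  classes <- neuron_classes()
  m <- matrix(0L, 4, 4, dimnames = list(pre = classes, post = classes))
  if (length(net$edges$pre)) {
    tab <- table(factor(net$class_of[net$edges$pre], levels = 1:4),
                 factor(net$class_of[net$edges$post], levels = 1:4))
    m[] <- as.integer(tab)
  }
  m
}

#' Export network edges as TSV
#'
#' Writes one row per synapse with columns `pre_id`, `post_id`,
#' `weight_nS`, `delay_ms`, `pre_class`, `post_class`, preceded by
#' comment lines recording population sizes and the build seed.
#'
#' @param net A `microcircuit_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  classes <- neuron_classes()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# microcircuit network export"),
    paste0("# sizes: ", paste(sprintf("%s=%d", classes, net$sizes), collapse = " ")),
    paste0("# seed: ", net$seed)
  ), con)
  df <- data.frame(
    pre_id = net$edges$pre, post_id = net$edges$post,
    weight_nS = net$edges$weight, delay_ms = net$edges$delay,
    pre_class = classes[net$class_of[net$edges$pre]],
    post_class = classes[net$class_of[net$edges$post]]
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scale population sizes for reduced-scale runs
#'
#' Multiplies each class count by `scale` and rounds. Connection
#' probabilities and synaptic weights are left unchanged, so reduced
#' networks receive proportionally less recurrent input; they are
#' intended for testing and desk-scale experiments, not for quantitative
#' extrapolation to the full-size circuit.
#'
#' @param sizes Named counts (`Pyr`, `PV`, `SOM`, `VIP`).
#' @param scale Positive scalar; 1 keeps the sizes unchanged.
#' @return Named integer vector of scaled counts.
#' @export
scale_sizes <- function(sizes, scale) {
  stopifnot(scale > 0)
  s <- as.integer(round(as.numeric(sizes[neuron_classes()]) * scale))
  names(s) <- neuron_classes()
  s
}
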