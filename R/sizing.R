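# Population sizing for E/I-ratio conditions.
#
# The E/I ratio is defined as the Pyr population size divided by the
# combined size of all inhibitory interneuron populations. A condition is
# generated from a target ratio by converting neurons of one interneuron
# subtype (PV or SOM) into Pyr neurons, holding the other two subtypes
# and the total count fixed.

#' Size the four neuronal populations for a target E/I ratio
#'
#' Computes integer population counts whose total equals `total` and
#' whose excitatory-to-inhibitory ratio is as close as possible to
#' `ratio`, by varying the Pyr count and one interneuron subtype while
#' holding the other two subtypes fixed. The Pyr count is
#' `round(total * r / (1 + r))` and the varied subtype absorbs the
#' rounding residual.
#'
#' @param ratio Target E/I ratio (Pyr count over total interneuron
#'   count); must be positive.
#' @param varied Which interneuron subtype is traded against Pyr
#'   neurons: `"PV"` or `"SOM"`.
#' @param total Total neuron count, held fixed across conditions
#'   (default 13257, the reference circuit).
#' @param fixed Named integer vector giving the counts of the two
#'   non-varied interneuron subtypes. Defaults to the control counts of
#'   the subtypes other than `varied`.
#' @return An object of class `population_sizes`: a named integer vector
#'   with elements `Pyr`, `PV`, `SOM`, `VIP`, plus attributes `ratio`
#'   (achieved ratio) and `varied`.
#' @examples
#' size_populations(3.5, "PV")   # the control circuit
#' size_populations(4.0, "PV")   # fewer PV cells, more Pyr cells
#' @export
size_populations <- function(ratio, varied = c("PV", "SOM"), total = 13257L,
                             fixed = NULL) {
  varied <- match.arg(varied)
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0,
            is.numeric(total), length(total) == 1L, total > 0)
  inh_classes <- setdiff(neuron_classes(), "Pyr")
  fixed_classes <- setdiff(inh_classes, varied)
  if (is.null(fixed)) {
    fixed <- control_counts()[fixed_classes]
  }
  if (!all(fixed_classes %in% names(fixed)))
    stop("`fixed` must name the two non-varied subtypes: ",
         paste(fixed_classes, collapse = ", "))
  fixed <- fixed[fixed_classes]
  if (any(fixed < 0)) stop("fixed counts must be non-negative")

  n_pyr <- as.integer(round(total * ratio / (1 + ratio)))
  n_varied <- as.integer(total - n_pyr - sum(fixed))
  if (n_varied < 0)
    stop(sprintf(
      "infeasible target: ratio %.3g with fixed counts %s would require %d %s neurons",
      ratio, paste(fixed, collapse = "+"), n_varied, varied))

  sizes <- c(Pyr = n_pyr, PV = 0L, SOM = 0L, VIP = 0L)
  sizes[fixed_classes] <- as.integer(fixed)
  sizes[varied] <- n_varied
  sizes <- sizes[neuron_classes()]
  structure(sizes,
            ratio = unname(n_pyr / sum(sizes[inh_classes])),
            varied = varied,
            class = "population_sizes")
}

#' @export
print.population_sizes <- function(x, ...) {
  cat("Microcircuit population sizes (total ", sum(x), "):\n", sep = "")
  print(unclass(x)[seq_along(x)])
  cat(sprintf("achieved E/I ratio %.4f (varied subtype: %s)\n",
              attr(x, "ratio"), attr(x, "varied")))
  invisible(x)
}

#' Population sizes of the control condition
#'
#' The reference circuit: 10341 Pyr, 1341 PV, 875 SOM and 700 VIP
#' neurons (achieved E/I ratio 10341/2916 ~= 3.546, nominally labelled
#' 3.5). Note this row is an anchor inherited from the reference model;
#' it is not produced by the rounding rule of [size_populations()],
#' which would give 10311 Pyr for an exact target of 3.5.
#'
#' @return A `population_sizes` object.
#' @export
control_sizes <- function() {
  sizes <- control_counts()
  structure(sizes,
            ratio = unname(sizes[["Pyr"]] / sum(sizes[-1])),
            varied = "PV",
            class = "population_sizes")
}

#' Population sizes for a named E/I condition
#'
#' Maps a nominal E/I-ratio label to population counts. The label 3.5
#' denotes the control circuit and returns its canonical counts; any
#' other ratio is produced by [size_populations()] with the
#' corresponding subtype varied against Pyr neurons.
#'
#' @inheritParams size_populations
#' @return A `population_sizes` object.
#' @export
condition_sizes <- function(ratio, varied = c("PV", "SOM"), total = 13257L) {
  varied <- match.arg(varied)
  if (isTRUE(all.equal(ratio, 3.5)) && total == 13257L) return(control_sizes())
  size_populations(ratio, varied, total)
}
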