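#' Default model configuration
#'
#' All tunable constants of the circuit in one nested list, organised in the
#' sections \code{lif}, \code{stdp}, \code{weights}, \code{gating} and
#' \code{protocol}. The neuron, plasticity and dopamine constants follow the
#' published parameter set (\code{v_th} 0.1, \code{tau_m} 20 ms, \code{A+}
#' 0.925, \code{A-} 0.9, \code{DA_peak} 10, \code{tau_t} 2, conflict
#' threshold 3, dopamine window 100 ms). The fixed wiring magnitudes
#' (\code{mutual}, \code{kc_apl}, \code{apl_kc}, \code{da_apl},
#' \code{apl_da}, \code{da_mbon}, \code{relay}) and the input-current gain
#' are calibration parameters of this implementation; see the methods
#' vignette for how each default was chosen and then frozen.
#'
#' @param ... named overrides of individual entries, using dotted paths into
#'   the sections, e.g. \code{default_config(protocol.dt = 1,
#'   weights.mutual = 3)}
#' @return nested configuration list
#' @export
default_config <- function(...) {
  cfg <- list(
    lif = unclass(lif_config()),
    stdp = unclass(stdp_config()),
    weights = list(
      init = 0.5,    # initial memory weights (CC input->output, KC->MBON)
      relay = 2,     # one-to-one visual->CC-input and visual->KC relay
      mutual = 2,    # mutual inhibition between the two output neurons
      kc_apl = 1.1, apl_kc = 1.5, da_apl = 3, apl_da = 1.5, da_mbon = 2,
      min = 0, max = 10),
    gating = list(
      th = 3,             # conflict-monitor threshold on |s1 - s2|
      da_duration = 100,  # ms of phasic dopamine drive at choice onset
      da_drive = 2),      # external current to the DA neuron in that window
    input_gain = 0.16,    # saliency -> input current conversion
    da = list(peak = 10, tau_t = 2, cutoff = 0.01),
    protocol = list(
      dt = 0.1,           # integration step, ms
      episode_ms = 1000,  # training presentation per pattern
      choice_ms = 2000,   # choice phase duration
      subtrial_ms = 100)) # sub-trial length within the choice phase
  dots <- list(...)
  for (nm in names(dots)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(path) == 1) {
      if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
      cfg[[nm]] <- dots[[nm]]
    } else {
      if (!path[1] %in% names(cfg) || !path[2] %in% names(cfg[[path[1]]]))
        stop("unknown config key: ", nm)
      cfg[[path[1]]][[path[2]]] <- dots[[nm]]
    }
  }
  cfg
}

#' Build the two-pathway decision circuit
#'
#' Constructs the untrained model: a 5-neuron visual system feeding, by
#' one-to-one relays, a linear central-complex pathway (input layer ->
#' two-behaviour output layer, full plastic memory matrix, mutual
#' inhibition) and a nonlinear mushroom-body pathway (Kenyon cells -> two
#' MBONs) gated by two APL interneurons and one dopaminergic neuron. Both
#' memory matrices start at the same constant, so the untrained network is
#' exactly symmetric between the two behaviours and its preference index is
#' 0 in expectation.
#'
#' @param n_channels number of input channels (5 for the visual patterns;
#'   the multi-cue tasks use 2 or 4)
#' @param config a [default_config()] list
#' @return an object of class \code{decision_circuit}
#' @export
#' @examples
#' m <- decision_circuit()
#' coef(m)  # untrained memory weights, all 0.5
decision_circuit <- function(n_channels = 5, config = default_config()) {
  stopifnot(n_channels >= 1)
  W0 <- matrix(config$weights$init, n_channels, 2,
               dimnames = list(NULL, c("behavior1", "behavior2")))
  structure(list(n = n_channels, config = config,
                 W_cc = W0, W_mb = W0,
                 da_on = TRUE, apl_on = TRUE,
                 trained = FALSE, log = NULL),
            class = "decision_circuit")
}

#' Enable or disable the gating neurons of the nonlinear pathway
#'
#' Ablation switch used in the mechanism analyses: \code{da_on = FALSE}
#' removes the dopaminergic neuron's outgoing connections (and its external
#' drive), \code{apl_on = FALSE} removes the APL interneurons' outgoing
#' connections. With both off the mushroom-body pathway reduces to the
#' uninhibited feed-forward KC -> MBON network and behaves exactly like the
#' linear circuit.
#'
#' @param model a [decision_circuit()]
#' @param da_on,apl_on logical switches
#' @return the modified model
#' @export
set_nonlinear_gating <- function(model, da_on = TRUE, apl_on = TRUE) {
  stopifnot(inherits(model, "decision_circuit"))
  model$da_on <- isTRUE(da_on)
  model$apl_on <- isTRUE(apl_on)
  model
}

# map the named Fig.-5 variants onto gating switches
variant_gating <- function(model, variant = c("nonlinear", "only-APL",
                                              "linear", "none")) {
  variant <- match.arg(variant)
  switch(variant,
         "nonlinear" = set_nonlinear_gating(model, TRUE, TRUE),
         "only-APL"  = set_nonlinear_gating(model, FALSE, TRUE),
         # "linear" reads the CC input layer; gating state is irrelevant but
         # the reduced network is used so the MB side cannot interfere
         "linear"    = set_nonlinear_gating(model, FALSE, FALSE),
         "none"      = set_nonlinear_gating(model, FALSE, FALSE))
}

#' @export
print.decision_circuit <- function(x, ...) {
  cat("Two-pathway fly decision circuit (", x$n, "input channels )\n")
  cat("  linear pathway : CC", x$n, "-> 2, mutual inhibition",
      x$config$weights$mutual, "\n")
  cat("  nonlinear path : KC", x$n, "-> 2 MBON, APL x2, DA x1 (da_on =",
      x$da_on, ", apl_on =", x$apl_on, ")\n")
  cat("  trained        :", x$trained, "\n")
  s <- colSums(x$W_cc)
  cat("  memory sums    : s1 =", round(s[1], 3), ", s2 =", round(s[2], 3),
      "(conflict threshold", x$config$gating$th, ")\n")
  invisible(x)
}

#' @export
summary.decision_circuit <- function(object, ...) {
  out <- list(n = object$n, trained = object$trained,
              W_cc = object$W_cc, W_mb = object$W_mb,
              agree = isTRUE(all.equal(object$W_cc, object$W_mb)),
              sums = colSums(object$W_cc),
              log = object$log)
  class(out) <- "summary.decision_circuit"
  out
}

#' @export
print.summary.decision_circuit <- function(x, ...) {
  cat("decision_circuit summary\n")
  cat("  trained:", x$trained, " CC/MB weights agree:", x$agree, "\n")
  cat("  CC memory matrix (input channel x behaviour):\n")
  print(round(x$W_cc, 3))
  if (!is.null(x$log)) {
    cat("  training log:\n")
    print(x$log)
  }
  invisible(x)
}

#' Extract the learned memory weights
#'
#' @param object a [decision_circuit()]
#' @param pathway \code{"cc"} (central complex, default) or \code{"mb"}
#'   (mushroom body); after training the two are identical
#' @param ... unused
#' @return the input-channel-by-behaviour weight matrix
#' @export
coef.decision_circuit <- function(object, pathway = c("cc", "mb"), ...) {
  pathway <- match.arg(pathway)
  if (pathway == "cc") object$W_cc else object$W_mb
}

#' Simulate spike trains from the model
#'
#' \code{simulate} runs the choice-phase network freely on a stimulus and
#' returns spike records, one per repetition.
#'
#' @param object a [decision_circuit()]
#' @param nsim number of repetitions
#' @param seed RNG seed
#' @param current,other stimulus pair, as for [spike_record()]
#' @param duration ms per repetition
#' @param ... unused
#' @return list of \code{nsim} spike-record data frames
#' @export
simulate.decision_circuit <- function(object, nsim = 1, seed = NULL,
                                      current = encode_pattern("green", "upright"),
                                      other = numeric(5), duration = 500, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    spike_record(object, current, other, duration))
}
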