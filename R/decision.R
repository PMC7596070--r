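#' Preference index
#'
#' \eqn{PI = (t_1 - t_2)/(t_1 + t_2)}: the normalised difference between the
#' counts of the two behavioural choices over a choice phase. +1 means the
#' current pattern was always approached, -1 always avoided.
#'
#' @param t1,t2 non-negative choice counts for behaviours 1 and 2
#' @return preference index in \code{[-1, 1]}
#' @export
#' @examples
#' preference_index(15, 5)  # 0.5
preference_index <- function(t1, t2) {
  stopifnot(t1 >= 0, t2 >= 0)
  if (t1 + t2 == 0) stop("no choices recorded: t1 + t2 must be positive")
  (t1 - t2) / (t1 + t2)
}

#' Conflict monitor: route a stimulus to the linear or nonlinear pathway
#'
#' Sums the central-complex memory weights from the active (nonzero) filtered
#' input channels to each output behaviour (\code{s1}, \code{s2}). If the
#' difference exceeds the threshold the fast linear pathway can discriminate
#' and is used; otherwise the stimulus is in conflict and the nonlinear
#' mushroom-body pathway is engaged. A stimulus with at most one live
#' channel is never in conflict and always routes to the linear pathway.
#'
#' @param model a [decision_circuit()]
#' @param filtered_input length-\code{model$n} filtered stimulus vector
#' @return \code{"linear"} or \code{"nonlinear"}, with attributes \code{s1},
#'   \code{s2}
#' @export
conflict_monitor <- function(model, filtered_input) {
  active <- which(filtered_input > 0)
  s1 <- sum(model$W_cc[active, 1])
  s2 <- sum(model$W_cc[active, 2])
  # a single live cue cannot be in conflict with itself: the fast linear
  # pathway always suffices, whatever the memory sums say. Only with two or
  # more competing cues does the weight-sum threshold arbitrate.
  out <- if (length(active) <= 1 ||
             abs(s1 - s2) > model$config$gating$th) "linear" else "nonlinear"
  structure(out, s1 = s1, s2 = s2)
}

#' Run the 2-second choice phase on a stimulus pair
#'
#' The choice phase is split into sub-trials (default 20 x 100 ms) with the
#' network state reset between them; each sub-trial's first output spike is
#' one behavioural choice. The conflict monitor selects the readout pathway
#' (overridable). Under the nonlinear pathway the dopaminergic neuron is
#' driven externally for the first \code{da_duration} ms of the phase,
#' transiently silencing APL so the salient cue's visual-to-KC relay is
#' potentiated before APL gating resumes. The memory matrices are frozen;
#' STDP runs only on the gating connections. Sub-trials with no output spike
#' are resolved uniformly at random; a stimulus whose filtered input is all
#' zero (identical patterns) is flagged undecided instead.
#'
#' @param model a (usually trained) [decision_circuit()]
#' @param current the attended pattern; \code{other} the competing pattern
#' @param other competing pattern
#' @param duration choice-phase length, ms (default from config, 2000)
#' @param pathway \code{"auto"} (conflict monitor), \code{"linear"} or
#'   \code{"nonlinear"}
#' @param da_duration override of the dopamine window, ms
#' @return an object of class \code{decision_outcome}: pathway, counts
#'   \code{t1}, \code{t2}, \code{pi}, per-sub-trial choices and first-spike
#'   latencies, number of undecided sub-trials, and the conflict sums
#' @export
choose <- function(model, current, other, duration = NULL,
                   pathway = c("auto", "linear", "nonlinear"),
                   da_duration = NULL) {
  stopifnot(inherits(model, "decision_circuit"))
  pathway <- match.arg(pathway)
  cfg <- model$config
  if (is.null(duration)) duration <- cfg$protocol$choice_ms
  if (is.null(da_duration)) da_duration <- cfg$gating$da_duration
  filt <- competitive_filter(current, other)
  cm <- conflict_monitor(model, filt)
  if (all(filt == 0)) {
    return(structure(list(pathway = NA_character_, t1 = 0L, t2 = 0L,
                          pi = NA_real_, subtrial_choices = integer(0),
                          latencies = numeric(0), undecided = TRUE,
                          n_undecided = NA_integer_,
                          s1 = attr(cm, "s1"), s2 = attr(cm, "s2")),
                     class = "decision_outcome"))
  }
  if (pathway == "auto") pathway <- as.character(cm)
  syns <- assemble_synapses(model, "choice")
  da_ext <- no_da_ext()
  if (pathway == "nonlinear" && model$da_on)
    da_ext <- list(pop = unname(POP[["da"]]), current = cfg$gating$da_drive,
                   t_on = 0, t_off = da_duration)
  readout <- if (pathway == "nonlinear") POP[["mbon"]] else POP[["cc_out"]]
  res <- run_network(model, syns, cfg$input_gain * filt, duration,
                     readout = readout, reset_every = cfg$protocol$subtrial_ms,
                     da_ext = da_ext)
  choices <- res$sub_choice
  und <- is.na(choices)
  choices[und] <- sample(1:2, sum(und), replace = TRUE)
  t1 <- sum(choices == 1L); t2 <- sum(choices == 2L)
  structure(list(pathway = pathway, t1 = t1, t2 = t2,
                 pi = preference_index(t1, t2),
                 subtrial_choices = choices, latencies = res$sub_time,
                 undecided = FALSE, n_undecided = sum(und),
                 s1 = attr(cm, "s1"), s2 = attr(cm, "s2")),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  if (isTRUE(x$undecided)) {
    cat("<decision_outcome> undecided (filtered input empty)\n")
    return(invisible(x))
  }
  cat("<decision_outcome>", x$pathway, "pathway: t1 =", x$t1, ", t2 =", x$t2,
      ", PI =", round(x$pi, 3), "\n")
  if (x$n_undecided > 0)
    cat("  (", x$n_undecided, "sub-trials undecided, resolved at random )\n")
  invisible(x)
}

#' Serialise a decision outcome to JSON
#'
#' @param x a \code{decision_outcome}
#' @param path optional file; if \code{NULL} the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
outcome_json <- function(x, path = NULL) {
  j <- jsonlite::toJSON(list(pathway = x$pathway, t1 = x$t1, t2 = x$t2,
                             pi = x$pi, subtrial_choices = x$subtrial_choices),
                        auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}

#' Choice-phase prediction for a trained circuit
#'
#' \code{predict} on a trained model runs [choose()] on a stimulus pair.
#'
#' @param object a [decision_circuit()]
#' @param current,other stimulus pair
#' @param ... passed to [choose()]
#' @return a \code{decision_outcome}
#' @export
predict.decision_circuit <- function(object, current, other, ...) {
  choose(object, current, other, ...)
}

#' Per-cue choice probabilities from spike counts
#'
#' \eqn{p_i = t_i / \sum_j t_j}, where \eqn{t_i} is the spike count of cue
#' \eqn{i} in the Kenyon-cell layer (nonlinear circuit) or the
#' central-complex input layer (linear circuit).
#'
#' @param spike_counts non-negative counts, at least one positive
#' @return probability vector summing to 1, order preserved
#' @export
#' @examples
#' cue_probabilities(c(30, 10))  # 0.75 0.25
cue_probabilities <- function(spike_counts) {
  stopifnot(all(spike_counts >= 0))
  tot <- sum(spike_counts)
  if (tot == 0) stop("all-zero spike counts")
  spike_counts / tot
}

#' Per-cue spike counts under a gating variant
#'
#' Drives an n-cue model with normalised saliencies and counts the spikes of
#' each cue's channel over a continuous window: in the central-complex input
#' layer for the linear variant, in the Kenyon-cell layer for the only-APL
#' and full nonlinear (DA-GABA-MB) variants. Under the nonlinear variant the
#' dopamine window first lets the salient cue through and potentiates its
#' relay, then APL feedback suppresses the weaker cues, amplifying the
#' count ratio relative to the linear pass-through.
#'
#' Each repetition starts from fresh synapses and random sub-threshold
#' initial membrane potentials; counts are summed across repetitions. The
#' jitter removes the spurious phase locking between Kenyon cells and the
#' APL oscillator that a fully synchronised start would produce, so the
#' expected counts vary monotonically with cue saliency.
#'
#' @param model a [decision_circuit()] with \code{n_channels = length(cues)}
#' @param cues saliencies in \code{[1, 20]} (see [normalize_cues()])
#' @param window ms of simulation per repetition (default 500)
#' @param variant \code{"linear"}, \code{"only-APL"} or \code{"nonlinear"}
#' @param da_duration dopamine window, ms (nonlinear variant)
#' @param reps repetitions averaged over (each with fresh phase jitter)
#' @return integer vector of per-cue spike counts, summed over \code{reps}
#' @export
gain_gate <- function(model, cues, window = 500,
                      variant = c("nonlinear", "only-APL", "linear"),
                      da_duration = NULL, reps = 30) {
  variant <- match.arg(variant)
  stopifnot(length(cues) == model$n, all(cues >= 0))
  cfg <- model$config
  if (is.null(da_duration)) da_duration <- cfg$gating$da_duration
  m <- variant_gating(model, variant)
  syns <- assemble_synapses(m, "choice")
  da_ext <- no_da_ext()
  if (variant == "nonlinear")
    da_ext <- list(pop = unname(POP[["da"]]), current = cfg$gating$da_drive,
                   t_on = 0, t_off = da_duration)
  layer <- if (variant == "linear") "cc_in" else "kc"
  total <- integer(model$n)
  for (r in seq_len(reps)) {
    res <- run_network(m, syns, cfg$input_gain * cues, window,
                       da_ext = da_ext,
                       v0 = jitter_v0(m$n, cfg$lif$v_th))
    total <- total + res$counts[[layer]]
  }
  total
}
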