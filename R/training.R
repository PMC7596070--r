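#' Apply the phasic-dopamine punishment depression to the memory weights
#'
#' When a punishment event is live, every weight from a currently active
#' input channel to the chosen behaviour is depressed, in both the
#' central-complex and mushroom-body memory matrices, by
#' \eqn{DA(t)\,dt/\tau_t} per step while \eqn{DA(t)} exceeds
#' \code{cutoff * DA_peak}. The cumulative depression is therefore
#' \eqn{\approx DA_{peak}} independently of the step size. The compiled
#' engine applies the per-step rule during a run; this function applies the
#' remaining cumulative depression analytically from time \code{t} until the
#' trace falls below the cutoff (used when a punishment lands at the end of
#' an episode), clipping at the weight bounds.
#'
#' @param model a [decision_circuit()]
#' @param trace a list with \code{t_pun}, \code{da_peak}, \code{tau_t} (see
#'   [da_level()]), or \code{NULL} for no live punishment
#' @param active_inputs indices of the input channels active under the
#'   current filtered stimulus
#' @param chosen_behavior 1 or 2
#' @param t current time, ms (\code{>= trace$t_pun})
#' @return the model with updated memory weights
#' @export
punish_update <- function(model, trace, active_inputs, chosen_behavior, t) {
  if (is.null(trace)) return(model)
  stopifnot(chosen_behavior %in% 1:2, t >= trace$t_pun)
  cutoff <- model$config$da$cutoff
  # remaining integral of DA(s)/tau_t from t to the cutoff time
  lvl <- da_level(t, trace$t_pun, trace$da_peak, trace$tau_t)
  dec <- max(lvl - cutoff * trace$da_peak, 0)
  wmin <- model$config$weights$min
  for (field in c("W_cc", "W_mb")) {
    w <- model[[field]]
    w[active_inputs, chosen_behavior] <-
      pmax(w[active_inputs, chosen_behavior] - dec, wmin)
    model[[field]] <- w
  }
  model
}

#' Run one 1-second training episode on a single pattern
#'
#' The filtered stimulus drives the training network (no DA-APL loop, no
#' conflict monitor); the first output spike fixes the chosen behaviour.
#' Punishment fires when behaviour 1 is chosen under the punishment-related
#' pattern or behaviour 2 under the safe pattern, starting a phasic dopamine
#' trace that depresses the weights from the active input channels to the
#' chosen output neuron. STDP shapes the memory matrix throughout the
#' episode; the mushroom-body matrix is kept identical to the
#' central-complex matrix, as the two pathways undergo the same training.
#' If no output spike occurs the behaviour is drawn uniformly at random and
#' realised as a single exploratory output spike at episode end, to which
#' STDP and the punishment rule apply as usual. A punished episode ends with
#' the avoidance response: the agent performs the alternative behaviour, and
#' STDP pairs that motor spike with the active inputs, so the alternative
#' memory column is potentiated and the next encounter is decided correctly
#' (this is what bounds reversal learning at one punished episode per
#' pattern per contingency).
#'
#' @param model a [decision_circuit()]
#' @param pattern the presented [encode_pattern()] pattern (or channel
#'   vector)
#' @param other the competing pattern, used only for competitive filtering
#' @param punished logical: is \code{pattern} the punishment-related one?
#' @return list with \code{model} (updated) and \code{episode} (a one-row
#'   data frame: chosen behaviour, whether punishment was applied,
#'   \code{t_pun}, post-episode weight sums \code{s1}, \code{s2} over the
#'   active channels, decided flag)
#' @export
train_pattern <- function(model, pattern, other, punished) {
  stopifnot(inherits(model, "decision_circuit"))
  cfg <- model$config
  filt <- competitive_filter(pattern, other)
  active <- which(filt > 0)
  syns <- assemble_synapses(model, "training")
  syns$mb_mem$plastic <- FALSE   # MB matrix mirrors the CC matrix (copied below)
  pun <- list(enabled = TRUE,
              on_choice = c(punished, !punished),
              da_peak = cfg$da$peak, tau_t = cfg$da$tau_t,
              cutoff = cfg$da$cutoff,
              mem_syns = which(names(syns) == "cc_mem"),
              active_pre = as.integer(active))
  res <- run_network(model, syns, cfg$input_gain * filt,
                     duration = cfg$protocol$episode_ms,
                     readout = POP[["cc_out"]], punish = pun)
  dn <- dimnames(model$W_cc)
  model$W_cc <- res$W$cc_mem
  dimnames(model$W_cc) <- dn
  chosen <- res$first_choice
  decided <- !is.na(chosen)
  pun_applied <- isTRUE(res$punished)
  t_pun <- res$t_pun

  if (!decided) {
    chosen <- sample(1:2, 1)
    # exploratory output spike at episode end: pair with the most recent
    # presynaptic spikes of the active channels, then the punishment rule
    last <- res$last_spike$cc_in[active]
    seen <- last >= 0
    if (any(seen)) {
      dw <- stdp_delta(cfg$protocol$episode_ms - last[seen],
                       cfg = structure(cfg$stdp, class = "stdp_config"))
      w <- model$W_cc
      w[active[seen], chosen] <- pmin(w[active[seen], chosen] + dw,
                                      cfg$weights$max)
      model$W_cc <- w
    }
    if ((punished && chosen == 1) || (!punished && chosen == 2)) {
      t_pun <- cfg$protocol$episode_ms
      trace <- list(t_pun = t_pun, da_peak = cfg$da$peak,
                    tau_t = cfg$da$tau_t)
      model$W_mb <- model$W_cc
      model <- punish_update(model, trace, active, chosen, t_pun)
      pun_applied <- TRUE
    }
  }
  # punishment evokes the avoidance action: the agent performs the
  # alternative behaviour for the rest of the episode, and STDP pairs that
  # motor spike with the still-active input channels, so the alternative
  # column gains weight and the very next episode is decided correctly
  if (pun_applied) {
    alt <- 3L - chosen
    last <- res$last_spike$cc_in[active]
    seen <- last >= 0
    if (any(seen)) {
      dw <- stdp_delta(cfg$protocol$episode_ms - last[seen],
                       cfg = structure(cfg$stdp, class = "stdp_config"))
      w <- model$W_cc
      w[active[seen], alt] <- pmin(w[active[seen], alt] + dw,
                                   cfg$weights$max)
      model$W_cc <- w
    }
  }
  model$W_mb <- model$W_cc
  pat_name <- if (inherits(pattern, "visual_pattern")) pattern$name else "cue"
  episode <- data.frame(pattern = pat_name, chosen = chosen,
                        punished_pattern = punished,
                        punishment_applied = pun_applied,
                        t_pun = if (is.null(t_pun)) NA_real_ else t_pun,
                        decided = decided,
                        s1 = sum(model$W_cc[active, 1]),
                        s2 = sum(model$W_cc[active, 2]))
  list(model = model, episode = episode)
}

#' Train the two-pattern conditioning task
#'
#' Alternates 1-second training episodes on the safe and punished patterns.
#' One epoch (2 s total) normally suffices: each pattern is learned within at
#' most one punished episode, after which the correct behaviour is chosen.
#'
#' @param model a [decision_circuit()]
#' @param safe,punished the safe and punishment-related patterns
#' @param epochs number of alternating presentations of the pair (default 1;
#'   0 returns the model unchanged)
#' @return the trained model, with the episode log in \code{model$log}
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' m <- train_task(decision_circuit(),
#'                 safe = encode_pattern("green", "upright"),
#'                 punished = encode_pattern("blue", "inverted"))
#' summary(m)
#' }
train_task <- function(model, safe, punished, epochs = 1) {
  stopifnot(epochs >= 0)
  log <- model$log
  for (e in seq_len(epochs)) {
    a <- train_pattern(model, safe, punished, punished = FALSE)
    model <- a$model
    b <- train_pattern(model, punished, safe, punished = TRUE)
    model <- b$model
    log <- rbind(log, cbind(epoch = e, rbind(a$episode, b$episode)))
  }
  if (epochs > 0) model$trained <- TRUE
  model$log <- log
  model
}
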