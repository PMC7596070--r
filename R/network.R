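# Low-level bridge between the model object and the compiled clock-driven
# engine. Population order is fixed: 1 visual, 2 CC input, 3 CC output,
# 4 KC, 5 MBON, 6 APL, 7 DA. Synapse lists carry names so trained weight
# matrices can be read back by role rather than by position.

POP <- c(visual = 1L, cc_in = 2L, cc_out = 3L, kc = 4L, mbon = 5L,
         apl = 6L, da = 7L)

make_pops <- function(n, visual_ext, v0 = NULL) {
  sizes <- c(n, n, 2L, n, 2L, 2L, 1L)
  wta <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  lapply(seq_along(sizes), function(p) {
    ext <- numeric(sizes[p])
    if (p == POP[["visual"]]) ext <- visual_ext
    pop <- list(n = sizes[p], ext = ext, wta = wta[p])
    if (!is.null(v0)) pop$v0 <- v0[[p]]
    pop
  })
}

# random sub-threshold initial potentials, one value per neuron; breaks the
# spurious phase locking a fully synchronised all-zero start produces
jitter_v0 <- function(n, v_th) {
  sizes <- c(n, n, 2L, n, 2L, 2L, 1L)
  lapply(sizes, function(s) stats::runif(s, 0, v_th))
}

# mask marks where synapses exist; zero-mask entries carry no charge and are
# never touched by STDP (a masked-out entry is "no synapse", not weight 0)
syn <- function(pre, post, W, sign, plastic, wmin, wmax,
                mask = matrix(1, nrow(W), ncol(W))) {
  list(pre = unname(POP[[pre]]), post = unname(POP[[post]]),
       W = W, mask = mask, sign = sign, plastic = plastic,
       wmin = wmin, wmax = wmax)
}

# Assemble the synapse list for one phase. The training network has no
# DA-APL loop and no conflict monitor; the choice network adds the gating
# connections, freezes the two memory matrices, and runs STDP on the gating
# synapses (visual->KC, APL->KC, APL->DA, DA->MBON).
assemble_synapses <- function(model, phase = c("training", "choice")) {
  phase <- match.arg(phase)
  w <- model$config$weights
  n <- model$n
  mem_plastic <- phase == "training"
  off2 <- matrix(c(0, w$mutual, w$mutual, 0), 2, 2)
  eye <- diag(1, n)
  syns <- list(
    vis_cc  = syn("visual", "cc_in", diag(w$relay, n), 1, FALSE, w$min, w$max,
                  mask = eye),
    cc_mem  = syn("cc_in", "cc_out", model$W_cc, 1, mem_plastic, w$min, w$max),
    cc_inh  = syn("cc_out", "cc_out", off2, -1, FALSE, w$min, w$max,
                  mask = 1 - diag(1, 2)),
    vis_kc  = syn("visual", "kc", diag(w$relay, n), 1, phase == "choice",
                  w$min, w$max, mask = eye),
    mb_mem  = syn("kc", "mbon", model$W_mb, 1, mem_plastic, w$min, w$max),
    mb_inh  = syn("mbon", "mbon", off2, -1, FALSE, w$min, w$max,
                  mask = 1 - diag(1, 2)))
  if (phase == "choice") {
    gat <- list(
      kc_apl  = syn("kc", "apl", matrix(w$kc_apl, n, 2), 1, FALSE, w$min, w$max),
      # APL->KC plasticity is dopamine-gated: without the DA neuron the
      # inhibition is a fixed uniform gain control (the only-APL ablation)
      apl_kc  = syn("apl", "kc", matrix(w$apl_kc, 2, n), -1, model$da_on,
                    w$min, w$max),
      da_apl  = syn("da", "apl", matrix(w$da_apl, 1, 2), -1, FALSE, w$min, w$max),
      apl_da  = syn("apl", "da", matrix(w$apl_da, 2, 1), -1, TRUE, w$min, w$max),
      # DA->MBON is kept fixed: its phasic drive must tie the two MBONs
      # symmetrically while dopamine is active, and STDP here would lock
      # the whole choice phase onto whichever MBON won the first race
      da_mbon = syn("da", "mbon", matrix(w$da_mbon, 1, 2), 1, FALSE,
                    w$min, w$max))
    if (!model$da_on)  gat[c("da_apl", "da_mbon")] <- NULL
    if (!model$apl_on) gat[c("apl_kc", "apl_da")]  <- NULL
    syns <- c(syns, gat)
  }
  syns
}

no_punish <- function() {
  list(enabled = FALSE, on_choice = c(FALSE, FALSE), da_peak = 10, tau_t = 2,
       cutoff = 0.01, mem_syns = integer(0), active_pre = integer(0))
}

no_da_ext <- function() list(pop = 0L, current = 0, t_on = 0, t_off = 0)

# Single entry point to the compiled engine.
run_network <- function(model, syns, visual_ext, duration,
                        readout = 0L, reset_every = 0,
                        da_ext = no_da_ext(), punish = no_punish(),
                        record = FALSE, v0 = NULL) {
  pops <- make_pops(model$n, visual_ext, v0)
  res <- .engine_run(pops, unname(syns), duration, model$config$protocol$dt,
                     model$config$lif, model$config$stdp,
                     as.integer(readout), reset_every, da_ext, punish, record)
  names(res$W) <- names(syns)
  names(res$counts) <- names(POP)
  names(res$last_spike) <- names(POP)
  res
}

#' Run a free simulation and collect the spike record
#'
#' Simulates the assembled network (training- or choice-phase wiring) for a
#' given duration under a fixed stimulus and returns every spike as a data
#' frame, one row per spike, sorted by time then population.
#'
#' @param model a [decision_circuit()] model
#' @param current,other the attended and competing [encode_pattern()]
#'   patterns (or raw channel vectors); \code{other} defaults to no
#'   competition
#' @param duration simulated time, ms
#' @param phase \code{"training"} or \code{"choice"} wiring
#' @param da_window ms of external dopamine drive at onset (choice phase
#'   only; default taken from the model config)
#' @param seed optional RNG seed for reproducibility
#' @return data frame with columns \code{time_ms}, \code{population},
#'   \code{neuron_id}, of class \code{spike_record}
#' @export
spike_record <- function(model, current, other = numeric(5), duration = 500,
                         phase = c("choice", "training"),
                         da_window = NULL, seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  filt <- competitive_filter(current, other)
  syns <- assemble_synapses(model, phase)
  da_ext <- no_da_ext()
  if (phase == "choice" && model$da_on) {
    if (is.null(da_window)) da_window <- model$config$gating$da_duration
    da_ext <- list(pop = unname(POP[["da"]]),
                   current = model$config$gating$da_drive,
                   t_on = 0, t_off = da_window)
  }
  res <- run_network(model, syns, model$config$input_gain * filt, duration,
                     da_ext = da_ext, record = TRUE)
  out <- data.frame(time_ms = res$spikes$time_ms,
                    population = names(POP)[res$spikes$pop],
                    neuron_id = res$spikes$neuron_id)
  out <- out[order(out$time_ms, out$population, out$neuron_id), ]
  rownames(out) <- NULL
  class(out) <- c("spike_record", "data.frame")
  out
}

#' Write a spike record to CSV
#'
#' @param x a \code{spike_record} data frame
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_spike_record <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
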