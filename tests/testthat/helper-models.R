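# Shared trained models, built once per test run. Training is deterministic
# up to the RNG draws inside the episodes, so each cached model is built
# under a fixed seed.
.model_cache <- new.env(parent = emptyenv())

trained_model <- function(ci = 1, seed = 42) {
  key <- paste0("ci", ci, "_s", seed)
  if (is.null(.model_cache[[key]])) {
    set.seed(seed)
    .model_cache[[key]] <- train_task(
      decision_circuit(),
      safe = encode_pattern("green", "upright", ci = ci),
      punished = encode_pattern("blue", "inverted", ci = ci))
  }
  .model_cache[[key]]
}

# first-spike time of a single LIF neuron under constant current, by Euler
euler_first_spike <- function(I, dt, cfg = lif_config(), t_max = 100) {
  v <- 0
  for (k in seq_len(ceiling(t_max / dt))) {
    s <- lif_step(v, I, cfg, dt)
    v <- s$v
    if (s$spiked) return(k * dt)
  }
  Inf
}
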