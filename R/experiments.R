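# Named, seeded reproductions of the published experiments. Each experiment
# is a pure function of (config, seed); run_experiment() dispatches by name
# and optionally writes CSV + JSON summary + log to an output directory.

EXPERIMENTS <- c("single_cue", "two_cue", "ci_shape_sweep", "ci_color_sweep",
                 "conflict_sweep", "ablation_da_apl", "da_duration_sweep",
                 "spike_train_compare", "reversal", "window_task",
                 "obstacle_task")

# standard two-cue conditioning at a given colour intensity
train_two_cue <- function(ci = 1, config = default_config()) {
  train_task(decision_circuit(5, config),
             safe = encode_pattern("green", "upright", ci),
             punished = encode_pattern("blue", "inverted", ci))
}

# reversed-cue conflict test (shape and colour predict opposite behaviours)
conflict_test <- function(model, ci, pathway = "auto", da_duration = NULL) {
  choose(model,
         current = encode_pattern("blue", "upright", ci),
         other = encode_pattern("green", "inverted", ci),
         pathway = pathway, da_duration = da_duration)
}

exp_single_cue <- function(config) {
  safe <- encode_pattern("green", "upright")
  pun <- encode_pattern("blue", "upright")
  m <- train_task(decision_circuit(5, config), safe = safe, punished = pun)
  res <- list(safe = choose(m, safe, pun), punished = choose(m, pun, safe))
  data <- data.frame(current = c(safe$name, pun$name),
                     t1 = vapply(res, `[[`, integer(1), "t1"),
                     t2 = vapply(res, `[[`, integer(1), "t2"),
                     pi = vapply(res, `[[`, numeric(1), "pi"),
                     row.names = NULL)
  list(data = data,
       summary = list(pi_safe = data$pi[1], pi_punished = data$pi[2]))
}

exp_two_cue <- function(config) {
  m <- train_two_cue(1, config)
  tests <- list(
    trained_pair = list(encode_pattern("green", "upright"),
                        encode_pattern("blue", "inverted")),
    color = list(encode_pattern("green", "upright"),
                 encode_pattern("blue", "upright")),
    shape = list(encode_pattern("white", "upright"),
                 encode_pattern("white", "inverted")))
  rows <- lapply(names(tests), function(nm) {
    o <- choose(m, tests[[nm]][[1]], tests[[nm]][[2]])
    data.frame(test = nm, current = tests[[nm]][[1]]$name,
               t1 = o$t1, t2 = o$t2, pi = o$pi)
  })
  data <- do.call(rbind, rows)
  list(data = data, summary = as.list(stats::setNames(data$pi, data$test)))
}

ci_sweep <- function(config, cue = c("shape", "color"), grid = seq(0, 1, 0.1)) {
  cue <- match.arg(cue)
  rows <- lapply(grid, function(ci) {
    m <- train_two_cue(ci, config)
    o <- if (cue == "shape") {
      choose(m, encode_pattern("white", "upright"),
             encode_pattern("white", "inverted"))
    } else {
      choose(m, encode_pattern("green", "upright", ci),
             encode_pattern("blue", "upright", ci))
    }
    data.frame(ci = ci, t1 = o$t1, t2 = o$t2,
               pi = if (o$undecided) NA_real_ else o$pi)
  })
  data <- do.call(rbind, rows)
  list(data = data,
       summary = list(cue = cue, pi_min = min(data$pi, na.rm = TRUE),
                      pi_max = max(data$pi, na.rm = TRUE)))
}

exp_conflict_sweep <- function(config, grid = seq(0.1, 2, 0.1)) {
  trained <- train_two_cue(0.8, config)
  naive <- decision_circuit(5, config)
  data <- do.call(rbind, lapply(grid, function(ci) {
    data.frame(ci = ci,
               pi_linear = conflict_test(trained, ci, "linear")$pi,
               pi_nonlinear = conflict_test(trained, ci, "nonlinear")$pi,
               pi_untrained = conflict_test(naive, ci)$pi)
  }))
  # curve-shape property: logistic midpoint slope of the nonlinear sweep vs
  # straight-line slope of the linear sweep (both on the PI scale)
  p01 <- (1 - data$pi_nonlinear) / 2   # falling curve mapped to [0, 1]
  fit_log <- suppressWarnings(
    stats::glm(p01 ~ ci, data = data, family = stats::quasibinomial()))
  slope_nl <- abs(stats::coef(fit_log)[["ci"]]) / 4 * 2
  slope_li <- abs(stats::coef(stats::lm(pi_linear ~ ci, data = data))[["ci"]])
  list(data = data,
       summary = list(pi_untrained_mean = mean(data$pi_untrained),
                      logistic_mid_slope_nonlinear = slope_nl,
                      line_slope_linear = slope_li,
                      sigmoid_steeper = slope_nl > slope_li))
}

exp_ablation <- function(config, grid = seq(0.1, 2, 0.1)) {
  trained <- train_two_cue(0.8, config)
  variants <- c("nonlinear", "only-APL", "none")
  data <- do.call(rbind, lapply(grid, function(ci) {
    pis <- vapply(variants, function(v)
      conflict_test(variant_gating(trained, v), ci, "nonlinear")$pi,
      numeric(1))
    data.frame(ci = ci, pi_linear = conflict_test(trained, ci, "linear")$pi,
               pi_full = pis[["nonlinear"]],
               pi_only_apl = pis[["only-APL"]], pi_none = pis[["none"]])
  }))
  counts <- lapply(c(nonlinear = "nonlinear", `only-APL` = "only-APL",
                     linear = "linear"), function(v)
    gain_gate(decision_circuit(2, config), normalize_cues(c(10, 9)),
              variant = v))
  ratio <- function(ct) ct[1] / max(ct[2], 1L)
  list(data = data,
       summary = list(
         none_matches_linear_rmse =
           sqrt(mean((data$pi_none - data$pi_linear)^2)),
         counts = counts,
         ratio_linear = ratio(counts$linear),
         ratio_only_apl = ratio(counts$`only-APL`),
         ratio_nonlinear = ratio(counts$nonlinear)))
}

exp_da_duration <- function(config, durations = c(10, 70, 100, 300, 1000),
                            grid = seq(0.1, 2, 0.1)) {
  trained <- train_two_cue(0.8, config)
  data <- do.call(rbind, lapply(durations, function(d)
    do.call(rbind, lapply(grid, function(ci)
      data.frame(da_duration = d, ci = ci,
                 pi = conflict_test(trained, ci, "nonlinear",
                                    da_duration = d)$pi)))))
  # decision quality: mean |PI| away from the CI = 1 crossover
  away <- abs(data$ci - 1) >= 0.3
  q <- tapply(abs(data$pi[away]), data$da_duration[away], mean)
  mid <- names(q) %in% c("70", "100")
  list(data = data,
       summary = list(quality = as.list(q),
                      quality_mid = mean(q[mid]),
                      quality_extreme = mean(q[!mid]),
                      mid_exceeds_extreme = mean(q[mid]) > mean(q[!mid])))
}

exp_spike_trains <- function(config, cues = c(10, 9), window = 500) {
  m <- decision_circuit(length(cues), config)
  p <- normalize_cues(cues)
  variants <- c(linear = "linear", `only-APL` = "only-APL",
                nonlinear = "nonlinear")
  data <- do.call(rbind, lapply(names(variants), function(v) {
    ct <- gain_gate(m, p, window = window, variant = variants[[v]])
    data.frame(variant = v, cue = seq_along(cues), saliency = p, count = ct)
  }))
  wide <- split(data$count, data$variant)
  list(data = data,
       summary = list(saliencies = p,
                      ratio = lapply(wide, function(ct) ct[1] / max(ct[2], 1L))))
}

exp_reversal <- function(config) {
  r <- run_reversal(decision_circuit(5, config))
  agg <- tapply(r$counts$incorrect, r$counts$block, max)
  list(data = r$counts,
       summary = list(max_incorrect_initial = unname(agg[1]),
                      max_incorrect_reversals = max(agg[-1])))
}

exp_window <- function(config) {
  m <- decision_circuit(2, config)
  rows <- lapply(c("nonlinear", "linear", "uniform"), function(pol) {
    s <- simulate_window(pol, model = if (pol == "uniform") NULL else m)
    data.frame(policy = pol, mean_steps = as.numeric(s))
  })
  data <- do.call(rbind, rows)
  list(data = data,
       summary = as.list(stats::setNames(data$mean_steps, data$policy)))
}

exp_obstacle <- function(config, scene = c(3, 5, 9, 7)) {
  m <- decision_circuit(4, config)
  variants <- c("nonlinear", "only-APL", "linear")
  data <- do.call(rbind, lapply(variants, function(v) {
    p <- simulate_obstacle(scene, variant = v, model = m)
    data.frame(variant = v, action = seq_along(scene), distance = scene,
               probability = p)
  }))
  pmax_by <- tapply(data$probability, data$variant, max)
  list(data = data,
       summary = list(scene = scene,
                      p_max = as.list(pmax_by),
                      best_action_is_farthest = all(tapply(
                        seq_len(nrow(data)), data$variant, function(i)
                          data$action[i][which.max(data$probability[i])] ==
                            which.max(scene)))))
}

#' Run a named experiment
#'
#' Reproduces one of the published protocols, seeded and config-driven.
#' Valid names: \code{single_cue}, \code{two_cue}, \code{ci_shape_sweep},
#' \code{ci_color_sweep}, \code{conflict_sweep}, \code{ablation_da_apl},
#' \code{da_duration_sweep}, \code{spike_train_compare}, \code{reversal},
#' \code{window_task}, \code{obstacle_task}. Re-running with the same name,
#' seed and config reproduces identical results (and files).
#'
#' @param name experiment name (see above)
#' @param seed RNG seed; all stochasticity derives from it
#' @param out_dir optional directory; when given, writes
#'   \code{<name>.csv} (raw curve/table), \code{<name>_summary.json} and
#'   \code{<name>.log}
#' @param config a [default_config()] list
#' @param ... experiment-specific overrides (e.g. \code{grid}, \code{scene},
#'   \code{durations}, \code{cues})
#' @return list with \code{name}, \code{seed}, \code{data} (data frame),
#'   \code{summary} (list) and, if written, \code{files}
#' @export
#' @examples
#' \donttest{
#' r <- run_experiment("single_cue", seed = 1)
#' r$summary
#' }
run_experiment <- function(name, seed = 1, out_dir = NULL,
                           config = default_config(), ...) {
  if (length(name) != 1 || !name %in% EXPERIMENTS)
    stop("unknown experiment name: ", paste(name, collapse = ", "),
         "\nvalid names: ", paste(EXPERIMENTS, collapse = ", "))
  set.seed(seed)
  res <- switch(name,
                single_cue = exp_single_cue(config),
                two_cue = exp_two_cue(config),
                ci_shape_sweep = ci_sweep(config, "shape", ...),
                ci_color_sweep = ci_sweep(config, "color", ...),
                conflict_sweep = exp_conflict_sweep(config, ...),
                ablation_da_apl = exp_ablation(config, ...),
                da_duration_sweep = exp_da_duration(config, ...),
                spike_train_compare = exp_spike_trains(config, ...),
                reversal = exp_reversal(config),
                window_task = exp_window(config),
                obstacle_task = exp_obstacle(config, ...))
  out <- list(name = name, seed = seed, data = res$data,
              summary = res$summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(out_dir, paste0(name, c(".csv", "_summary.json",
                                               ".log")))
    utils::write.csv(res$data, files[1], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(c(list(schema = "drosdecide-summary-1",
                                experiment = name, seed = seed),
                           res$summary),
                         files[2], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    writeLines(c(paste("experiment:", name), paste("seed:", seed),
                 paste("rows:", nrow(res$data)),
                 paste("summary keys:",
                       paste(names(res$summary), collapse = ", "))),
               files[3])
    out$files <- files
  }
  out
}

#' Generate the task fixtures
#'
#' Writes small CSV fixtures: the visual pattern library at a few colour
#' intensities, window-task cue pairs with their normalised saliencies, and
#' obstacle scenes. Deterministic given the seed.
#'
#' @param seed RNG seed (used for the sampled obstacle scenes)
#' @param dir output directory (created if needed)
#' @return character vector of the written file paths
#' @export
generate_fixtures <- function(seed = 1, dir = "fixtures") {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- do.call(rbind, lapply(c(0.5, 0.8, 1), function(ci) {
    pats <- pattern_library(ci)
    do.call(rbind, lapply(pats, function(p)
      data.frame(ci = ci, name = p$name, t(as_channels(p)))))
  }))
  f1 <- file.path(dir, "patterns.csv")
  utils::write.csv(lib, f1, row.names = FALSE, quote = FALSE)

  d <- expand.grid(d1 = 1:4, d2 = 1:4)
  d <- d[d$d1 >= d$d2, ]
  norm <- t(apply(d, 1, function(r) normalize_cues(as.numeric(r))))
  f2 <- file.path(dir, "window_cues.csv")
  utils::write.csv(cbind(d, p1 = norm[, 1], p2 = norm[, 2]), f2,
                   row.names = FALSE, quote = FALSE)

  scenes <- t(replicate(8, sample(2:9, 4)))
  colnames(scenes) <- c("left", "up", "right", "down")
  f3 <- file.path(dir, "obstacle_scenes.csv")
  utils::write.csv(data.frame(scene = seq_len(nrow(scenes)), scenes), f3,
                   row.names = FALSE, quote = FALSE)
  c(f1, f2, f3)
}
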