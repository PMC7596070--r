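# Desk-scale surrogates for the agent tasks: a window-crossing grid with two
# conflicting distance cues, a four-cue obstacle scene, and the online
# reversal-learning loop.

#' Window-crossing grid task
#'
#' The agent starts in a corner of a square grid and must reach the centre.
#' The remaining horizontal and vertical distances are the two conflicting
#' cues; at every step with both axes live, the axis to move along is drawn
#' with the policy's cue probabilities (uniform: 0.5/0.5; linear/nonlinear:
#' [cue_probabilities()] over [gain_gate()] counts of the normalised cues)
#' and the agent moves one cell toward the goal along it. With one axis
#' exhausted movement is deterministic along the other.
#'
#' @param policy \code{"nonlinear"}, \code{"linear"} or \code{"uniform"}
#' @param start corner name (\code{"upper-left"}, \code{"upper-right"},
#'   \code{"lower-left"}, \code{"lower-right"}) or a length-2 integer
#'   position
#' @param trials number of repetitions averaged (default 16)
#' @param grid odd grid side length (default 9, goal at the centre)
#' @param model optional 2-channel [decision_circuit()]; built if missing
#' @return mean steps to goal over the trials, with the per-trial step
#'   counts as attribute \code{"steps"}
#' @export
simulate_window <- function(policy = c("nonlinear", "linear", "uniform"),
                            start = "upper-left", trials = 16, grid = 9,
                            model = NULL) {
  policy <- match.arg(policy)
  stopifnot(trials >= 1, grid >= 3, grid %% 2 == 1)
  goal <- c((grid + 1) / 2, (grid + 1) / 2)
  if (is.character(start)) {
    start <- switch(start,
                    "upper-left" = c(1, 1), "upper-right" = c(grid, 1),
                    "lower-left" = c(1, grid), "lower-right" = c(grid, grid),
                    stop("unknown start corner: ", start))
  }
  stopifnot(length(start) == 2, all(start >= 1), all(start <= grid))
  if (policy != "uniform" && is.null(model)) model <- decision_circuit(2)
  cache <- new.env(parent = emptyenv())
  axis_prob <- function(d) {
    if (policy == "uniform") return(c(0.5, 0.5))
    key <- paste(d, collapse = "_")
    if (is.null(cache[[key]])) {
      counts <- gain_gate(model, normalize_cues(d),
                          variant = if (policy == "nonlinear") "nonlinear"
                                    else "linear")
      cache[[key]] <- cue_probabilities(counts)
    }
    cache[[key]]
  }
  steps <- vapply(seq_len(trials), function(trial) {
    pos <- start; k <- 0
    while (any(pos != goal)) {
      d <- abs(pos - goal)
      axis <- if (all(d > 0)) {
        if (stats::runif(1) < axis_prob(d)[1]) 1 else 2
      } else which(d > 0)
      pos[axis] <- pos[axis] + sign(goal[axis] - pos[axis])
      k <- k + 1
    }
    k
  }, numeric(1))
  structure(mean(steps), steps = steps)
}

#' Obstacle-avoidance action probabilities
#'
#' Four distances (left, up, right, down) from the obstacle centre to the
#' borders of the field of view are the four conflicting cues. They are
#' normalised to the input range, passed through the selected circuit
#' variant, and the per-cue spike counts converted to choice probabilities.
#' A single-shot probability computation: the avoidance direction with the
#' largest remaining distance should receive the largest probability, and
#' the full DA-GABA-MB variant sharpens that maximum most.
#'
#' @param scene positive distances \code{c(d1, d2, d3, d4)}
#' @param variant \code{"linear"}, \code{"only-APL"} or \code{"nonlinear"}
#' @param model optional 4-channel [decision_circuit()]
#' @return probability vector over the four avoidance actions
#' @export
simulate_obstacle <- function(scene,
                              variant = c("nonlinear", "only-APL", "linear"),
                              model = NULL) {
  variant <- match.arg(variant)
  stopifnot(length(scene) == 4, all(scene > 0))
  if (is.null(model)) model <- decision_circuit(4)
  cue_probabilities(gain_gate(model, normalize_cues(scene), variant = variant))
}

#' Online reversal learning
#'
#' Runs a sequence of contingency blocks. Within each block the two patterns
#' are presented alternately as online training episodes (plasticity live
#' throughout); a pattern counts as learned once its correct behaviour has
#' been chosen twice consecutively, and the block ends when both patterns
#' are learned. Incorrect choices (the punished ones) are counted per
#' pattern per block.
#'
#' @param model a [decision_circuit()] (untrained: block 1 is the initial
#'   reinforcement learning)
#' @param protocol list of blocks, each \code{list(punished = <1 or 2>)}
#'   naming which of the two patterns carries punishment in that block;
#'   consecutive blocks must differ. Default: initial learning plus two
#'   reversals.
#' @param patterns list of the two patterns (default upright-green T and
#'   inverted-blue T)
#' @param max_episodes safety cap on presentations per pattern per block
#' @return list with \code{counts} (data frame: block, pattern, incorrect)
#'   and \code{model} (final state)
#' @export
run_reversal <- function(model,
                         protocol = list(list(punished = 2),
                                         list(punished = 1),
                                         list(punished = 2)),
                         patterns = list(encode_pattern("green", "upright"),
                                         encode_pattern("blue", "inverted")),
                         max_episodes = 25) {
  pun_idx <- vapply(protocol, `[[`, numeric(1), "punished")
  if (any(diff(pun_idx) == 0))
    stop("consecutive blocks must differ in contingency")
  rows <- list()
  for (b in seq_along(protocol)) {
    punished <- pun_idx[b]
    incorrect <- c(0L, 0L)
    streak <- c(0L, 0L)
    ep <- 0L
    while (any(streak < 2) && ep < 2 * max_episodes) {
      p <- ep %% 2 + 1            # alternate the two patterns
      ep <- ep + 1L
      if (streak[p] >= 2) next    # this pattern already learned
      fit <- train_pattern(model, patterns[[p]], patterns[[3 - p]],
                           punished = (p == punished))
      model <- fit$model
      correct <- if (p == punished) 2L else 1L
      if (fit$episode$chosen == correct) {
        streak[p] <- streak[p] + 1L
      } else {
        streak[p] <- 0L
        incorrect[p] <- incorrect[p] + 1L
      }
    }
    rows[[b]] <- data.frame(block = b, pattern = c(1L, 2L),
                            punished_pattern = punished,
                            incorrect = incorrect)
  }
  model$trained <- TRUE
  list(counts = do.call(rbind, rows), model = model)
}
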