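#' Encode a visual pattern as a 5-channel saliency vector
#'
#' Patterns are represented by five input neurons: the first three carry the
#' R, G, B colour channels, the last two the upright / inverted T shape cue.
#' The base saliency of an active channel is 10; the colour channels are
#' scaled by the colour intensity \code{ci}, so an upright green T at
#' \code{ci = 0.8} is \code{[0, 8, 0, 10, 0]}. White activates all three
#' colour channels equally.
#'
#' @param color one of \code{"green"}, \code{"blue"}, \code{"white"},
#'   \code{"none"}
#' @param shape one of \code{"upright"}, \code{"inverted"}, \code{"none"}
#' @param ci colour intensity scalar, \code{>= 0} (default 1); values above 1
#'   make the colour cue more salient than the shape cue
#' @return an object of class \code{visual_pattern}: a list with \code{name},
#'   \code{channels} (length-5 numeric, ordered R, G, B, upright, inverted)
#'   and \code{ci}
#' @export
#' @examples
#' encode_pattern("green", "upright")$channels        # 0 10 0 10 0
#' encode_pattern("blue", "inverted")$channels        # 0 0 10 0 10
encode_pattern <- function(color = c("green", "blue", "white", "none"),
                           shape = c("upright", "inverted", "none"),
                           ci = 1) {
  color <- match.arg(color)
  shape <- match.arg(shape)
  stopifnot(is.numeric(ci), length(ci) == 1, ci >= 0)
  ch <- numeric(5)
  names(ch) <- c("R", "G", "B", "upright", "inverted")
  ch[switch(color, green = "G", blue = "B", white = c("R", "G", "B"),
            none = character(0))] <- 10 * ci
  ch[switch(shape, upright = "upright", inverted = "inverted",
            none = character(0))] <- 10
  name <- paste0(if (shape != "none") paste0(shape, "-") else "",
                 if (color != "none") paste0(color, "-") else "", "T")
  structure(list(name = name, channels = ch, ci = ci),
            class = "visual_pattern")
}

#' @export
print.visual_pattern <- function(x, ...) {
  cat("<visual_pattern>", x$name, ": [",
      paste(format(x$channels, trim = TRUE), collapse = ", "),
      "] (ci =", x$ci, ")\n")
  invisible(x)
}

as_channels <- function(x) {
  if (inherits(x, "visual_pattern")) x$channels
  else { stopifnot(is.numeric(x), length(x) == 5); x }
}

#' Competitive filtering between two simultaneously presented patterns
#'
#' The pattern not currently attended inhibits the current input channel by
#' channel; the result is the rectified difference
#' \code{max(current - other, 0)}. Channels shared by both patterns (e.g. the
#' white colour of an upright-white vs inverted-white pair) cancel exactly,
#' so only the discriminating cue reaches the decision circuits.
#'
#' @param current the attended [encode_pattern()] pattern (or raw 5-vector)
#' @param other the competing pattern
#' @return filtered length-5 numeric vector
#' @export
#' @examples
#' competitive_filter(encode_pattern("white", "upright"),
#'                    encode_pattern("white", "inverted"))  # shape cue only
competitive_filter <- function(current, other) {
  pmax(as_channels(current) - as_channels(other), 0)
}

#' Normalise raw cue magnitudes to the network input range
#'
#' Maps non-negative cue values (distances, in the agent tasks) onto the
#' saliency range the input neurons expect, \code{[1, 20]}, by
#' \code{1 + 19 * x / max(x)}. Order is preserved; an all-equal input maps to
#' all 20.
#'
#' @param raw numeric vector of non-negative cue magnitudes, at least one
#'   positive
#' @return numeric vector of saliencies in \code{[1, 20]}
#' @export
#' @examples
#' normalize_cues(c(0, 5, 10))  # 1, 10.5, 20
normalize_cues <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1, all(raw >= 0))
  if (all(raw == 0)) stop("all-zero cue vector cannot be normalised")
  1 + 19 * raw / max(raw)
}

#' Named pattern library
#'
#' The stimuli used by the conditioning experiments, addressable by name
#' (e.g. \code{"upright-green-T"}).
#'
#' @param ci colour intensity applied to the colour channels
#' @return named list of [encode_pattern()] objects
#' @export
pattern_library <- function(ci = 1) {
  combos <- expand.grid(shape = c("upright", "inverted"),
                        color = c("green", "blue", "white"),
                        stringsAsFactors = FALSE)
  pats <- lapply(seq_len(nrow(combos)), function(i)
    encode_pattern(combos$color[i], combos$shape[i], ci))
  names(pats) <- vapply(pats, `[[`, "", "name")
  pats
}
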