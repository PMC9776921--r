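# shared internal helpers

#' Derive a reproducible stage seed from a global seed and a tag
#'
#' Stages of the pipeline draw their own seeds deterministically from one
#' global seed so that any stage can be rerun in isolation with identical
#' results. The derived seed always fits in a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param tag character tag naming the consumer (e.g. `"cohort1"`, `"mdc"`).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(tag), length(tag) == 1L)
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) * 2654435761
  as.integer((abs(seed) * 7919 + h) %% 2147483629) + 1L
}

# stop() with sprintf formatting, no call in message
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

# competition ("1224") ranking of values, largest first
.competition_rank <- function(x) {
  vapply(x, function(v) 1L + sum(x > v), integer(1))
}
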