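#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"), which does not
#' reproduce conventionally rounded table cells (e.g. 90.65 -> 90.7) or split
#' sizes (92.5 -> 93). This helper always rounds halves up (away from zero for
#' positive input), with a small epsilon guard against binary representation
#' of decimal halves.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(92.5)      # 93
#' round_half_up(90.65, 1)  # 90.7
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Derive a named seed substream from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through named
#' substreams, so that any stage can be reproduced in isolation and stages do
#' not perturb each other's random state.
#'
#' @param seed master integer seed.
#' @param name character stream name, e.g. `"split"`, `"expand-1"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
seed_substream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  codes <- as.numeric(utf8ToInt(name))
  h <- sum(codes * seq_along(codes) * 7919) %% 2147483646
  as.integer((abs(seed) + h) %% 2147483646)
}

## run code under a seeded, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## sample() without its n==1 surprise: draws `size` elements from vector x
sample_ids <- function(x, size) {
  stopifnot(size <= length(x))
  x[sample.int(length(x), size)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## validation-error constructor used across modules (exit code 2 in the CLI)
qc_error <- function(msg, class = "qsarcocktail_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

qc_log <- function(...) {
  if (isTRUE(getOption("qsarcocktail.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(...))
}
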