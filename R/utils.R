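#' @importFrom rlang .data abort %||%
#' @importFrom stats predict rnorm setNames
#' @importFrom utils head
NULL

# Deterministic fan-out of one user-facing seed into per-stage seeds.
# Lehmer-style step keeps every derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(as.double(seed)) * 48271 + 1000003 * as.double(stage)) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

parse_error <- function(message, ...) {
  abort(message, class = "rosetta_parse_error", ...)
}

violation <- function(rule, where, message) {
  tibble::tibble(rule = rule, where = where, message = message)
}

no_violations <- function() {
  tibble::tibble(rule = character(), where = character(), message = character())
}
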