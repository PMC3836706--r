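#' Derive a stream of child seeds from a master seed
#'
#' Deterministically expands one integer seed into `n` independent child
#' seeds, so that nested generators (per subject, per frame, per replicate)
#' can each be seeded reproducibly without sharing a stream. All child seeds
#' fit in a 32-bit signed integer.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
seed_stream <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_design_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("design_infeasible", "error")))
}
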