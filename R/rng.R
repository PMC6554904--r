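# Seed plumbing. A single root seed is mixed with a stage label to give each
# pipeline stage (cases, controls, events, mortality, ...) its own independent
# stream, so adding or reordering a downstream stage never perturbs the draws
# of an earlier one. All randomness in the package flows through with_seed(),
# which restores the caller's RNG state on exit: no hidden global state.

stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(stage)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
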