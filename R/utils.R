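# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed fan-out from one master seed, kept inside
# 32-bit integer range so stages can be rerun independently.
derive_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, render = 2L, localize = 3L, track = 4L,
              analyze = 5L, spatial = 6L, summarize = 7L)
  idx <- if (is.character(stage)) stages[[stage]] else as.integer(stage)
  as.integer((as.double(seed) * 48271 + idx * 104729) %% 2147483647)
}
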