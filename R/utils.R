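# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic derived seeds (kept below 2^31)
derive_seed <- function(seed, offset) (as.integer(seed) + 104729L * as.integer(offset)) %% 2147480017L

stop_inconsistent <- function(msg) {
  stop(structure(class = c("cvdbn_inconsistent_evidence", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
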