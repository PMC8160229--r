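# Internal helpers: seed derivation and scoped RNG.

# Deterministic integer hash of a seed plus context tokens, kept below 2^31
# so it is always a valid `set.seed()` argument.  Characters contribute via
# their UTF-8 code points.
derive_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(paste(p, collapse = ""))) else as.numeric(p)
  }))
  h <- 11
  for (p in parts) h <- (h * 31 + p + 17) %% 2147483629
  as.integer(h + 1)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
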