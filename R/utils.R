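# Internal helpers: deterministic child seeds and scoped RNG use.

# Deterministic 31-bit child seed from a master seed and a component tag.
# Keeps independent streams for collection / expression / clinical / qMSP
# generation so regenerating one component never perturbs another.
child_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- as.double(master %% 2147483647L)
  for (k in utf8ToInt(tag)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
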