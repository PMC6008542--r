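#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded helpers do not perturb each other.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible substream seed (< 2^31) from a master seed and any
# number of string/numeric keys. Simple FNV-style mixing; collisions are
# harmless (streams merely coincide) but practically absent at our scales.
mix_seed <- function(master, ...) {
  keys <- unlist(lapply(list(...), function(k) {
    if (is.character(k)) utf8ToInt(paste(k, collapse = "/")) else as.numeric(k)
  }))
  # multiplier kept small so h * mult + k stays exactly representable in a
  # double (max ~1.5e14 < 2^53)
  h <- (as.numeric(master) %% 2147483629) + 1
  for (k in keys) h <- (h * 69069 + (as.numeric(k) %% 2147483629)) %% 2147483629
  as.integer(h %% 2147483587 + 1)
}

# Short stable hex digest of a serialized R object (used to version run
# output directories without external digest dependencies).
tiny_digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 216613626
  for (b in bytes) h <- (h * 69069 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
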