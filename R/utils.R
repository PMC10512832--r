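# Internal helpers: scoped RNG, canonical config keys, in-memory caches.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a label, staying inside 32-bit range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

# Canonical key for one design point: exact for integers, porosity printed to
# full precision so distinct phi never collide.
config_key <- function(c, phi, m, n, l, R = NULL) {
  base <- sprintf("c%d|phi%.10g|m%d|n%d|l%d", as.integer(c), phi,
                  as.integer(m), as.integer(n), as.integer(l))
  if (is.null(R)) base else paste0(base, "|R", as.integer(R))
}

new_cache <- function() new.env(parent = emptyenv())

cache_get <- function(cache, key) {
  if (is.null(cache)) return(NULL)
  if (exists(key, envir = cache, inherits = FALSE)) get(key, envir = cache) else NULL
}

cache_set <- function(cache, key, value) {
  if (!is.null(cache)) assign(key, value, envir = cache)
  invisible(value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
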