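# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(structure(
    class = c("dfc_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_degenerate <- function(...) {
  stop(structure(
    class = c("dfc_degenerate_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid(name, " must be a single integer >= ", min, " (got ", deparse(x), ")")
  }
  as.integer(x)
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_invalid(name, " must be a single finite number in [", lower, ", ", upper, "]")
  }
  as.numeric(x)
}

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state more than once.  Counter scheme: seeds are drawn as a
# block from the master-seeded generator; values stay below 2^31.
derive_seeds <- function(master_seed, n) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Polynomial rolling hash over the serialized object; cheap content
# fingerprint for provenance headers (not cryptographic).
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  # skip the serialization header (R version stamp) so the hash reflects
  # content only
  if (length(bytes) > 14L) bytes <- bytes[-seq_len(14L)]
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483629
  sprintf("%08x", h)
}
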