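# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators do not perturb the session stream.
# seed = NULL runs expr against the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

# Deterministic zero-padded identifiers: id_seq("u", 3) -> u1..u3 style with
# fixed width so lexical and numeric orders agree.
id_seq <- function(prefix, n) {
  if (n == 0L) return(character(0))
  sprintf(paste0(prefix, "%0", max(3L, nchar(n)), "d"), seq_len(n))
}

# Sample k distinct elements from pool (k may be 0); errors if k > pool size.
sample_distinct <- function(pool, k, what = "species") {
  stop_if(k > length(pool),
          "requested ", k, " distinct ", what, " but pool has only ",
          length(pool))
  if (k == 0L) return(pool[0])
  pool[sample.int(length(pool), k)]
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

# Multiplicative string hash (31-bit); used for provenance stamps without
# an external digest dependency.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 216613626
  for (b in bytes) h <- (h * 16777619 + b) %% 2147483647
  sprintf("%08x", h)
}
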