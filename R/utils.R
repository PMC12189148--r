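# dB <-> linear energy helpers; the level floor stands in for -Inf.

db_to_energy <- function(db) 10^(db / 10)

energy_to_db <- function(e, floor_db = -100) {
  out <- rep(floor_db, length(e))
  pos <- e > 0
  out[pos] <- pmax(10 * log10(e[pos]), floor_db)
  if (is.matrix(e)) out <- matrix(out, nrow(e), ncol(e))
  out
}

stop_input <- function(msg, ...) abort(msg, class = "soniscape_error_input", ...)
stop_config <- function(msg, ...) abort(msg, class = "soniscape_error_config", ...)
stop_io <- function(msg, ...) abort(msg, class = "soniscape_error_io", ...)
stop_index <- function(msg, ...) abort(msg, class = "soniscape_error_index", ...)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-component seed from a base seed, kept within 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647L)
}

# Row-wise maximum over a set of matrix columns.
row_max <- function(m, cols) {
  if (length(cols) == 1L) return(m[, cols])
  do.call(pmax, lapply(cols, function(j) m[, j]))
}
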