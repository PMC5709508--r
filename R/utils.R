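# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-hair substream seed below 2^31, derived from a base
# seed and hair id so replicate results are independent of growth order.
substream_seed <- function(base_seed, hair_id) {
  (as.numeric(base_seed) * 7919 + as.numeric(hair_id) * 104729) %% 2147483647
}

# round half up (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}
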