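`%||%` <- function(a, b) if (is.null(a)) b else a

input_error <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("truncph_input_error", "error"),
                      call = call))
}

## log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  lo <- x <= 0
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
  out
}

## Run expr without disturbing the caller's RNG stream.
with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## Sum `val` into an accumulator of length `len` at (possibly repeated) `idx`;
## idx == 0 entries are dropped.
index_sum <- function(idx, val, len) {
  keep <- idx >= 1L
  out <- numeric(len)
  if (!any(keep)) return(out)
  s <- rowsum(val[keep], idx[keep])
  out[as.integer(rownames(s))] <- s
  out
}

## For each grid index k, the sum of v_i over subjects whose index range
## [a_i, b_i] covers k (a_i <= b_i assumed).
range_sum <- function(a, b, v, K) {
  d <- index_sum(a, v, K + 1L) - index_sum(pmin(b + 1L, K + 1L), v, K + 1L)
  cumsum(d)[seq_len(K)]
}
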