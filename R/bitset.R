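## Bit-packed genome sets.
##
## The miner spends almost all of its time intersecting genome sets and
## counting their sizes, so literal columns are packed 31 genomes per
## integer word (31, not 32, keeps every word a valid non-negative R
## integer).  Intersection is a vectorised bitwAnd over the words and
## cardinality a 16-bit popcount table lookup.

.bit_cache <- new.env(parent = emptyenv())

popcount16_table <- function() {
  if (is.null(.bit_cache$pc16)) {
    v <- 0:65535
    pc <- integer(65536L)
    for (k in 0:15) pc <- pc + bitwAnd(bitwShiftR(v, k), 1L)
    .bit_cache$pc16 <- pc
  }
  .bit_cache$pc16
}

## 0/1 matrix (n x L) -> integer word matrix (ceiling(n/31) x L)
pack_columns <- function(mat) {
  n <- nrow(mat)
  W <- (n + 30L) %/% 31L
  word <- rep(seq_len(W), each = 31L)[seq_len(n)]
  pow <- 2^((seq_len(n) - 1L) %% 31L)
  packed <- rowsum(mat * pow, word, reorder = TRUE)
  storage.mode(packed) <- "integer"
  dimnames(packed) <- list(NULL, colnames(mat))
  packed
}

popcount_words <- function(words) {
  pc <- popcount16_table()
  sum(pc[bitwAnd(words, 65535L) + 1L] + pc[bitwShiftR(words, 16L) + 1L])
}
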