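# Independent scoring oracle: an explicit transition-table automaton over
# match positions, built by enumerating the reset-then-retest rule, and
# scanned column-wise across many padded key strings at once. Shares no
# code with the package's on-line matcher.

oracle_build_dfa <- function(pattern, alphabet = 1:4) {
  L <- length(pattern)
  nxt <- matrix(0L, nrow = L, ncol = length(alphabet))
  wrap <- matrix(0L, nrow = L, ncol = length(alphabet))
  for (s in 0:(L - 1)) {
    for (ai in seq_along(alphabet)) {
      a <- alphabet[ai]
      if (a == pattern[s + 1]) {
        if (s + 1 == L) {
          nxt[s + 1, ai] <- 0L
          wrap[s + 1, ai] <- 1L
        } else {
          nxt[s + 1, ai] <- s + 1L
        }
      } else if (a == pattern[1]) {
        nxt[s + 1, ai] <- 1L
      } else {
        nxt[s + 1, ai] <- 0L
      }
    }
  }
  list(nxt = nxt, wrap = wrap, alphabet = alphabet)
}

# keymat: n x maxlen matrix of key indices into the alphabet, NA-padded
oracle_score_matrix <- function(keymat, pattern, alphabet = 1:4) {
  dfa <- oracle_build_dfa(pattern, alphabet)
  n <- nrow(keymat)
  state <- rep(1L, n)  # row index = match position + 1
  wraps <- integer(n)
  for (j in seq_len(ncol(keymat))) {
    k <- keymat[, j]
    ok <- !is.na(k)
    if (!any(ok)) next
    idx <- cbind(state[ok], match(k[ok], alphabet))
    wraps[ok] <- wraps[ok] + dfa$wrap[idx]
    state[ok] <- dfa$nxt[idx] + 1L
  }
  list(complete = wraps, partial = state - 1L)
}

oracle_score_one <- function(keys, pattern, alphabet = 1:4) {
  r <- oracle_score_matrix(matrix(keys, nrow = 1), pattern, alphabet)
  list(complete = r$complete[1], partial = r$partial[1],
       correct = r$complete[1] * length(pattern) + r$partial[1])
}

# random key strings padded into a matrix
random_key_matrix <- function(n, max_len, alphabet = 1:4) {
  lens <- sample.int(max_len, n, replace = TRUE)
  keymat <- matrix(NA_integer_, nrow = n, ncol = max_len)
  keys <- sample(alphabet, sum(lens), replace = TRUE)
  off <- 0L
  for (i in seq_len(n)) {
    keymat[i, seq_len(lens[i])] <- keys[(off + 1L):(off + lens[i])]
    off <- off + lens[i]
  }
  keymat
}
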