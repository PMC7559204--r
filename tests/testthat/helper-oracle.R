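# Independent oracles used to freeze expected values.

# Direct memoized recursion of the edit-distance recursion: base case
# max(i, j) when min(i, j) = 0, unit substitution cost when characters
# differ. Kept deliberately naive and separate from the package's dynamic
# programme.
lev_recursive <- function(a, b) {
  ai <- utf8ToInt(a)
  bi <- utf8ToInt(b)
  memo <- array(NA_integer_, dim = c(length(ai) + 1L, length(bi) + 1L))
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (min(i, j) == 0L) {
      max(i, j)
    } else {
      min(rec(i - 1L, j) + 1L,
          rec(i, j - 1L) + 1L,
          rec(i - 1L, j - 1L) + (ai[i] != bi[j]))
    }
    memo[i + 1L, j + 1L] <<- as.integer(v)
    v
  }
  rec(length(ai), length(bi))
}

# all strings of length 0..maxlen over an alphabet
all_strings <- function(alphabet, maxlen) {
  unlist(lapply(0:maxlen, function(n) {
    if (n == 0L) return("")
    apply(expand.grid(rep(list(alphabet), n)), 1L, paste, collapse = "")
  }), use.names = FALSE)
}

rand_string <- function(maxlen = 12L, alphabet = letters[1:6]) {
  n <- sample(0:maxlen, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
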