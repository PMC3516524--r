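# Internal helpers shared across modules.

# Deterministic substream seed derivation: a Lehmer-style mix of a master
# seed with integer keys. Stays below 2^31-1 so it is always a valid
# set.seed() argument. Keys are combined in order, so mix_seed(s, a, b)
# and mix_seed(s, b, a) differ.
mix_seed <- function(seed, ...) {
  k <- (as.double(seed) %% 2147483647) + 1
  for (x in c(...)) {
    k <- (k * 48271 + as.double(x) + 1) %% 2147483647
  }
  as.integer(k)
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

# All permutations of 1..k as a matrix (k! rows). Only sensible for small k;
# callers guard against large k.
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    shifted <- sub
    shifted[shifted >= i] <- shifted[shifted >= i] + 1L
    out[[i]] <- cbind(rep(i, nrow(sub)), shifted)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
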