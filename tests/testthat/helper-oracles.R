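# Independent oracles used by the unit and acceptance tests.  These
# deliberately avoid the package's own algorithms: structures are
# enumerated and scored at the leaves, tail sums use closed forms or
# direct summation, and combinatorial probabilities use choose().

# Exhaustive minimum-free-energy oracle: enumerate every nested
# structure (min hairpin loop 3) by backtracking and score each pair
# set from scratch against the stacking table.
brute_force_mfe <- function(seq) {
  codes <- mirflow:::seq_to_codes(seq)
  n <- length(codes)
  pairable <- function(a, b) mirflow:::.PAIR_INDEX[a, b] > 0L
  score <- function(pairs) {
    e <- 0
    for (i in seq_len(n)) {
      j <- pairs[i]
      if (j <= i) next
      if (i + 1L <= n && pairs[i + 1L] == j - 1L && j - 1L > i + 1L) {
        p1 <- mirflow:::.PAIR_INDEX[codes[i], codes[j]]
        p2 <- mirflow:::.PAIR_INDEX[codes[i + 1L], codes[j - 1L]]
        e <- e + mirflow:::.STACK_ENERGY[p1, p2]
      }
    }
    e
  }
  best <- 0
  pairs <- integer(n)
  rec <- function(stack) {
    if (!length(stack)) {
      e <- score(pairs)
      if (e < best) best <<- e
      return(invisible())
    }
    iv <- stack[[1L]]
    rest <- stack[-1L]
    i <- iv[1L]; j <- iv[2L]
    if (i > j) {
      rec(rest)
      return(invisible())
    }
    rec(c(list(c(i + 1L, j)), rest))
    if (j >= i + 4L) {
      for (k in (i + 4L):j) {
        if (!pairable(codes[i], codes[k])) next
        pairs[i] <<- k; pairs[k] <<- i
        rec(c(list(c(i + 1L, k - 1L)), list(c(k + 1L, j)), rest))
        pairs[i] <<- 0L; pairs[k] <<- 0L
      }
    }
  }
  rec(list(c(1L, n)))
  best
}

# Duplex energy oracle: enumerate every ungapped antiparallel offset
# and, within it, every subset of pairable positions; score stacks
# between adjacent chosen positions.  Exponential, for short inputs.
brute_force_duplex <- function(mirna, site) {
  a <- mirflow:::seq_to_codes(mirna)
  b <- rev(mirflow:::seq_to_codes(site))
  la <- length(a); lb <- length(b)
  best <- 0
  for (off in (-(la - 1L)):(lb - 1L)) {
    is <- max(1L, 1L - off):min(la, lb - off)
    if (length(is) < 2L) next
    q <- mirflow:::.PAIR_INDEX[cbind(a[is], b[is + off])]
    pp <- which(q > 0L)
    if (length(pp) < 2L) next
    for (mask in 0:(2^length(pp) - 1L)) {
      chosen <- pp[bitwAnd(mask, 2^(seq_along(pp) - 1L)) > 0L]
      if (length(chosen) < 2L) next
      e <- 0
      for (t in chosen) {
        if ((t + 1L) %in% chosen)
          e <- e + mirflow:::.STACK_ENERGY[q[t], q[t + 1L]]
      }
      if (e < best) best <- e
    }
  }
  best
}

# Direct-summation oracle for the two-library count test: terms built
# by the multiplicative recurrence p(k+1) = p(k) r (x+k+1)/(k+1), with
# the smaller tail accumulated termwise.
ac_oracle <- function(x, y, N1, N2) {
  r <- N2 / N1
  p0 <- (1 + r)^(-(x + 1))
  terms <- numeric(0)
  pk <- p0
  # run well past both the observed count and the distribution mode
  kmax <- max(2000L, as.integer(20 * (x + y + 10)),
              as.integer(3 * (x + 1) * max(r, 1)) + 50L)
  for (k in 0:kmax) {
    terms[k + 1L] <- pk
    pk <- pk * (r / (1 + r)) * (x + k + 1) / (k + 1)
    if (k > y && pk < terms[y + 1L] * 1e-18 &&
        pk < max(terms) * 1e-30) break
  }
  lower <- sum(terms[seq_len(min(y + 1L, length(terms)))])
  upper <- sum(terms[(y + 1L):length(terms)])
  min(1, 2 * min(lower, upper))
}

# Combinatorial oracle for the hypergeometric upper tail.
hyper_oracle <- function(N, n, M, m) {
  if (m == 0) return(1)
  k <- m:min(n, M)
  sum(choose(M, k) * choose(N - M, n - k)) / choose(N, n)
}

# Closed-form stacking energy of a full perfect helix (all consecutive
# stacks of the perfect duplex), used for perfect-complement checks.
perfect_helix_energy <- function(mirna) {
  a <- mirflow:::seq_to_codes(mirna)
  n <- length(a)
  comp <- c(4L, 3L, 2L, 1L)
  q <- mirflow:::.PAIR_INDEX[cbind(a, comp[a])]
  sum(mirflow:::.STACK_ENERGY[cbind(q[-n], q[-1L])])
}

rand_nt <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
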