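# Independent brute-force oracles for the exact tail statistics; no lchoose,
# no distribution functions, so they share no code path with the package.

# binomial pmf by repeated multiplication, upper tail by direct summation
binom_tail_bruteforce <- function(k, n, p0) {
  pmf <- numeric(n + 1)
  pmf[1] <- (1 - p0)^n
  if (n > 0) {
    r <- p0 / (1 - p0)
    for (j in 0:(n - 1)) pmf[j + 2] <- pmf[j + 1] * (n - j) / (j + 1) * r
  }
  sum(pmf[(k + 1):(n + 1)])
}

# binomial coefficient as a direct factorial-ratio product
choose_prod <- function(a, b) {
  if (b == 0) return(1)
  prod((a - b + 1):a / seq_len(b))
}

hyper_tail_enum <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j)
    choose_prod(K, j) * choose_prod(N - K, n - j) / choose_prod(N, n),
    numeric(1)))
}
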