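# Independent exact-rational oracle for the hypergeometric tests.
#
# Probabilities of 2x2 tables with fixed margins are ratios of products of
# binomial coefficients. Binomials up to N = 60 exceed double-precision
# integers (choose(60,30) ~ 1.2e17), so they are built exactly with a
# small base-1e7 big-integer arithmetic (Pascal's triangle), the per-table
# numerators num_k = C(m1,k) * C(N-m1, m2-k) are exact integer products,
# and only the final ratio num/denominator is converted to double. The
# oracle never calls dhyper() or any package code.

bi_from_num <- function(n) {
  stopifnot(n >= 0, n == floor(n), n < 2^53)
  if (n == 0) return(0)
  limbs <- numeric(0)
  while (n > 0) {
    limbs <- c(limbs, n %% 1e7)
    n <- n %/% 1e7
  }
  limbs
}

bi_add <- function(a, b) {
  k <- max(length(a), length(b))
  a <- c(a, numeric(k - length(a)))
  b <- c(b, numeric(k - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(k)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e7
    s[i] <- s[i] %% 1e7
  }
  while (carry > 0) {
    s <- c(s, carry %% 1e7)
    carry <- carry %/% 1e7
  }
  while (length(s) > 1 && s[length(s)] == 0) s <- s[-length(s)]
  s
}

bi_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    prod <- a[i] * b            # each term < 1e7 * 1e7 = 1e14 < 2^53
    for (j in seq_along(b)) {
      pos <- i + j - 1
      out[pos] <- out[pos] + prod[j]
      # normalize eagerly so accumulations stay below 2^53
      if (out[pos] >= 9e15) {
        out[pos + 1] <- out[pos + 1] + out[pos] %/% 1e7
        out[pos] <- out[pos] %% 1e7
      }
    }
  }
  carry <- 0
  for (i in seq_along(out)) {
    out[i] <- out[i] + carry
    carry <- out[i] %/% 1e7
    out[i] <- out[i] %% 1e7
  }
  stopifnot(carry == 0)
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

bi_to_num <- function(a) sum(a * 1e7^(seq_along(a) - 1))

# Pascal's triangle of exact binomials up to n_max, memoized per session.
.binom_env <- new.env(parent = emptyenv())
big_binomials <- function(n_max) {
  key <- as.character(n_max)
  if (!is.null(.binom_env[[key]])) return(.binom_env[[key]])
  tri <- vector("list", n_max + 1L)
  tri[[1L]] <- list(1)                      # C(0, 0)
  for (n in seq_len(n_max)) {
    prev <- tri[[n]]
    row <- vector("list", n + 1L)
    row[[1L]] <- 1
    row[[n + 1L]] <- 1
    if (n >= 2) for (k in 2:n)
      row[[k]] <- bi_add(prev[[k - 1L]], prev[[k]])
    tri[[n + 1L]] <- row
  }
  .binom_env[[key]] <- tri
  tri
}

big_choose <- function(tri, n, k) tri[[n + 1L]][[k + 1L]]

# Exact numerators num_k = C(m1, k) * C(N - m1, m2 - k) over the support,
# converted to double only at the end (relative error ~1e-16 per value).
oracle_numerators <- function(N, m1, m2, tri = big_binomials(N)) {
  lo <- max(0L, m2 - (N - m1))
  hi <- min(m1, m2)
  ks <- lo:hi
  num <- vapply(ks, function(k)
    bi_to_num(bi_mul(big_choose(tri, m1, k),
                     big_choose(tri, N - m1, m2 - k))), numeric(1))
  list(k = ks, num = num, denom = bi_to_num(big_choose(tri, N, m2)))
}

# Mid-p lower tail on the both-mutated count.
oracle_midp <- function(N, m1, m2, b, tri = big_binomials(N)) {
  en <- oracle_numerators(N, m1, m2, tri)
  (sum(en$num[en$k < b]) + 0.5 * en$num[en$k == b]) / en$denom
}

# Two-sided Fisher: sum of probabilities of tables no more likely than the
# observed, ties included up to a relative error of 1e-7 (the convention
# the implementation follows).
oracle_fisher <- function(a, b, c, d, tri = NULL) {
  N <- a + b + c + d
  if (is.null(tri)) tri <- big_binomials(N)
  en <- oracle_numerators(N, a + b, a + c, tri)
  obs <- en$num[en$k == a]
  min(1, sum(en$num[en$num <= obs * (1 + 1e-7)]) / en$denom)
}
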