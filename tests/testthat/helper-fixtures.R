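# shared in-code fixtures

# canonical background spectrum for n = 10 used throughout the examples
tiny_G <- function() folded_sfs(c(0.5, 0.3, 0.1, 0.06, 0.04), 10L)

make_records <- function(position, x, n = 10L) {
  data.frame(position = as.integer(position), x = as.integer(x),
             n = as.integer(n), folded = TRUE)
}

# draw m folded classes i.i.d. from a folded_sfs
draw_classes <- function(G, m) {
  sample.int(length(G$G), m, replace = TRUE, prob = G$G)
}

# exhaustive subset-enumeration projection oracle: expected unfolded
# spectrum of a subsample of size j, averaging over all C(n, j) subsets of
# a sample whose derived count is distributed as p over 0..n
project_oracle <- function(p, j) {
  n <- length(p) - 1L
  out <- numeric(j + 1L)
  subsets <- utils::combn(n, j)
  for (k in 0:n) {
    if (p[k + 1L] == 0) next
    # derived lineages are 1..k WLOG (exchangeability)
    for (s in seq_len(ncol(subsets))) {
      a <- sum(subsets[, s] <= k)
      out[a + 1L] <- out[a + 1L] + p[k + 1L] / ncol(subsets)
    }
  }
  out
}

# brute-force sweep-spectrum oracle: sums over escape count e, ancestral
# derived count a (from the enumeration-based projection) and the identity
# of the swept-class ancestor, then folds and conditions on polymorphism
sweep_spectrum_oracle <- function(G, p_e) {
  n <- G$n
  sym <- symmetrize_spectrum(G)
  out <- numeric(n + 1L)
  for (e in 0:n) {
    we <- choose(n, e) * p_e^e * (1 - p_e)^(n - e)
    if (we == 0) next
    if (e == n) {
      out <- out + we * sym
      next
    }
    j <- e + 1L
    P <- project_oracle(sym, j)
    for (a in 0:j) {
      if (P[a + 1L] == 0) next
      # each of the j ancestral lineages is equally likely to be the one
      # subtending the swept class
      for (anc_derived in c(TRUE, FALSE)) {
        pr <- if (anc_derived) a / j else 1 - a / j
        if (pr == 0) next
        obs <- if (anc_derived) a - 1L + (n - e) else a
        out[obs + 1L] <- out[obs + 1L] + we * P[a + 1L] * pr
      }
    }
  }
  K <- n %/% 2L
  folded <- numeric(K)
  for (k in 0:n) {
    f <- min(k, n - k)
    if (f >= 1L) folded[f] <- folded[f] + out[k + 1L]
  }
  folded / sum(folded)
}
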