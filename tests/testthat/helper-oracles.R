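# independent oracles: brute-force / enumeration implementations kept
# deliberately separate from the package code paths they check

# HWE exact p-value by direct enumeration: weight each heterozygote count
# by its multinomial coefficient times 2^het, normalize, and sum the
# probabilities no larger than the observed one
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_alt <- n_Aa + 2 * n_aa
  if (n_alt == 0 || n_alt == 2 * n) return(1.0)
  hets <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  logw <- vapply(hets, function(h) {
    aa <- (n_alt - h) / 2
    AA <- n - h - aa
    lchoose(n, AA) + lchoose(n - AA, h) + h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs + 1e-12])
}

# all compositions of `total` into `k` non-negative parts
compositions <- function(total, k) {
  if (k == 1) return(matrix(total, ncol = 1))
  out <- list()
  for (first in 0:total) {
    rest <- compositions(total - first, k - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# log-likelihood of unphased genotype data at given haplotype frequencies;
# haps: 0/1 matrix (n_haps x L), freqs parallel; g: dosage matrix
genotype_loglik <- function(g, haps, freqs) {
  ll <- 0
  for (s in seq_len(nrow(g))) {
    p_s <- 0
    for (i in seq_len(nrow(haps))) {
      for (j in i:nrow(haps)) {
        if (all(haps[i, ] + haps[j, ] == g[s, ])) {
          p_s <- p_s + (if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j])
        }
      }
    }
    if (p_s <= 0) return(-Inf)
    ll <- ll + log(p_s)
  }
  ll
}

# best log-likelihood over an exhaustive simplex grid with `steps`
# subdivisions (frequencies are multiples of 1/steps)
grid_best_loglik <- function(g, steps) {
  L <- ncol(g)
  haps <- as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE]
  # vectorized: genotype class probability per sample via pair table
  n_h <- nrow(haps)
  pairs <- which(upper.tri(matrix(0, n_h, n_h), diag = TRUE), arr.ind = TRUE)
  key <- apply(g, 1, paste, collapse = ",")
  pair_key <- apply(haps[pairs[, 1], , drop = FALSE] +
                      haps[pairs[, 2], , drop = FALSE], 1, paste,
                    collapse = ",")
  grid <- compositions(steps, n_h) / steps
  best <- -Inf
  counts <- table(key)
  for (r in seq_len(nrow(grid))) {
    f <- grid[r, ]
    w <- ifelse(pairs[, 1] == pairs[, 2],
                f[pairs[, 1]]^2, 2 * f[pairs[, 1]] * f[pairs[, 2]])
    class_p <- tapply(w, pair_key, sum)
    p_obs <- class_p[names(counts)]
    if (any(is.na(p_obs)) || any(p_obs <= 0)) next
    ll <- sum(counts * log(p_obs))
    if (ll > best) best <- ll
  }
  best
}

# brute-force four-gamete partitioner: checks every contiguous run for
# validity (all pairs < 4 gametes) and takes the longest valid run at each
# left endpoint, scanning left to right
fgt_brute_partition <- function(pass_matrix) {
  m <- nrow(pass_matrix)
  valid_run <- function(s, e) {
    if (e == s) return(TRUE)
    for (i in s:(e - 1)) for (j in (i + 1):e) {
      if (!pass_matrix[i, j]) return(FALSE)
    }
    TRUE
  }
  blocks <- list()
  s <- 1
  while (s <= m) {
    e_best <- s
    for (e in s:m) if (valid_run(s, e)) e_best <- e
    # runs are hereditary: any extension failure is final, but check all
    if (e_best > s) blocks[[length(blocks) + 1]] <- s:e_best
    s <- e_best + 1
  }
  blocks
}

# exhaustive minimum r2 cover for small instances
min_cover_size <- function(covers) {
  m <- nrow(covers)
  for (k in 1:m) {
    combs <- utils::combn(m, k, simplify = FALSE)
    for (cand in combs) {
      if (all(apply(covers[, cand, drop = FALSE], 1, any))) return(k)
    }
  }
  m
}

# Weir & Cockerham (1984) two-population variance components, transcribed
# independently in the "n_c" parameterization written out term by term
wc_oracle <- function(n1, n2, p1, p2, h1, h2) {
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}
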