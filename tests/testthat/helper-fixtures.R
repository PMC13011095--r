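# Shared in-code fixtures for the test suite.

# Block list builder: nb blocks of size bs with common correlation rho,
# occupying the leading features.
mk_blocks <- function(nb, bs, rho) {
  lapply(seq_len(nb), function(b)
    list(members = ((b - 1) * bs + 1):(b * bs), rho = rho))
}

# Small two-group abundance table with a planted block.
toy_table <- function(n_features = 12, n1 = 15, n2 = 10, depth = 5000,
                      rho = 0.8, block = 4, seed = 42) {
  st <- correlation_structure(n_features,
                              list(list(members = seq_len(block),
                                        rho = rho)))
  generate_abundance_table(st, cohort_spec(c(n1, n2), depth = depth,
                                           seed = seed))
}

# Direct per-pair log-ratio variance computation (independent oracle for
# the variation matrix).
oracle_variation <- function(frac) {
  d <- nrow(frac)
  tt <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    if (i != j) tt[i, j] <- stats::var(log(frac[i, ] / frac[j, ]))
  tt
}

# ANOSIM R statistic computed from scratch (independent of the package
# implementation) for a distance matrix and labels.
oracle_anosim_r <- function(d, labels) {
  ut <- upper.tri(d)
  rk <- rank(d[ut])
  same <- outer(labels, labels, "==")[ut]
  m <- length(rk)
  (mean(rk[!same]) - mean(rk[same])) / (m / 2)
}

# Exact enumeration ANOSIM p over all label permutations (tiny n only):
# proportion of permutations (including identity) with R >= observed.
oracle_anosim_p <- function(d, labels) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  r_obs <- oracle_anosim_r(d, labels)
  rs <- vapply(perms(seq_along(labels)),
               function(ix) oracle_anosim_r(d, labels[ix]), numeric(1))
  mean(rs >= r_obs - 1e-12)
}
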