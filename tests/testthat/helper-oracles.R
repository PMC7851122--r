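# Independent brute-force oracles, written as explicit loops over the
# published formulas so they share no code with the implementation.

# Burt constraint of the ego: node 1 is the ego with unit ties to every
# alter; proportional weights p_ij = (z_ij + z_ji) / sum_q (z_iq + z_qi);
# C = 100 * sum_j (p_ej + sum_{q != e,j} p_eq p_qj)^2.
oracle_constraint <- function(ties, weighted = TRUE) {
  k <- nrow(ties)
  a <- ties
  a[is.na(a)] <- 0
  if (!weighted) a <- (a >= 1) * 1
  nodes <- k + 1
  z <- matrix(0, nodes, nodes)
  for (j in 2:nodes) {
    z[1, j] <- 1
    z[j, 1] <- 1
  }
  if (k >= 2) {
    for (i in 2:nodes) for (j in 2:nodes) if (i != j) z[i, j] <- a[i - 1, j - 1]
  }
  p <- matrix(0, nodes, nodes)
  for (i in 1:nodes) {
    denom <- 0
    for (q in 1:nodes) if (q != i) denom <- denom + z[i, q] + z[q, i]
    for (j in 1:nodes) if (j != i) p[i, j] <- (z[i, j] + z[j, i]) / denom
  }
  total <- 0
  for (j in 2:nodes) {
    indirect <- 0
    for (q in 2:nodes) if (q != j) indirect <- indirect + p[1, q] * p[q, j]
    total <- total + (p[1, j] + indirect)^2
  }
  100 * total
}

# Effective size, binary simplification: k minus the mean alter-alter
# degree, degrees counted by explicit loops on presence-coded ties.
oracle_effective_size_binary <- function(ties) {
  k <- nrow(ties)
  if (k == 1) return(1)
  total_deg <- 0
  for (i in 1:k) for (j in 1:k) {
    if (i != j && !is.na(ties[i, j]) && ties[i, j] >= 1) total_deg <- total_deg + 1
  }
  k - total_deg / k
}

# Burt's weighted effective size over the ego-included graph:
# ES = sum_j (1 - sum_{q != e,j} p_eq m_qj),
# m_qj = (z_qj + z_jq) / max_w (z_qw + z_wq).
oracle_effective_size_burt <- function(ties) {
  k <- nrow(ties)
  a <- ties
  a[is.na(a)] <- 0
  nodes <- k + 1
  z <- matrix(0, nodes, nodes)
  for (j in 2:nodes) {
    z[1, j] <- 1
    z[j, 1] <- 1
  }
  if (k >= 2) {
    for (i in 2:nodes) for (j in 2:nodes) if (i != j) z[i, j] <- a[i - 1, j - 1]
  }
  s <- z + t(z)
  p <- matrix(0, nodes, nodes)
  for (i in 1:nodes) for (j in 1:nodes) if (i != j) p[i, j] <- s[i, j] / sum(s[i, -i])
  total <- 0
  for (j in 2:nodes) {
    red <- 0
    for (q in 2:nodes) {
      if (q != j) red <- red + p[1, q] * (s[q, j] / max(s[q, -q]))
    }
    total <- total + (1 - red)
  }
  total
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups (tie-free data assumed).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">"))
  obs <- u_stat(x, y)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# Random egonet strength matrices for property-style loops.
rand_egonet <- function(k, strengths = 0:2) {
  m <- matrix(0, k, k)
  if (k >= 2) {
    v <- sample(strengths, k * (k - 1) / 2, replace = TRUE)
    m[upper.tri(m)] <- v
    m <- m + t(m)
  }
  diag(m) <- NA_real_
  m
}

star_egonet <- function(k) {
  m <- matrix(0, k, k)
  diag(m) <- NA_real_
  m
}

complete_egonet <- function(k, strength = 1) {
  m <- matrix(strength, k, k)
  diag(m) <- NA_real_
  m
}
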