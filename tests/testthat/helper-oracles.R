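# Independent oracles used to check the package's own implementations.

# Recursive depth-first enumeration of minimal mutational pathways between
# two codons, pruning any pathway prefix that reaches a stop codon.
# Structurally different from the permutation-matrix walk in the package.
oracle_pathway_counts <- function(a, b, code) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diffs <- which(ca != cb)
  if (length(diffs) == 0) return(c(S = 0, N = 0, n_paths = 1))
  acc <- list()
  walk <- function(cur, remaining, s, n) {
    if (length(remaining) == 0) {
      acc[[length(acc) + 1]] <<- c(s, n)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- cb[p]
      if (code[[nxt]] == "*") next
      syn <- code[[cur]] == code[[nxt]]
      walk(nxt, setdiff(remaining, p), s + syn, n + !syn)
    }
  }
  walk(a, diffs, 0, 0)
  if (length(acc) == 0) return(c(S = 0, N = 0, n_paths = 0))
  m <- do.call(rbind, acc)
  c(S = mean(m[, 1]), N = mean(m[, 2]), n_paths = nrow(m))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value
# (point-probability rule), via R's dhyper.
oracle_fet_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  ps <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- ps[xs == a]
  min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

# Direct-definition BH adjustment: adj_i = min over j with p_j >= p_i of
# m * p_j / rank_j, capped at 1. Quadratic, definition-first.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / r[p >= p[i]]))
  }, 0)
}

# Exhaustive ancestral-state summation for the likelihood of one alignment
# column on a small tree: sums pi(root) * prod over edges P[parent, child]
# over all joint internal-node states.
oracle_column_likelihood <- function(tree, pmats, pi, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ns <- length(pi)
  root <- ntip + 1L
  grids <- expand.grid(rep(list(seq_len(ns)), nnode))
  total <- 0
  for (g in seq_len(nrow(grids))) {
    states <- c(tip_states, as.integer(grids[g, ]))
    pr <- pi[states[root]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * pmats[[e]][states[tree$edge[e, 1]], states[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  total
}

# Numerical-quadrature mean of a beta distribution restricted to its i-th
# equal-probability slice.
oracle_truncated_beta_means <- function(p, q, K) {
  bounds <- stats::qbeta(seq(0, 1, length.out = K + 1), p, q)
  vapply(seq_len(K), function(i) {
    stats::integrate(function(x) x * stats::dbeta(x, p, q),
                     bounds[i], bounds[i + 1],
                     rel.tol = 1e-10)$value * K
  }, 0)
}
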