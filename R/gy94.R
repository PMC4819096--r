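# Goldman-Yang codon substitution model: F3x4 frequencies, rate matrix,
# transition probabilities via eigendecomposition in the pi-symmetrized
# basis, and Felsenstein pruning over a mixture of omega site classes.

#' F3x4 codon equilibrium frequencies
#'
#' Estimates position-specific nucleotide frequencies from the ungapped
#' codons of an alignment, multiplies them into 64 codon frequencies, removes
#' stop codons and renormalizes over the sense codons.
#'
#' @param aln A `codon_alignment`.
#' @param code Genetic code.
#' @param pseudo Pseudo-frequency added to position-specific nucleotide
#'   counts when a nucleotide is absent at some position (which would zero
#'   out sense-codon frequencies); applied with a warning.
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
f3x4_frequencies <- function(aln, code = standard_genetic_code(),
                             pseudo = 0.5) {
  stopifnot(inherits(aln, "codon_alignment"))
  codons <- aln$codons[aln$codons != GAP_CODON]
  if (length(codons) == 0L) stop("alignment has no ungapped codons")
  counts <- matrix(0, nrow = 4, ncol = 3,
                   dimnames = list(NUCLEOTIDES, NULL))
  for (pos in 1:3) {
    tab <- table(factor(substr(codons, pos, pos), levels = NUCLEOTIDES))
    counts[, pos] <- as.numeric(tab)
  }
  if (any(counts == 0)) {
    warning("nucleotide absent at some codon position; adding pseudo-count ",
            pseudo)
    counts <- counts + pseudo
  }
  freq <- sweep(counts, 2L, colSums(counts), "/")
  info <- code_info(code)
  pi61 <- vapply(info$sense, function(cd) {
    freq[substr(cd, 1, 1), 1] * freq[substr(cd, 2, 2), 2] *
      freq[substr(cd, 3, 3), 3]
  }, 0)
  pi61 / sum(pi61)
}

# Unnormalized GY94 generator for one omega class.
# Returns Q (rows sum to 0) and its mean substitution rate under pi.
codon_generator <- function(omega, kappa, pi, info) {
  ns <- info$n_sense
  Q <- matrix(0, ns, ns)
  p <- info$pairs
  rate <- pi[p$to] * ifelse(p$ts, kappa, 1) * ifelse(p$syn, 1, omega)
  Q[cbind(p$from, p$to)] <- rate
  diag(Q) <- -rowSums(Q)
  list(Q = Q, mean_rate = -sum(pi * diag(Q)))
}

# Eigendecomposition of a reversible generator in the pi-symmetrized basis;
# returns a closure computing P(t) = exp(Qt).
generator_expm <- function(Q, pi) {
  sq <- sqrt(pi)
  # A = D^{1/2} Q D^{-1/2}: scale rows by sqrt(pi), columns by 1/sqrt(pi)
  A <- (Q * sq) / rep(sq, each = nrow(Q))
  A <- (A + t(A)) / 2  # guard against rounding asymmetry
  e <- eigen(A, symmetric = TRUE)
  U <- e$vectors / sq       # rows scaled by 1/sqrt(pi)
  Vt <- t(e$vectors * sq)   # columns scaled by sqrt(pi), transposed
  lambda <- e$values
  function(t) {
    P <- U %*% (exp(lambda * t) * Vt)
    P[P < 0] <- 0
    P
  }
}

# Map alignment codons to sense-codon indices (NA = gap/stop/other, treated
# as missing data in the likelihood).
alignment_state_matrix <- function(aln, info) {
  idx <- matrix(info$sense_index[aln$codons], nrow = nrow(aln$codons),
                dimnames = list(aln$taxa, NULL))
  idx
}

# Collapse alignment columns to unique site patterns.
compress_patterns <- function(states) {
  key <- apply(states, 2L, paste0, collapse = ",")
  uk <- unique(key)
  map <- match(key, uk)
  first <- match(uk, key)
  list(patterns = states[, first, drop = FALSE],
       weights = as.numeric(table(factor(map, levels = seq_along(uk)))),
       map = map)
}

# Felsenstein pruning for one rate class: per-pattern log-likelihood.
# pmats: list over edges of P(t) matrices, aligned with tree$edge rows.
prune_class <- function(tree, pmats, patterns, pi) {
  ns <- length(pi)
  npat <- ncol(patterns)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  partial <- vector("list", nnode)
  logscale <- numeric(npat)
  edge <- tree$edge
  for (k in seq_len(nrow(edge))) {  # postorder
    parent <- edge[k, 1L]; child <- edge[k, 2L]
    P <- pmats[[k]]
    if (child <= ntip) {
      st <- patterns[child, ]
      M <- matrix(1, ns, npat)
      ok <- !is.na(st)
      if (any(ok)) M[, ok] <- P[, st[ok], drop = FALSE]
    } else {
      M <- P %*% partial[[child]]
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- M
    } else {
      partial[[parent]] <- partial[[parent]] * M
    }
    if (min(partial[[parent]]) < 1e-150) {
      # rescale to avoid underflow on deep trees
      cm <- apply(partial[[parent]], 2L, max)
      cm[cm == 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2L, cm, "/")
      logscale <- logscale + log(cm)
    }
  }
  root <- edge[nrow(edge), 1L]
  lik <- colSums(pi * partial[[root]])
  log(lik) + logscale
}

#' Codon mixture log-likelihood on a fixed tree
#'
#' Computes the log-likelihood of a codon alignment under a GY94 model with a
#' discrete mixture of omega site classes, by Felsenstein pruning with
#' per-branch transition matrices `exp(Q t)`. Generators are jointly scaled
#' so the mixture-average substitution rate is one per codon (branch lengths
#' are expected substitutions per codon). Gap codons are treated as missing
#' data.
#'
#' @param aln A `codon_alignment`.
#' @param tree An `ape::phylo` tree whose tip labels equal the alignment
#'   taxa; branch lengths required.
#' @param classes Data frame with columns `proportion` and `omega`
#'   (proportions summing to 1).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param pi Equilibrium frequencies over sense codons (e.g.
#'   [f3x4_frequencies()]); `"uniform"` for 1/61 each.
#' @param scale Global branch-length scale factor.
#' @param code Genetic code.
#' @return List: `lnL`, `site_lik` (pattern x class per-site likelihood
#'   matrix), `weights`, `map` (column -> pattern), `classes`.
#' @export
codon_log_likelihood <- function(aln, tree, classes, kappa, pi = "uniform",
                                 scale = 1, code = standard_genetic_code()) {
  ctx <- likelihood_context(aln, tree, pi, code)
  context_loglik(ctx, classes, kappa, scale)
}

# Precomputed quantities that do not change across optimizer evaluations:
# postorder tree, compressed site patterns, equilibrium frequencies.
likelihood_context <- function(aln, tree, pi = "uniform",
                               code = standard_genetic_code()) {
  info <- code_info(code)
  if (identical(pi, "uniform")) pi <- rep(1 / info$n_sense, info$n_sense)
  if (identical(pi, "F3x4")) pi <- f3x4_frequencies(aln, code = code)
  stopifnot(abs(sum(pi) - 1) < 1e-8, length(pi) == info$n_sense)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree tip labels must equal alignment taxa")
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  states <- alignment_state_matrix(aln, info)
  states <- states[tree$tip.label, , drop = FALSE]
  cp <- compress_patterns(states)
  list(info = info, pi = pi, tree = tree, patterns = cp$patterns,
       weights = cp$weights, map = cp$map)
}

context_loglik <- function(ctx, classes, kappa, scale = 1) {
  if (abs(sum(classes$proportion) - 1) > 1e-8 || any(classes$omega < 0)) {
    stop("invalid site-class mixture")
  }
  if (kappa <= 0 || scale <= 0) stop("kappa and scale must be positive")
  pi <- ctx$pi
  gens <- lapply(classes$omega, codon_generator, kappa = kappa, pi = pi,
                 info = ctx$info)
  mean_rate <- sum(classes$proportion *
                     vapply(gens, function(g) g$mean_rate, 0))
  if (!is.finite(mean_rate) || mean_rate <= 0) stop("degenerate rate matrix")
  el <- ctx$tree$edge.length * scale / mean_rate

  K <- nrow(classes)
  site_loglik <- matrix(NA_real_, ncol(ctx$patterns), K)
  for (k in seq_len(K)) {
    expm_k <- generator_expm(gens[[k]]$Q, pi)
    pmats <- lapply(el, expm_k)
    site_loglik[, k] <- prune_class(ctx$tree, pmats, ctx$patterns, pi)
  }
  # mixture over classes in a numerically safe way
  m <- apply(site_loglik, 1L, max)
  mix <- log(as.vector(exp(site_loglik - m) %*% classes$proportion)) + m
  lnL <- sum(ctx$weights * mix)
  if (!is.finite(lnL)) {
    stop("non-finite log-likelihood at pattern ",
         which(!is.finite(mix))[1L])
  }
  list(lnL = lnL, site_loglik = site_loglik, weights = ctx$weights,
       map = ctx$map, classes = classes)
}

#' Discretize a beta distribution into equal-probability categories
#'
#' Category `i` takes the mean of the beta distribution restricted to its
#' i-th probability-1/K slice (the usual discretization of the beta omega
#' distribution in the M7/M8 site models).
#'
#' @param beta_p,beta_q Beta shape parameters (> 0).
#' @param K Number of categories (>= 1).
#' @return Numeric vector of K category means in (0, 1).
#' @export
#' @examples
#' discretize_beta(1, 1, 10)  # 0.05, 0.15, ..., 0.95
discretize_beta <- function(beta_p, beta_q, K) {
  if (!is.finite(beta_p) || !is.finite(beta_q) || beta_p <= 0 || beta_q <= 0) {
    stop("beta shapes must be finite and positive")
  }
  stopifnot(K >= 1)
  bounds <- stats::qbeta(seq(0, 1, length.out = K + 1), beta_p, beta_q)
  # mean over [a,b] of Beta(p,q) = p/(p+q) * (I_b(p+1,q) - I_a(p+1,q)) / (1/K)
  cdf1 <- stats::pbeta(bounds, beta_p + 1, beta_q)
  means <- (beta_p / (beta_p + beta_q)) * diff(cdf1) * K
  pmin(pmax(means, 1e-12), 1 - 1e-12)
}
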