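test_that("F3x4 frequencies normalize and match hand computation", {
  aln <- codon_alignment(c(a = "ATGGCT", b = "ATGGCC"))
  pi <- suppressWarnings(f3x4_frequencies(aln, pseudo = 0))
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  # hand calculation: pos1 freq A=0.5 G=0.5; pos2 T=0.5 C=0.5;
  # pos3 G=0.5, C=0.25, T=0.25
  f1 <- c(A = .5, C = 0, G = .5, T = 0)
  f2 <- c(A = 0, C = .5, G = 0, T = .5)
  f3 <- c(A = 0, C = .25, G = .5, T = .25)
  code <- standard_genetic_code()
  sense <- names(code)[code != "*"]
  raw <- vapply(sense, function(cd) {
    f1[substr(cd, 1, 1)] * f2[substr(cd, 2, 2)] * f3[substr(cd, 3, 3)]
  }, 0)
  expect_equal(unname(pi), unname(raw / sum(raw)), tolerance = 1e-12)

  # uniform base usage gives uniform sense-codon frequencies
  aln_u <- codon_alignment(c(a = "ACGT", b = "CGTA", c = "GTAC", d = "TACG") |>
                             (\(x) stats::setNames(strrep(x, 3), names(x)))())
  pi_u <- f3x4_frequencies(aln_u)
  expect_equal(unname(pi_u), rep(1 / 61, 61), tolerance = 1e-12)
})

test_that("generator satisfies its structural invariants", {
  info <- evoscreen:::code_info(standard_genetic_code())
  set.seed(2)
  pi <- runif(61); pi <- pi / sum(pi)
  g <- evoscreen:::codon_generator(0.4, 2.5, pi, info)
  expect_equal(max(abs(rowSums(g$Q))), 0, tolerance = 1e-12)
  # detailed balance
  expect_equal(max(abs(pi * g$Q - t(pi * g$Q))), 0, tolerance = 1e-14)
  # transition probabilities: rows sum to 1, stationary under pi
  P <- evoscreen:::generator_expm(g$Q, pi)(0.5 / g$mean_rate)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-9)
  expect_equal(as.vector(pi %*% P), pi, tolerance = 1e-8)
})

test_that("beta discretization matches closed forms and quadrature", {
  expect_equal(discretize_beta(1, 1, 10), seq(0.05, 0.95, by = 0.1),
               tolerance = 1e-9)
  # law of total expectation
  for (pq in list(c(0.843, 2.462), c(2, 5), c(0.2, 0.3))) {
    m <- discretize_beta(pq[1], pq[2], 10)
    expect_equal(mean(m), pq[1] / sum(pq), tolerance = 1e-6)
    expect_equal(m, oracle_truncated_beta_means(pq[1], pq[2], 10),
                 tolerance = 1e-6)
  }
  expect_error(discretize_beta(Inf, 1, 10), "finite")
  expect_error(discretize_beta(0, 1, 10), "positive")
})

test_that("single-codon zero-branch likelihood equals log pi", {
  tr <- ape::read.tree(text = "(a:0.0,b:0.0);")
  aln <- codon_alignment(c(a = "ATG", b = "ATG"))
  ll <- codon_log_likelihood(aln, tr, data.frame(proportion = 1, omega = 1),
                             kappa = 2, pi = "uniform")
  expect_equal(ll$lnL, log(1 / 61), tolerance = 1e-9)
})

test_that("pruning equals exhaustive ancestral-state summation", {
  info <- evoscreen:::code_info(standard_genetic_code())
  pi <- rep(1 / 61, 61)
  for (trial in 1:2) {
    tr <- if (trial == 1) tree_3taxa() else
      ape::read.tree(text = "((a:0.2,b:0.1):0.15,(c:0.3,d:0.05):0.1);")
    sim <- simulate_codon_alignment(tr, 4, kappa = 2, omega = 0.5,
                                    seed = trial)
    classes <- data.frame(proportion = 1, omega = 0.5)
    ll <- codon_log_likelihood(sim$alignment, tr, classes, kappa = 2,
                               pi = "uniform")
    # independent oracle: brute-force summation over internal states
    tr_po <- ape::reorder.phylo(tr, "postorder")
    g <- evoscreen:::codon_generator(0.5, 2, pi, info)
    expm <- evoscreen:::generator_expm(g$Q, pi)
    pmats <- lapply(tr_po$edge.length / g$mean_rate, expm)
    states <- evoscreen:::alignment_state_matrix(sim$alignment, info)
    states <- states[tr_po$tip.label, , drop = FALSE]
    want <- sum(log(vapply(seq_len(ncol(states)), function(j) {
      oracle_column_likelihood(tr_po, pmats, pi, states[, j])
    }, 0)))
    expect_equal(ll$lnL, want, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to re-rooting and leaf order", {
  tr <- tree_6taxa()
  sim <- simulate_codon_alignment(tr, 30, kappa = 2, omega = 0.3, seed = 9)
  classes <- data.frame(proportion = c(0.7, 0.3), omega = c(0.1, 1.5))
  base <- codon_log_likelihood(sim$alignment, tr, classes, kappa = 2.2,
                               pi = "uniform")$lnL
  rerooted <- ape::root(tr, outgroup = "e", resolve.root = TRUE)
  expect_equal(codon_log_likelihood(sim$alignment, rerooted, classes,
                                    kappa = 2.2, pi = "uniform")$lnL,
               base, tolerance = 1e-6)
  shuffled <- codon_alignment(as.character(sim$alignment)[c(4, 2, 6, 1, 5, 3)])
  expect_equal(codon_log_likelihood(shuffled, tr, classes, kappa = 2.2,
                                    pi = "uniform")$lnL,
               base, tolerance = 1e-9)
})

test_that("M0 fit recovers simulated omega and kappa", {
  tr <- tree_8taxa()
  sim <- simulate_codon_alignment(tr, 400, kappa = 2, omega = 0.2, seed = 21)
  fit <- fit_codon_model(sim$alignment, tr, "M0", n_starts = 1,
                         pi = "uniform")
  expect_true(fit$converged)
  expect_equal(fit$params$omega, 0.2, tolerance = 0.25)
  expect_equal(fit$kappa, 2, tolerance = 0.25)
  expect_equal(fit$scale, 1, tolerance = 0.25)
  # every column posterior is 1 for the single class
  expect_equal(unname(fit$site_posteriors[, 1]),
               rep(1, ncol(sim$alignment$codons)))
  expect_equal(nrow(neb_positive_sites(fit)), 0)
})

test_that("nested fits never lose likelihood and LRT behaves", {
  tr <- tree_6taxa()
  sim <- simulate_codon_alignment(tr, 60, kappa = 2, omega = 0.3, seed = 13)
  cmp <- compare_site_models(sim$alignment, tr, null = "M1a", alt = "M2a",
                             n_starts = 1, optimize_scale = FALSE)
  expect_gte(cmp$alt_fit$lnL, cmp$null_fit$lnL - 1e-6)
  expect_equal(cmp$lrt$df, 2)
  expect_gte(cmp$lrt$statistic, 0)

  expect_equal(lrt(-100, -100, df = 2)$statistic, 0)
  expect_false(lrt(-100, -100, df = 2)$significant)
  expect_error(lrt(-100, -100.1, df = 2), "optimization failure")
  expect_equal(lrt(-10, -8, df = 2)$p_value,
               pchisq(4, 2, lower.tail = FALSE))
})

test_that("NEB finds planted positively selected sites with M2a", {
  tr <- tree_8taxa(b = 0.15)
  site_omega <- c(rep(0.1, 90), rep(4, 10))
  sim <- simulate_codon_alignment(tr, 100, kappa = 2,
                                  site_omega = site_omega, seed = 11)
  fit <- fit_codon_model(sim$alignment, tr, "M2a", n_starts = 2,
                         optimize_scale = FALSE, pi = "uniform")
  # posteriors normalize
  expect_equal(unname(rowSums(fit$site_posteriors)),
               rep(1, 100), tolerance = 1e-9)
  pos <- neb_positive_sites(fit, 0.9)
  expect_gt(nrow(pos), 0)
  # detected sites concentrate in the planted 91..100 block
  expect_gte(mean(pos$site > 90), 0.7)

  # a model with no positive class yields an annotated empty result
  m1a <- fit_codon_model(sim$alignment, tr, "M1a", n_starts = 1,
                         optimize_scale = FALSE, pi = "uniform")
  res <- neb_positive_sites(m1a)
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "note"), "no class")
})

test_that("site_class_mixture respects each model's constraints", {
  m1a <- site_class_mixture("M1a", list(p0 = 0.8, omega0 = 0.1))
  expect_equal(m1a$omega[2], 1)
  expect_equal(sum(m1a$proportion), 1)
  m8 <- site_class_mixture("M8", list(p0 = 0.9, beta_p = 0.5, beta_q = 1.5,
                                      omega_s = 2), K = 10)
  expect_equal(nrow(m8), 11)
  expect_equal(sum(m8$proportion), 1)
  expect_true(all(m8$omega[1:10] <= 1))
  expect_gte(m8$omega[11], 1)
  m3 <- site_class_mixture("M3", list(p0 = 0.3, v1 = 0.5, omega0 = 0.01,
                                      omega1 = 0.3, omega2 = 1.5))
  expect_equal(sum(m3$proportion), 1)
})

test_that("M8 recovers its mixture parameters within broad tolerance", {
  tr <- tree_8taxa(b = 0.15)
  cls <- data.frame(proportion = c(rep(0.09, 10), 0.1),
                    omega = c(discretize_beta(0.5, 1.5, 10), 2.5))
  sim <- simulate_codon_alignment(tr, 300, kappa = 2, site_classes = cls,
                                  seed = 77)
  fit <- fit_codon_model(sim$alignment, tr, "M8", n_starts = 1,
                         optimize_scale = FALSE, pi = "uniform")
  # beta shapes are weakly identified at this size; the class weights and
  # the presence of a clearly positive extra class are the recoverable part
  expect_lt(abs(fit$params$p0 - 0.9), 0.15)
  expect_gt(fit$params$omega_s, 1.2)
  expect_gt(fit$params$beta_p, 0.2)
  expect_lt(fit$params$beta_p, 1.5)
  expect_equal(fit$kappa, 2, tolerance = 0.2)
})
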