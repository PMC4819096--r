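# Synthetic-data generators: codon alignments evolved under site-class
# omega on a fixed tree, MK count tables with a chosen neutrality structure,
# SNP tables, expression p-value tables, and a full synthetic study.
# Every generator is a pure function of its arguments and seed.

#' Simulate a codon alignment under site-class omega
#'
#' Draws root codons from the equilibrium frequencies and evolves them along
#' every branch by sampling from `exp(Q t)` under the GY94 model, with each
#' column assigned to an omega site class. Generators are scaled exactly as
#' in [codon_log_likelihood()] (mixture-average rate 1), so fitted parameters
#' are directly comparable to the simulation truth.
#'
#' @param tree `ape::phylo` tree with branch lengths (expected substitutions
#'   per codon).
#' @param n_codons Number of codon columns.
#' @param kappa Transition/transversion ratio (default 2).
#' @param pi Sense-codon frequencies or `"uniform"` (default).
#' @param site_classes Data frame `proportion`, `omega` (proportions sum
#'   to 1); or use `omega` for a single-class shorthand.
#' @param site_omega Optional per-column omega vector of length `n_codons`
#'   (deterministic class assignment); overrides `site_classes`.
#' @param omega Scalar omega shorthand (ignored when `site_classes` given).
#' @param seed Integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @param code Genetic code.
#' @return List: `alignment` (a `codon_alignment`), `site_class` (integer
#'   class index per column), `site_omega` (true omega per column), `seed`.
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2,
                                     pi = "uniform", site_classes = NULL,
                                     site_omega = NULL, omega = 0.2,
                                     seed = 1,
                                     code = standard_genetic_code()) {
  info <- code_info(code)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (identical(pi, "uniform")) pi <- rep(1 / info$n_sense, info$n_sense)
  fixed_class <- NULL
  if (!is.null(site_omega)) {
    if (length(site_omega) != n_codons) {
      stop("site_omega must have length n_codons")
    }
    uo <- unique(site_omega)
    fixed_class <- match(site_omega, uo)
    site_classes <- data.frame(
      proportion = as.vector(table(factor(fixed_class,
                                          levels = seq_along(uo)))) / n_codons,
      omega = uo)
  } else if (is.null(site_classes)) {
    site_classes <- data.frame(proportion = 1, omega = omega)
  }
  if (abs(sum(site_classes$proportion) - 1) > 1e-8 ||
      any(site_classes$omega < 0)) {
    stop("invalid site-class specification")
  }
  gens <- lapply(site_classes$omega, codon_generator, kappa = kappa, pi = pi,
                 info = info)
  mean_rate <- sum(site_classes$proportion *
                     vapply(gens, function(g) g$mean_rate, 0))
  with_seed(seed, {
    K <- nrow(site_classes)
    site_class <- if (!is.null(fixed_class)) {
      fixed_class
    } else {
      sample.int(K, n_codons, replace = TRUE,
                 prob = site_classes$proportion)
    }
    tree_po <- ape::reorder.phylo(tree, "postorder")
    edge <- tree_po$edge[rev(seq_len(nrow(tree_po$edge))), , drop = FALSE]
    el <- tree_po$edge.length[rev(seq_len(nrow(tree_po$edge)))] / mean_rate
    ntip <- length(tree_po$tip.label)
    nnode <- ntip + tree_po$Nnode
    states <- matrix(NA_integer_, nnode, n_codons)
    root <- edge[1L, 1L]
    states[root, ] <- sample.int(info$n_sense, n_codons, replace = TRUE,
                                 prob = pi)
    expms <- lapply(gens, function(g) generator_expm(g$Q, pi))
    for (e in seq_len(nrow(edge))) {  # preorder
      parent <- edge[e, 1L]; child <- edge[e, 2L]
      for (k in seq_len(K)) {
        cols <- which(site_class == k)
        if (!length(cols)) next
        P <- expms[[k]](el[e])
        par_states <- states[parent, cols]
        for (s in unique(par_states)) {
          sel <- cols[par_states == s]
          states[child, sel] <- sample.int(info$n_sense, length(sel),
                                           replace = TRUE, prob = P[s, ])
        }
      }
    }
    seqs <- vapply(seq_len(ntip), function(i) {
      paste0(info$sense[states[i, ]], collapse = "")
    }, "")
    names(seqs) <- tree_po$tip.label
    list(alignment = codon_alignment(seqs), site_class = site_class,
         site_omega = site_classes$omega[site_class], seed = seed)
  })
}

#' Simulate MK contingency tables
#'
#' Draws each cell of the 2x2 polymorphism/divergence table as an independent
#' Poisson with the given expected counts, so the neutrality index of the
#' expectation equals the target implied by `expected`.
#'
#' @param expected Named or positional numeric vector `c(Pn, Ps, Dn, Ds)` of
#'   expected counts (all >= 0, not all zero).
#' @param n_replicates Number of tables.
#' @param seed Integer seed.
#' @return List of `mk_table` objects; attribute `"expected"` records the
#'   expectation.
#' @export
simulate_mk_data <- function(expected, n_replicates = 1, seed = 1) {
  expected <- unname(expected)
  if (length(expected) != 4 || any(expected < 0)) {
    stop("expected must be four non-negative rates (Pn, Ps, Dn, Ds)")
  }
  if (sum(expected) == 0) stop("all-zero expectation")
  with_seed(derive_seed(seed, 101L), {
    tabs <- lapply(seq_len(n_replicates), function(i) {
      x <- stats::rpois(4, expected)
      mk_table(x[1], x[2], x[3], x[4])
    })
    attr(tabs, "expected") <- expected
    tabs
  })
}

#' Simulate differential-expression result tables
#'
#' Null genes receive uniform(0, 1) raw p-values; spiked genes receive raw
#' p-values drawn uniformly from (0, `spike_p_scale`], small enough that the
#' |z| criterion is met (the default scale 1e-9 guarantees |z| >= 5.5 since
#' `pnorm(-5.5)` is about 1.9e-8). Adjusted p-values are BH; fold-change
#' signs are random.
#'
#' @param n_genes Genes per dataset (default 5000).
#' @param n_datasets Number of datasets (default 1).
#' @param spike_genes Character vector of gene symbols to spike (subset of
#'   the generated universe `G00001..`); or an integer count, in which case
#'   the first `spike_genes` genes are spiked.
#' @param spike_p_scale Upper bound of the spiked raw p (default 1e-9).
#' @param spike_datasets For each spiked gene, how many datasets carry the
#'   spike (default: all).
#' @param seed Integer seed.
#' @return List of data frames (one per dataset, named `SYN001..`) with
#'   columns `probe_id, gene_symbol, p_raw, p_adj, log_fc`; attribute
#'   `"spike_genes"` records the planted set.
#' @export
simulate_expression_tables <- function(n_genes = 5000, n_datasets = 1,
                                       spike_genes = character(0),
                                       spike_p_scale = 1e-9,
                                       spike_datasets = n_datasets,
                                       seed = 1) {
  if (spike_p_scale <= 0 || spike_p_scale > 1) {
    stop("spike_p_scale must be in (0, 1]")
  }
  universe <- sprintf("G%05d", seq_len(n_genes))
  if (is.numeric(spike_genes)) spike_genes <- universe[seq_len(spike_genes)]
  if (!all(spike_genes %in% universe)) {
    stop("spike set must be a subset of the gene universe")
  }
  with_seed(derive_seed(seed, 202L), {
    lapply(stats::setNames(seq_len(n_datasets),
                           sprintf("SYN%03d", seq_len(n_datasets))),
           function(d) {
      p <- stats::runif(n_genes)
      spiked_here <- spike_genes[
        (seq_along(spike_genes) + d) %% n_datasets < spike_datasets]
      idx <- match(spiked_here, universe)
      if (length(idx)) p[idx] <- stats::runif(length(idx)) * spike_p_scale
      data.frame(probe_id = paste0(universe, "_at"),
                 gene_symbol = universe,
                 p_raw = p,
                 p_adj = bh_adjust(p),
                 log_fc = stats::rnorm(n_genes) *
                   sample(c(-1, 1), n_genes, replace = TRUE))
    }) -> tabs
    attr(tabs, "spike_genes") <- spike_genes
    tabs
  })
}

#' Simulate a SNP table for a CDS
#'
#' Enumerates all single-base coding variants of the CDS, classifies each
#' with [classify_coding_change()], then samples `n_variants` according to
#' the requested effect mix. SIFT scores and PolyPhen calls are drawn from
#' the configured distributions.
#'
#' @param cds Coding sequence.
#' @param n_variants Number of variants (at most 3 x CDS length).
#' @param effect_mix Named probabilities over
#'   `c(synonymous, missense, nonsense)`; default: uniform over all possible
#'   variants (i.e. the mutational opportunity of the CDS).
#' @param sift_sampler Function(n) returning SIFT scores (default uniform) or
#'   a single numeric value for a point mass.
#' @param polyphen_probs Probabilities over `benign, possibly_damaging,
#'   probably_damaging` (default c(0.4, 0.2, 0.4)).
#' @param p_high_confidence Probability a probably_damaging call is high
#'   confidence (default 0.8).
#' @param p_validated Probability a variant is 1000-Genomes-validated
#'   (default 0.8).
#' @param seed Integer seed.
#' @param code Genetic code.
#' @return Annotated variant data frame (schema of [read_variant_table()]
#'   plus `effect`, `residue_position`, `ref_aa`, `alt_aa`, `tolerance`).
#' @export
simulate_snp_table <- function(cds, n_variants, effect_mix = NULL,
                               sift_sampler = stats::runif,
                               polyphen_probs = c(0.4, 0.2, 0.4),
                               p_high_confidence = 0.8, p_validated = 0.8,
                               seed = 1, code = standard_genetic_code()) {
  cds <- toupper(cds)
  L <- nchar(cds)
  if (L %% 3 != 0) stop("CDS length must be divisible by 3")
  if (n_variants > 3 * L) {
    stop("n_variants exceeds the 3 x CDS-length mutational opportunity")
  }
  if (is.numeric(sift_sampler)) {
    val <- sift_sampler
    sift_sampler <- function(n) rep(val, n)
  }
  ref <- strsplit(cds, "")[[1]]
  cand <- expand.grid(pos = seq_len(L), alt = NUCLEOTIDES,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$alt != ref[cand$pos], ]
  eff <- vapply(seq_len(nrow(cand)), function(i) {
    classify_coding_change(cds, cand$pos[i], ref[cand$pos[i]],
                           cand$alt[i], code)$effect
  }, "")
  cand$effect <- eff
  with_seed(derive_seed(seed, 303L), {
    if (is.null(effect_mix)) {
      pick <- sample.int(nrow(cand), n_variants)
    } else {
      effect_mix <- effect_mix / sum(effect_mix)
      want <- stats::setNames(as.vector(stats::rmultinom(1, n_variants,
                                                         effect_mix)),
                              names(effect_mix))
      pick <- integer(0)
      for (e in names(want)) {
        avail <- which(cand$effect == e)
        if (want[[e]] > length(avail)) {
          stop("not enough possible ", e, " variants in this CDS")
        }
        pick <- c(pick, sample(avail, want[[e]]))
      }
    }
    v <- cand[pick, , drop = FALSE]
    n <- nrow(v)
    df <- data.frame(
      gene = NA_character_,
      variant_id = sprintf("rsSYN%05d", seq_len(n)),
      cds_position = v$pos,
      ref = ref[v$pos],
      alt = v$alt,
      sift_score = pmin(pmax(sift_sampler(n), 0), 1),
      polyphen_call = sample(POLYPHEN_CALLS, n, replace = TRUE,
                             prob = polyphen_probs),
      polyphen_confidence = sample(c("high", "low"), n, replace = TRUE,
                                   prob = c(p_high_confidence,
                                            1 - p_high_confidence)),
      validated = stats::runif(n) < p_validated)
    annotate_variants(df, cds, code)
  })
}
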