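---
title: "Methods and design notes for evoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for evoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoscreen)
```

`evoscreen` chains an expression-screen triage to a molecular-evolution
work-up of the resulting candidate genes. This vignette documents the
statistical machinery, the defaults and why they were chosen, the numerical
details, and what the synthetic-data generators do and do not emulate.

## Expression triage

Input is the standard limma/GEO2R result schema (`probe_id, gene_symbol,
p_raw, p_adj, log_fc`). For each record the screen computes the
inverse-normal Z-score `z = qnorm(p_raw)` — the spreadsheet NORMSINV
convention, so z is negative for p < 0.5 — and keeps records with
`p_raw <= 0.001` and `|z| >= 5.5`, both boundaries inclusive. The |z|
criterion corresponds to p of roughly 1.9e-8 and therefore dominates the
p gate; the gate is kept as an explicit, independently configurable
threshold because it is the natural first filter when exporting from a
differential-expression tool.

Two deliberate conventions:

* **z derives from the raw p, not the adjusted p.** An inverse-normal score
  computed from BH-adjusted values would no longer be a quantile of a
  uniform null, and adjusted values stack into ties; the adjusted p is
  carried through for reporting only. An opt-in `sign_by_direction` flag
  signs z by the fold-change direction; the default leaves the plain
  quantile because the screen criterion uses |z| either way.
* **Overlap requires two distinct datasets**, case-insensitive on the gene
  symbol, with duplicate probes inside a dataset deduplicated to their
  smallest p. No alias resolution is attempted: symbol harmonization
  beyond case would require an external database.

BH adjustment is delegated to `stats::p.adjust(method = "BH")` behind
`bh_adjust()`, which adds the domain validation (p in (0, 1], offending
index named).

## NG86 counting and the McDonald–Kreitman test

`codon_sites()` assigns each codon position a synonymous fraction equal to
the share of its non-stop single-base mutants that are synonymous; stop
mutants leave the denominator (the usual Nei–Gojobori practice), so
S + N = 3 exactly for every sense codon. `codon_differences()` enumerates
all orderings of the differing positions, discards pathways through stop
codons, classifies each step, and averages the per-class counts over the
retained pathways; if every pathway hits a stop the pair is flagged
uncountable rather than silently zeroed. Pairwise totals average the two
sequences' sites (the standard convention; either sequence alone would bias
toward its own codon usage) and skip gap- or stop-containing columns with
an explicit tally. No multiple-hit (e.g. Jukes–Cantor) correction is
applied to the crude dN/dS; the divergences this package targets
(human–mouse) are modest, and the site models below are the proper tool
when saturation matters.

The MK table pairs validated within-species variant counts (Pn, Ps)
against fixed differences (Dn, Ds). Because pathway averaging yields
fractional divergence counts, they are rounded half-up to integers for the
contingency table — fixed-difference tables are conventionally integral —
and the raw fractional values are kept in the result. The neutrality index
(Pn/Ps)/(Dn/Ds) is reported as undefined (with the reason) whenever Ps,
Dn or Ds is zero.

`fisher_exact_2x2()` is an in-house exact test: all tables with the
observed margins are enumerated, point probabilities are computed in log
space via the log-gamma function, and the two-sided p is the sum of
probabilities not exceeding the observed one (point-probability rule, the
dominant convention and the one R's `fisher.test` uses; a relative
tolerance of 1e-7 guards the ≤ comparison against rounding). Sidedness is
not stated in most applied reports; the point-probability two-sided rule
reproduces the published MK p-values checked in the test suite, which
settles the convention empirically. A zero margin returns p = 1, flagged
degenerate. Nonsense variants are excluded from Pn by default (switchable):
premature stops are qualitatively different from amino-acid replacements
and are usually absent from divergence counts too.

## GY94 codon site models

The substitution model is the Goldman–Yang codon model: instantaneous rate
`q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for
single-nucleotide codon changes, 0 otherwise. Equilibrium frequencies are
F3x4 — position-specific nucleotide frequencies multiplied and
renormalized over the 61 sense codons — with a configurable pseudo-count
(default 0.5 on the position counts) applied with a warning if a
nucleotide is absent at some position, which would otherwise zero out
sense-codon frequencies.

Site-to-site variation in omega is a finite mixture:

| model | classes | free ω parameters |
|-------|---------|--------------------|
| M0 | 1 | ω |
| M1a | 2 | ω₀ ∈ (0,1); ω₁ = 1 fixed |
| M2a | 3 | ω₀ ∈ (0,1); ω₁ = 1; ω₂ ≥ 1 |
| M3 | 3 | ω₀, ω₁, ω₂ ≥ 0 |
| M7 | K | beta(p, q) on (0,1), discretized |
| M8 | K + 1 | p₀·beta(p, q) + (1−p₀)·ωₛ, ωₛ ≥ 1 |

The beta is discretized into K equal-probability categories whose values
are the exact means of the corresponding beta slices (via the incomplete
beta identity, not midpoints). K defaults to 10, the conventional choice
that keeps the discretization error well below the statistical noise at
the alignment sizes involved. kappa is a free parameter estimated by ML.
Branch lengths are taken from the input tree in expected substitutions per
codon, with a single global scale factor optionally optimized
(`optimize_scale = TRUE` by default); full per-branch optimization is out
of scope for tractability — with a trustworthy input tree the global
rescaling absorbs the dominant calibration error.

Likelihood is computed by Felsenstein pruning over compressed site
patterns. The reversible generator is exponentiated through its
eigendecomposition in the pi-symmetrized basis (`D^{1/2} Q D^{-1/2}` is
symmetric), which is exact, stable, and verified against a general-purpose
matrix exponential. Generators of all mixture classes are jointly rescaled
so the mixture-average substitution rate is one per codon, keeping branch
lengths interpretable and simulation/inference consistent. Partial
likelihoods are rescaled per column whenever they drift below 1e-150.
Gap codons are treated as missing data (unit partial likelihood).

Optimization is bounded quasi-Newton (L-BFGS-B) on transformed parameters
(log for positive quantities, logit for (0,1) quantities, stick-breaking
for mixture proportions, `1 + exp(x)` for the ω ≥ 1 classes with the
boundary effectively reachable), from three documented starts: package
defaults plus two deterministically jittered copies (fixed jitter seed).
Convergence tolerance is ~1e-8 relative on the objective; non-convergence
is flagged on the result, with the best-so-far returned.
`compare_site_models()` additionally starts the alternative model at a
point numerically equivalent to the fitted null (e.g. M8 with the beta
weight at 1 − 1e-9 and ωₛ at 1), which guarantees the nesting inequality
`lnL(alt) ≥ lnL(null)` up to optimizer tolerance. The LRT statistic is
clamped at zero; a deficit beyond 1e-6 raises an error, since it can only
mean an upstream optimization failure.

NEB site identification plugs the fitted parameters into the per-class
site likelihoods: the posterior that column c belongs to class k is
`p_k L_k(c) / Σ_j p_j L_j(c)`; columns whose total posterior over ω > 1
classes meets the threshold (default 0.95) are reported 1-based. BEB —
which integrates over parameter uncertainty instead of plugging in point
estimates — is not implemented; at the data sizes where it matters the
plug-in NEB is reported with that caveat, and implementing the BEB
integration grid is left as future work.

Two reporting subtleties surfaced by reproduction work are worth noting.
When a discrete-class model (M3) is reported without an explicit LRT
partner, the natural null is M0 with df = 4; results tables sometimes mark
it "n.s." without stating the pairing, so `lrt()` takes the df explicitly
rather than guessing. And published LRT statistics are often computed from
rounded log-likelihoods (e.g. 2 × (22007.790 − 22005.004) = 5.572 against
a printed 5.573); the package reports full-precision statistics and leaves
the rounding to the caller.

## Running dN/dS, regions, and variant overlays

`running_dnds()` pools per-codon NG86 counts over a rectangular window of
half-width `window` residues (default 10 — narrow enough to resolve
peptide-sized features of tens of residues, wide enough to accumulate a
handful of sites), clipped at the protein ends. The pooled ratio uses a
pseudocount c (default 0.5) on both difference counts:
`ω_i = ((N_diff + c)/N_sites) / ((S_diff + c)/S_sites)`, which keeps
sparse windows finite while leaving dense windows essentially untouched;
with c = 0 and a window covering the whole protein the track equals the
global pairwise ratio exactly. Windows with no comparable codons or zero
synonymous sites are marked undefined, never 0. Both knobs are recorded as
attributes on the track. The per-codon counts default to a single species
pair (the reference–outgroup comparison of the MK stage); a
posterior-weighted per-site ω from a fitted site model is an equally valid
input and can be supplied in its place.

Region summaries average the track over each peptide interval (1-based,
inclusive; overlap and nesting allowed, as with TLQP-21 inside TLQP-62)
and flag a region conserved when its mean falls below the gene-wide ω.
Variant overlays attach containing regions and flag variants at residues
where the track exceeds 1.0 — the usual display rule for mutations in
rapidly evolving regions. Peptide coordinates are user-supplied
configuration: published figures rarely print residue ranges, so no
authoritative coordinate set ships with the package.

## Variant tolerance

SIFT calls are damaging iff score ≤ 0.05 (inclusive, per the tool's
definition). The two-tool consensus is: tolerated when SIFT-tolerated and
PolyPhen-benign; damaging when SIFT-damaging and PolyPhen
probably-damaging at high confidence — low-confidence probably-damaging
calls are excluded from the damaging consensus; everything else is
discordant. Variants missing either prediction are tallied separately.
Gene-versus-gene contrasts of (damaging, tolerated) counts reuse the exact
Fisher test; this is offered as a reasonable realization of "marginally
significant excess of poorly tolerated variation" claims, not as a
canonical test.

Only variants validated against population-scale resequencing (the
`validated` flag) enter MK polymorphism counts by default; unvalidated
variants still count toward tolerance summaries, which mirror the broader
variant screens those figures come from.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes with known ground
truth: GY94 alignments evolved root-to-tips with per-column ω classes
(exactly the inference model, including the mixture-rate normalization, so
parameter-recovery tests are well-posed), Poisson MK tables around a
target expectation, SNP tables sampled from a CDS's enumerated mutational
opportunity with configurable effect mixes and score distributions, and
uniform-null expression tables with spiked genes whose raw p is drawn
below 1e-9 — comfortably past the |z| ≥ 5.5 boundary at 1.9e-8. Every
generator is a pure function of (arguments, seed) with its RNG stream
derived per output kind, so adding one generator call does not perturb
another's output.

What passing tests on these data show is that the estimators recover the
parameters of their own generating model and that the pipeline's plumbing
and thresholds behave as specified. What they cannot show: robustness to
alignment error, indels (whole-codon gaps are supported as missing data
but never simulated), selection on synonymous sites, non-equilibrium base
composition, linkage between polymorphisms (MK cells are independent
Poisson draws, a stand-in, not a claim about real site-frequency spectra),
or SIFT/PolyPhen behavior on real structures. Conclusions about real
candidate genes still require the real inputs.

In `simulate_study()`, the planted candidate combines a conserved
divergence history (ω = 0.10) with an excess of damaging missense
polymorphism, while background genes draw their polymorphism spectrum from
their own realized divergence spectrum — the neutral expectation, which
makes them true MK nulls. Default sizes (4 expression datasets of 2000
genes, 8-taxon trees, 120-codon genes, ~40 variants per gene) are chosen so
a full study exercises every stage in seconds while retaining power for
the planted signal.

## Problem sizes and test design

The validation suite checks every counting primitive against independent
oracles (exhaustive pathway enumeration over all 61×61 sense-codon pairs;
exhaustive hypergeometric sums over all 2×2 tables with entries ≤ 15;
brute-force ancestral-state summation on small trees; direct-definition BH
on random vectors) and the estimators by simulation: M0 recovery uses 10
replicates of 8 taxa × 500 codons (mean ω̂ within ±0.05 of truth), and the
M7-vs-M8 false-positive check uses 20 replicates of 6 taxa × 80 codons —
sizes at which a full run of the suite completes in a few minutes while
the Monte-Carlo error remains informative. The boundary null of the M7/M8
contrast makes the χ²(2) reference conservative, so the observed rejection
rate should sit at or below the nominal 5%.

## Known limitations

* BEB posteriors and per-branch ω models are not implemented.
* Codon frequency models other than F3x4 (F1x4, F61) are not offered.
* Only whole-codon gaps are supported; frame-breaking gaps are rejected at
  parse time rather than repaired.
* Ambiguity codes are rejected, not resolved.
* The pipeline's candidate ranking (MK significance, then LRT
  significance, then damaging-variant fraction, with MK p and gene name as
  tie-breaks) is an explicit artifact convention — published analyses rank
  candidates narratively, so any total order here is a design choice, and
  it is recorded in the report metadata.
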