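# Coding-variant classification and SIFT/PolyPhen-2 tolerance consolidation.

#' Classify a coding single-base change
#'
#' Substitutes the alternative base into the CDS, translates the affected
#' codon, and compares amino acids: same residue is synonymous, a stop gain
#' is nonsense, otherwise missense.
#'
#' @param cds Coding sequence (character scalar, length divisible by 3,
#'   starting at the first codon).
#' @param cds_position 1-based nucleotide offset of the change.
#' @param ref_base,alt_base Reference / alternative bases.
#' @param code Genetic code.
#' @return List: `effect` (`"synonymous"`, `"missense"`, `"nonsense"`),
#'   `residue_position`, `ref_aa`, `alt_aa`, `ref_codon`, `alt_codon`.
#' @export
#' @examples
#' classify_coding_change("TTTAAA", 3, "T", "C")$effect  # synonymous
classify_coding_change <- function(cds, cds_position, ref_base, alt_base,
                                   code = standard_genetic_code()) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (cds_position < 1 || cds_position > nchar(cds)) {
    stop("position ", cds_position, " outside the CDS")
  }
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  found <- substr(cds, cds_position, cds_position)
  if (found != ref_base) {
    stop("reference mismatch at CDS position ", cds_position,
         ": expected ", ref_base, ", CDS has ", found)
  }
  res <- ceiling(cds_position / 3)
  start <- 3 * (res - 1) + 1
  ref_codon <- substr(cds, start, start + 2)
  alt_codon <- ref_codon
  substr(alt_codon, cds_position - start + 1, cds_position - start + 1) <-
    alt_base
  ref_aa <- translate_codons(ref_codon, code)
  alt_aa <- translate_codons(alt_codon, code)
  effect <- if (alt_aa == "*" && ref_aa != "*") {
    "nonsense"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else {
    "missense"
  }
  list(effect = effect, residue_position = res, ref_aa = ref_aa,
       alt_aa = alt_aa, ref_codon = ref_codon, alt_codon = alt_codon)
}

#' SIFT tolerance call
#'
#' A substitution is predicted damaging when the SIFT score is at most 0.05
#' (boundary inclusive), otherwise tolerated.
#'
#' @param score SIFT score(s) in `[0, 1]`.
#' @param cutoff Damaging threshold (default 0.05).
#' @return Character vector: `"damaging"` or `"tolerated"`.
#' @export
sift_call <- function(score, cutoff = 0.05) {
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop("SIFT scores must lie in [0, 1]")
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score <= cutoff, "damaging", "tolerated"))
}

POLYPHEN_CALLS <- c("benign", "possibly_damaging", "probably_damaging")

#' Consolidate SIFT and PolyPhen-2 into a consensus tolerance category
#'
#' A variant is `tolerated_consensus` when SIFT says tolerated and PolyPhen-2
#' says benign; `damaging_consensus` when SIFT says damaging and PolyPhen-2
#' says probably damaging with high confidence (low-confidence probably
#' damaging calls are excluded from the damaging consensus); anything else is
#' `discordant`. Variants missing either prediction return `NA` and are
#' tallied separately by [tolerance_summary()].
#'
#' @param sift_score SIFT score(s) in `[0, 1]` (NA allowed).
#' @param polyphen_call One of `"benign"`, `"possibly_damaging"`,
#'   `"probably_damaging"` (NA allowed).
#' @param polyphen_confidence `"high"` or `"low"` (default `"high"`).
#' @param sift_cutoff SIFT damaging threshold.
#' @return Character vector: `"tolerated_consensus"`, `"damaging_consensus"`,
#'   `"discordant"`, or NA when a prediction is missing.
#' @export
consensus_tolerance <- function(sift_score, polyphen_call,
                                polyphen_confidence = "high",
                                sift_cutoff = 0.05) {
  n <- max(length(sift_score), length(polyphen_call))
  sift_score <- rep_len(sift_score, n)
  polyphen_call <- rep_len(polyphen_call, n)
  polyphen_confidence <- rep_len(polyphen_confidence, n)
  bad <- !is.na(polyphen_call) & !(polyphen_call %in% POLYPHEN_CALLS)
  if (any(bad)) {
    stop("unknown PolyPhen call(s): ",
         paste(unique(polyphen_call[bad]), collapse = ", "))
  }
  s <- sift_call(sift_score, sift_cutoff)
  out <- rep(NA_character_, n)
  have <- !is.na(s) & !is.na(polyphen_call)
  tol <- have & s == "tolerated" & polyphen_call == "benign"
  dam <- have & s == "damaging" & polyphen_call == "probably_damaging" &
    polyphen_confidence == "high"
  out[have] <- "discordant"
  out[tol] <- "tolerated_consensus"
  out[dam] <- "damaging_consensus"
  out
}

#' Read a variant table
#'
#' Tab-separated with header: `gene, variant_id, cds_position, ref, alt,
#' sift_score, polyphen_call, polyphen_confidence, validated` (empty
#' sift/polyphen fields allowed).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("gene", "variant_id", "cds_position", "ref", "alt",
            "sift_score", "polyphen_call", "polyphen_confidence", "validated")
  if (!all(need %in% names(df))) {
    stop("variant table ", path, " needs columns: ",
         paste(need, collapse = ", "))
  }
  df$validated <- as.logical(df$validated)
  df
}

#' Annotate variants against a CDS
#'
#' Applies [classify_coding_change()] row-wise and adds `effect`,
#' `residue_position`, `ref_aa`, `alt_aa` and the consensus `tolerance`.
#'
#' @param variants Variant data frame (see [read_variant_table()]).
#' @param cds Coding sequence of the gene.
#' @param code Genetic code.
#' @return The input with annotation columns appended.
#' @export
annotate_variants <- function(variants, cds, code = standard_genetic_code()) {
  v <- as.data.frame(variants)
  ann <- lapply(seq_len(nrow(v)), function(i) {
    classify_coding_change(cds, v$cds_position[i], v$ref[i], v$alt[i], code)
  })
  v$effect <- vapply(ann, `[[`, "", "effect")
  v$residue_position <- vapply(ann, `[[`, 0, "residue_position")
  v$ref_aa <- vapply(ann, `[[`, "", "ref_aa")
  v$alt_aa <- vapply(ann, `[[`, "", "alt_aa")
  v$tolerance <- consensus_tolerance(
    v$sift_score, v$polyphen_call,
    ifelse(is.na(v$polyphen_confidence), "high", v$polyphen_confidence))
  v
}

#' Per-gene tolerance summary
#'
#' Counts consensus categories among variants with both predictions present
#' (mirroring the usual tolerated/damaging split of nonsynonymous variants);
#' variants missing a prediction are tallied separately.
#'
#' @param variants Annotated variant data frame (with `gene` and `tolerance`
#'   columns; see [annotate_variants()] / [consensus_tolerance()]).
#' @param missense_only Count only missense variants (default TRUE when an
#'   `effect` column is present).
#' @return Data frame of class `tolerance_summary`: per gene `n_variants`,
#'   `n_tolerated_consensus`, `n_damaging_consensus`, `n_discordant`,
#'   `n_missing_prediction`, `fraction_tolerated`.
#' @export
tolerance_summary <- function(variants, missense_only = TRUE) {
  v <- as.data.frame(variants)
  if (missense_only && "effect" %in% names(v)) {
    v <- v[v$effect == "missense", , drop = FALSE]
  }
  genes <- sort(unique(v$gene))
  rows <- lapply(genes, function(g) {
    tol <- v$tolerance[v$gene == g]
    has <- !is.na(tol)
    n <- sum(has)
    nt <- sum(tol[has] == "tolerated_consensus")
    nd <- sum(tol[has] == "damaging_consensus")
    nx <- sum(tol[has] == "discordant")
    data.frame(gene = g, n_variants = n,
               n_tolerated_consensus = nt, n_damaging_consensus = nd,
               n_discordant = nx, n_missing_prediction = sum(!has),
               fraction_tolerated = if (n > 0) nt / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tolerance_summary", "data.frame")
  out
}

#' Pairwise Fisher tests of damaging vs tolerated counts across genes
#'
#' For every gene pair, evaluates the 2x2 table of consensus damaging and
#' tolerated counts with [fisher_exact_2x2()] — a simple way to ask whether
#' one gene's excess of poorly tolerated variation is significant relative to
#' another's.
#'
#' @param summaries A `tolerance_summary` data frame (>= 2 genes).
#' @return Data frame `gene_a`, `gene_b`, `p_two_sided`, `odds_ratio`.
#' @export
compare_gene_tolerance <- function(summaries) {
  s <- as.data.frame(summaries)
  if (nrow(s) < 2) stop("need at least two genes to compare")
  pairs <- utils::combn(seq_len(nrow(s)), 2)
  rows <- apply(pairs, 2L, function(ij) {
    a <- s[ij[1], ]; b <- s[ij[2], ]
    fet <- fisher_exact_2x2(a$n_damaging_consensus, a$n_tolerated_consensus,
                            b$n_damaging_consensus, b$n_tolerated_consensus)
    data.frame(gene_a = a$gene, gene_b = b$gene,
               p_two_sided = fet$p_two_sided, odds_ratio = fet$odds_ratio)
  })
  do.call(rbind, rows)
}

#' Polymorphism counts for the MK test from a variant table
#'
#' Tallies within-species nonsynonymous (`Pn`) and synonymous (`Ps`) variant
#' counts. By default only variants flagged validated are counted and
#' nonsense variants are excluded from `Pn`.
#'
#' @param variants Annotated variant data frame (`effect`, `validated`).
#' @param validated_only Count only validated variants (default TRUE).
#' @param include_nonsense Count nonsense variants into `Pn` (default FALSE).
#' @return Named integer vector `c(Pn =, Ps =)`.
#' @export
mk_polymorphism_counts <- function(variants, validated_only = TRUE,
                                   include_nonsense = FALSE) {
  v <- as.data.frame(variants)
  if (validated_only) v <- v[v$validated %in% TRUE, , drop = FALSE]
  nonsyn <- v$effect == "missense" |
    (include_nonsense & v$effect == "nonsense")
  c(Pn = sum(nonsyn), Ps = sum(v$effect == "synonymous"))
}
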