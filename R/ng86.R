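# Nei-Gojobori (1986) style counting of synonymous/nonsynonymous sites and
# differences, with pathway averaging over minimal mutational paths.

#' Synonymous and nonsynonymous sites of a codon
#'
#' For each codon position, the synonymous fraction is the number of
#' synonymous single-base mutants divided by the number of non-stop
#' single-base mutants at that position (stop mutants are excluded from the
#' denominator). `S_sites` sums the three fractions and
#' `N_sites = 3 - S_sites`.
#'
#' @param codon Ungapped, non-stop trinucleotide.
#' @param code Genetic code.
#' @return Named numeric vector `c(S_sites =, N_sites =)`.
#' @export
#' @examples
#' codon_sites("TTT")  # 1/3 synonymous site
codon_sites <- function(codon, code = standard_genetic_code()) {
  info <- code_info(code)
  codon <- toupper(codon)
  aa <- code[codon]
  if (is.na(aa)) stop("invalid codon: ", codon)
  if (aa == "*") stop("stop codon ", codon, " carries no sites")
  s <- info$sites[codon, ]
  c(S_sites = unname(s[["S"]]), N_sites = unname(s[["N"]]))
}

.perms <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Synonymous and nonsynonymous differences between two codons
#'
#' Enumerates all orderings of the differing positions (minimal mutational
#' pathways), discards pathways passing through a stop codon, classifies each
#' step as synonymous or nonsynonymous, and averages the per-class step
#' counts over the retained pathways.
#'
#' @param codon_a,codon_b Ungapped, non-stop trinucleotides.
#' @param code Genetic code.
#' @return Named numeric vector `c(S_diff =, N_diff =)` with logical
#'   attribute `"countable"`; `FALSE` (and zero counts) when every pathway
#'   passes through a stop codon.
#' @export
#' @examples
#' codon_differences("TTT", "GTA")  # averages the two stop-free pathways
codon_differences <- function(codon_a, codon_b, code = standard_genetic_code()) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  aa_a <- code[codon_a]; aa_b <- code[codon_b]
  if (is.na(aa_a) || is.na(aa_b)) {
    stop("invalid codon: ", codon_a, " / ", codon_b)
  }
  if (aa_a == "*" || aa_b == "*") stop("stop codons are not countable")
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  d <- length(diff_pos)
  out <- c(S_diff = 0, N_diff = 0)
  if (d == 0L) {
    attr(out, "countable") <- TRUE
    return(out)
  }
  orders <- .perms[[d]]
  s_tot <- 0; n_tot <- 0; kept <- 0L
  for (r in seq_len(nrow(orders))) {
    cur <- codon_a
    s <- 0; n <- 0
    ok <- TRUE
    for (p in diff_pos[orders[r, ]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (code[nxt] == "*") { ok <- FALSE; break }
      if (code[cur] == code[nxt]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) {
      s_tot <- s_tot + s; n_tot <- n_tot + n; kept <- kept + 1L
    }
  }
  if (kept == 0L) {
    attr(out, "countable") <- FALSE
    return(out)
  }
  out <- c(S_diff = s_tot / kept, N_diff = n_tot / kept)
  attr(out, "countable") <- TRUE
  out
}

#' Pairwise synonymous/nonsynonymous counts between two aligned sequences
#'
#' Sums NG86 sites (averaged over the two sequences, the usual convention)
#' and pathway-averaged differences over all codon columns where both codons
#' are ungapped and non-stop. Skipped columns (gap or stop in either
#' sequence) and columns whose pathways all pass through stops are tallied,
#' never silently dropped.
#'
#' @param aln A `codon_alignment`, or `NULL` if `seq_a`/`seq_b` are given
#'   directly as codon vectors.
#' @param seq_a,seq_b Taxon names in `aln` (or character vectors of codons
#'   when `aln` is `NULL`). Defaults to the first two taxa.
#' @param code Genetic code.
#' @return An object of class `codon_counts`: list with `S_sites`, `N_sites`,
#'   `S_diff`, `N_diff`, `codons_compared`, `skipped` (gap/stop columns),
#'   `uncountable` (all-stop-pathway columns), `per_codon` (data frame of
#'   per-column counts aligned to codon coordinates, `NA` where not
#'   comparable), and `omega` (crude dN/dS, no multiple-hit correction).
#' @export
pairwise_codon_counts <- function(aln = NULL, seq_a = NULL, seq_b = NULL,
                                  code = standard_genetic_code()) {
  if (!is.null(aln)) {
    stopifnot(inherits(aln, "codon_alignment"))
    if (is.null(seq_a)) seq_a <- aln$taxa[1L]
    if (is.null(seq_b)) seq_b <- aln$taxa[2L]
    a <- aln$codons[seq_a, ]
    b <- aln$codons[seq_b, ]
  } else {
    a <- toupper(seq_a); b <- toupper(seq_b)
  }
  if (length(a) != length(b)) stop("sequences differ in codon length")
  n <- length(a)
  per <- data.frame(codon = seq_len(n), S_sites = NA_real_, N_sites = NA_real_,
                    S_diff = NA_real_, N_diff = NA_real_,
                    comparable = FALSE)
  skipped <- 0L; uncountable <- 0L
  for (i in seq_len(n)) {
    ca <- a[i]; cb <- b[i]
    if (ca == GAP_CODON || cb == GAP_CODON ||
        is.na(code[ca]) || is.na(code[cb]) ||
        code[ca] == "*" || code[cb] == "*") {
      skipped <- skipped + 1L
      next
    }
    sa <- codon_sites(ca, code); sb <- codon_sites(cb, code)
    dd <- codon_differences(ca, cb, code)
    if (!attr(dd, "countable")) uncountable <- uncountable + 1L
    per$S_sites[i] <- (sa[["S_sites"]] + sb[["S_sites"]]) / 2
    per$N_sites[i] <- (sa[["N_sites"]] + sb[["N_sites"]]) / 2
    per$S_diff[i] <- dd[["S_diff"]]
    per$N_diff[i] <- dd[["N_diff"]]
    per$comparable[i] <- TRUE
  }
  compared <- sum(per$comparable)
  if (compared == 0L) stop("no comparable codon columns")
  S_sites <- sum(per$S_sites, na.rm = TRUE)
  N_sites <- sum(per$N_sites, na.rm = TRUE)
  S_diff <- sum(per$S_diff, na.rm = TRUE)
  N_diff <- sum(per$N_diff, na.rm = TRUE)
  dn <- if (N_sites > 0) N_diff / N_sites else NA_real_
  ds <- if (S_sites > 0) S_diff / S_sites else NA_real_
  omega <- if (!is.na(dn) && !is.na(ds) && ds > 0) dn / ds else NA_real_
  structure(list(S_sites = S_sites, N_sites = N_sites,
                 S_diff = S_diff, N_diff = N_diff,
                 codons_compared = compared, skipped = skipped,
                 uncountable = uncountable, per_codon = per,
                 dN = dn, dS = ds, omega = omega),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf(paste0("codon_counts: %d codons compared (%d skipped)\n",
                     "  sites  S = %.2f  N = %.2f\n",
                     "  diffs  S = %.2f  N = %.2f\n",
                     "  dN/dS = %s\n"),
              x$codons_compared, x$skipped, x$S_sites, x$N_sites,
              x$S_diff, x$N_diff,
              ifelse(is.na(x$omega), "undefined", sprintf("%.4f", x$omega))))
  invisible(x)
}
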