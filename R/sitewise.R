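# Running per-residue dN/dS track with peptide-region summaries and variant
# overlays.

#' Running dN/dS along a protein
#'
#' At residue `i`, pools per-codon synonymous/nonsynonymous sites and
#' differences over the rectangular window `[i - window, i + window]`
#' (clipped at the protein ends, so edge windows shrink), then computes
#' `omega_i = ((N_diff + c) / N_sites) / ((S_diff + c) / S_sites)` with
#' pseudocount `c`. Residues whose window has no comparable codons or zero
#' synonymous sites are marked undefined, never silently 0.
#'
#' @param per_codon_counts Data frame with columns `S_sites`, `N_sites`,
#'   `S_diff`, `N_diff` (NA rows allowed for non-comparable codons), one row
#'   per residue, e.g. the `per_codon` element of [pairwise_codon_counts()].
#' @param window Window half-width in residues (default 10).
#' @param pseudocount Pseudocount added to both difference counts
#'   (default 0.5; 0 recovers the raw pooled ratio).
#' @return Object of class `dnds_track`: data frame `residue`, `omega`,
#'   `defined`, with `window` and `pseudocount` attributes.
#' @export
running_dnds <- function(per_codon_counts, window = 10, pseudocount = 0.5) {
  pc <- as.data.frame(per_codon_counts)
  need <- c("S_sites", "N_sites", "S_diff", "N_diff")
  if (!all(need %in% names(pc))) {
    stop("per-codon counts need columns: ", paste(need, collapse = ", "))
  }
  if (window < 0) stop("window must be >= 0")
  n <- nrow(pc)
  z <- function(v) { v[is.na(v)] <- 0; v }
  cs <- function(v) cumsum(z(v))
  cums <- lapply(pc[need], cs)
  pool <- function(cum, i0, i1) {
    cum[i1] - if (i0 > 1) cum[i0 - 1] else 0
  }
  omega <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  for (i in seq_len(n)) {
    i0 <- max(1L, i - window); i1 <- min(n, i + window)
    Ss <- pool(cums$S_sites, i0, i1); Ns <- pool(cums$N_sites, i0, i1)
    Sd <- pool(cums$S_diff, i0, i1); Nd <- pool(cums$N_diff, i0, i1)
    if (Ss <= 0 || Ns <= 0) next
    num <- (Nd + pseudocount) / Ns
    den <- (Sd + pseudocount) / Ss
    if (den <= 0) next
    omega[i] <- num / den
    defined[i] <- TRUE
  }
  structure(data.frame(residue = seq_len(n), omega = omega,
                       defined = defined),
            class = c("dnds_track", "data.frame"),
            window = window, pseudocount = pseudocount)
}

#' Define peptide regions
#'
#' @param name Region names (e.g. peptide identifiers such as TLQP-21).
#' @param start,end 1-based inclusive residue coordinates; regions may
#'   overlap or nest.
#' @return Data frame of class `peptide_regions`.
#' @export
peptide_regions <- function(name, start, end) {
  if (any(start < 1) || any(end < start)) {
    stop("regions require 1 <= start <= end")
  }
  structure(data.frame(name = as.character(name), start = as.integer(start),
                       end = as.integer(end)),
            class = c("peptide_regions", "data.frame"))
}

#' Read a peptide-region table
#'
#' Tab-separated, with header `name start end` (1-based inclusive).
#'
#' @param path File path.
#' @return A [peptide_regions()] data frame.
#' @export
read_peptide_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(df))) {
    stop("region file needs columns: ", paste(need, collapse = ", "))
  }
  peptide_regions(df$name, df$start, df$end)
}

#' Per-region mean omega and conservation flag
#'
#' @param track A `dnds_track`.
#' @param regions A `peptide_regions` data frame (may be empty).
#' @param global_omega Gene-wide omega to compare against (e.g. the `omega`
#'   element of [pairwise_codon_counts()]).
#' @return Data frame `name`, `start`, `end`, `n_defined`, `mean_omega`,
#'   `conserved` (mean below the gene average; NA when the region is fully
#'   undefined).
#' @export
summarize_regions <- function(track, regions, global_omega) {
  if (nrow(regions) == 0) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), n_defined = integer(0),
                      mean_omega = numeric(0), conserved = logical(0)))
  }
  if (any(regions$end > nrow(track))) {
    stop("region extends beyond the protein length")
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    idx <- regions$start[i]:regions$end[i]
    vals <- track$omega[idx][track$defined[idx]]
    m <- if (length(vals)) mean(vals) else NA_real_
    data.frame(name = regions$name[i], start = regions$start[i],
               end = regions$end[i], n_defined = length(vals),
               mean_omega = m,
               conserved = if (is.na(m)) NA else m < global_omega)
  })
  do.call(rbind, rows)
}

#' Overlay variants on a dN/dS track
#'
#' Annotates each variant with the peptide regions containing it, its
#' tolerance call, and a high-omega flag set when the track value at the
#' variant's residue exceeds 1.0 (the convention of flagging mutations in
#' rapidly evolving regions). Out-of-range variants are rejected with a
#' report while the rest proceed.
#'
#' @param track A `dnds_track`.
#' @param regions A `peptide_regions` data frame.
#' @param variants Data frame with at least `residue_position` and
#'   `variant_id`; a `tolerance` column is carried through when present.
#' @return Data frame `variant_id`, `residue_position`, `tolerance`,
#'   `in_regions` (semicolon-joined names), `omega`, `high_omega`; rejected
#'   rows are in attribute `"rejected"`.
#' @export
overlay_variants <- function(track, regions, variants) {
  v <- as.data.frame(variants)
  if (!all(c("residue_position", "variant_id") %in% names(v))) {
    stop("variants need columns residue_position and variant_id")
  }
  n <- nrow(track)
  bad <- v$residue_position < 1 | v$residue_position > n |
    is.na(v$residue_position)
  rejected <- v[bad, , drop = FALSE]
  if (any(bad)) {
    warning(sum(bad), " variant(s) outside the protein [1, ", n,
            "] were rejected")
  }
  v <- v[!bad, , drop = FALSE]
  in_regions <- vapply(v$residue_position, function(p) {
    hits <- regions$name[regions$start <= p & p <= regions$end]
    paste(hits, collapse = ";")
  }, "")
  omega <- track$omega[v$residue_position]
  out <- data.frame(
    variant_id = v$variant_id,
    residue_position = v$residue_position,
    tolerance = if ("tolerance" %in% names(v)) v$tolerance else NA_character_,
    in_regions = in_regions,
    omega = omega,
    high_omega = !is.na(omega) & omega > 1.0)
  attr(out, "rejected") <- rejected
  out
}
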