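# McDonald-Kreitman test: 2x2 polymorphism/divergence table, exact two-sided
# Fisher test (log-gamma hypergeometric), and neutrality index.

#' Assemble a McDonald-Kreitman 2x2 table
#'
#' @param Pn,Ps Within-species nonsynonymous / synonymous variant counts.
#' @param Dn,Ds Fixed nonsynonymous / synonymous differences between species.
#' @return An object of class `mk_table`.
#' @export
mk_table <- function(Pn, Ps, Dn, Ds) {
  x <- c(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("MK table entries must be non-negative integers")
  }
  vals <- as.list(stats::setNames(as.integer(round(x)), names(x)))
  structure(vals, class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  m <- matrix(c(x$Pn, x$Ps, x$Dn, x$Ds), 2, byrow = TRUE,
              dimnames = list(c("polymorphism", "divergence"),
                              c("nonsynonymous", "synonymous")))
  print(m)
  invisible(x)
}

# log choose(n, k) via log-gamma
.lchoose_lg <- function(n, k) {
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
}

#' Exact two-sided Fisher test on a 2x2 table
#'
#' Computes the exact hypergeometric two-sided p-value: the sum of the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (point-probability
#' rule, with relative tolerance 1e-7 on the comparison). All probabilities
#' are computed in log space via the log-gamma function. A zero margin yields
#' p = 1 by convention, flagged degenerate.
#'
#' @param Pn,Ps,Dn,Ds Non-negative integer cell counts (row 1: `Pn`, `Ps`;
#'   row 2: `Dn`, `Ds`). Alternatively pass an `mk_table` as `Pn`.
#' @return Object of class `fet_result`: list with `p_two_sided`,
#'   `odds_ratio` (`(Pn*Ds)/(Ps*Dn)`, `Inf` when `Ps*Dn = 0` and
#'   `Pn*Ds > 0`, `NaN` when both products are 0) and `degenerate`.
#' @export
#' @examples
#' fisher_exact_2x2(27, 16, 79, 146)$p_two_sided  # ~0.0011
fisher_exact_2x2 <- function(Pn, Ps = NULL, Dn = NULL, Ds = NULL) {
  if (inherits(Pn, "mk_table")) {
    t <- Pn; Pn <- t$Pn; Ps <- t$Ps; Dn <- t$Dn; Ds <- t$Ds
  }
  cells <- c(Pn, Ps, Dn, Ds)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table")
  r1 <- Pn + Ps; r2 <- Dn + Ds
  c1 <- Pn + Dn; c2 <- Ps + Ds
  n <- r1 + r2
  ad <- as.numeric(Pn) * Ds
  bc <- as.numeric(Ps) * Dn
  orr <- if (bc == 0) { if (ad == 0) NaN else Inf } else ad / bc
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(structure(list(p_two_sided = 1, odds_ratio = orr,
                          degenerate = TRUE), class = "fet_result"))
  }
  support <- max(0L, r1 - c2):min(r1, c1)
  logp <- .lchoose_lg(c1, support) + .lchoose_lg(c2, r1 - support) -
    .lchoose_lg(n, r1)
  logp_obs <- logp[support == Pn]
  keep <- logp <= logp_obs + log1p(1e-7)
  p <- min(1, sum(exp(logp[keep])))
  structure(list(p_two_sided = p, odds_ratio = orr, degenerate = FALSE),
            class = "fet_result")
}

#' @export
print.fet_result <- function(x, ...) {
  cat(sprintf("Fisher exact (two-sided): p = %.4g, odds ratio = %.4g%s\n",
              x$p_two_sided, x$odds_ratio,
              if (x$degenerate) " [degenerate margin]" else ""))
  invisible(x)
}

#' McDonald-Kreitman test
#'
#' Compares within-species nonsynonymous/synonymous polymorphism to fixed
#' between-species differences. Fractional divergence counts (from pathway
#' averaging) are rounded half-up to integers for the contingency table; the
#' raw fractional values are retained in the result. The neutrality index
#' `NI = (Pn/Ps)/(Dn/Ds)` is reported as `NA` (with a reason) whenever
#' `Ps`, `Dn` or `Ds` is zero, never silently as 0 or infinity.
#'
#' @param Pn,Ps Validated within-species variant counts (nonsyn / syn).
#' @param divergence A `codon_counts` object from [pairwise_codon_counts()],
#'   or a numeric vector `c(Dn, Ds)`.
#' @param alpha Significance level; default 0.05.
#' @return Object of class `mk_result`: the `mk_table`, the `fet_result`,
#'   `neutrality_index` (+`ni_undefined_reason`), raw `Dn_raw`/`Ds_raw`,
#'   `alpha` and `significant`.
#' @export
#' @examples
#' mk_test(27, 16, c(79, 146))
mk_test <- function(Pn, Ps, divergence, alpha = 0.05) {
  if (inherits(divergence, "codon_counts")) {
    dn_raw <- divergence$N_diff; ds_raw <- divergence$S_diff
  } else {
    stopifnot(is.numeric(divergence), length(divergence) == 2L)
    dn_raw <- divergence[[1]]; ds_raw <- divergence[[2]]
  }
  Dn <- floor(dn_raw + 0.5)  # half-up
  Ds <- floor(ds_raw + 0.5)
  tab <- mk_table(Pn, Ps, Dn, Ds)
  fet <- fisher_exact_2x2(tab)
  reason <- NULL
  ni <- NA_real_
  if (Ps == 0) {
    reason <- "Ps = 0"
  } else if (Dn == 0) {
    reason <- "Dn = 0"
  } else if (Ds == 0) {
    reason <- "Ds = 0"
  } else {
    ni <- (Pn / Ps) / (Dn / Ds)
  }
  structure(list(table = tab, fet = fet, neutrality_index = ni,
                 ni_undefined_reason = reason,
                 Dn_raw = dn_raw, Ds_raw = ds_raw, alpha = alpha,
                 significant = fet$p_two_sided < alpha),
            class = "mk_result")
}

#' @export
print.mk_result <- function(x, ...) {
  print(x$table)
  print(x$fet)
  cat(sprintf("neutrality index: %s%s; %ssignificant at alpha = %g\n",
              ifelse(is.na(x$neutrality_index), "undefined",
                     sprintf("%.3f", x$neutrality_index)),
              if (!is.null(x$ni_undefined_reason))
                paste0(" (", x$ni_undefined_reason, ")") else "",
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Run MK tests on a gene table
#'
#' Reads (or accepts) a table with columns `gene, Pn, Ps, Dn, Ds` and runs
#' [mk_test()] per row.
#'
#' @param x Path to a TSV file with a header, or a data frame.
#' @param alpha Significance level.
#' @return Data frame with the input counts plus `p_two_sided`, `odds_ratio`,
#'   `neutrality_index` and `significant`.
#' @export
mk_test_table <- function(x, alpha = 0.05) {
  df <- if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  need <- c("gene", "Pn", "Ps", "Dn", "Ds")
  if (!all(need %in% names(df))) {
    stop("MK input needs columns: ", paste(need, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    r <- mk_test(df$Pn[i], df$Ps[i], c(df$Dn[i], df$Ds[i]), alpha = alpha)
    data.frame(p_two_sided = r$fet$p_two_sided,
               odds_ratio = r$fet$odds_ratio,
               neutrality_index = r$neutrality_index,
               significant = r$significant)
  })
  cbind(df[need], do.call(rbind, res))
}
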