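# Expression-screen triage: BH adjustment, inverse-normal Z-scores,
# candidate selection, and cross-dataset overlap.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' preserving input order (delegates to `stats::p.adjust(method = "BH")`
#' after validating the input).
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad)) {
    stop("p-values outside (0, 1] at index ", paste(bad, collapse = ", "))
  }
  stats::p.adjust(p, method = "BH")
}

#' Inverse-normal Z-score from a raw p-value
#'
#' `z = qnorm(p)`, the standard-normal quantile (spreadsheet NORMSINV
#' convention: negative for p < 0.5). Optionally signed by fold-change
#' direction.
#'
#' @param p_raw Raw p-values in (0, 1), exclusive: 0 and 1 have infinite
#'   quantiles and raise an error.
#' @param log_fc Optional signed log fold changes, used only when
#'   `sign_by_direction` is TRUE.
#' @param sign_by_direction If TRUE, return `sign(log_fc) * |z|`; default
#'   FALSE (plain quantile).
#' @return Numeric vector of Z-scores.
#' @export
#' @examples
#' z_from_p(0.001)  # -3.0902
z_from_p <- function(p_raw, log_fc = NULL, sign_by_direction = FALSE) {
  if (any(!is.finite(p_raw) | p_raw <= 0 | p_raw >= 1)) {
    stop("p values must lie strictly inside (0, 1)")
  }
  z <- stats::qnorm(p_raw)
  if (sign_by_direction) {
    if (is.null(log_fc)) stop("log_fc required when sign_by_direction = TRUE")
    z <- sign(log_fc) * abs(z)
  }
  z
}

#' Read a differential-expression result table
#'
#' Tab-separated with header: `probe_id, gene_symbol, p_raw, p_adj, log_fc`
#' (the usual limma/GEO2R export schema).
#'
#' @param path File path.
#' @return Data frame with the five columns.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol", "p_raw", "p_adj", "log_fc")
  if (!all(need %in% names(df))) {
    stop("expression table ", path, " needs columns: ",
         paste(need, collapse = ", "))
  }
  df[need]
}

#' Screen one expression dataset
#'
#' Computes Z-scores from raw p-values and selects candidate records passing
#' `p_raw <= p_cutoff` and `|z| >= z_cutoff` (both boundaries inclusive).
#'
#' @param records Data frame with `probe_id, gene_symbol, p_raw, p_adj,
#'   log_fc`, or a path readable by [read_expression_table()].
#' @param dataset_id Dataset label (e.g. a GEO series accession).
#' @param p_cutoff Raw-p gate (default 0.001).
#' @param z_cutoff Absolute Z-score criterion (default 5.5).
#' @param sign_by_direction Passed to [z_from_p()].
#' @return Object of class `dataset_screen`: list with `dataset_id`,
#'   `records` (input plus `z`), `significant_ids` (probe ids), thresholds.
#' @export
expression_screen <- function(records, dataset_id, p_cutoff = 0.001,
                              z_cutoff = 5.5, sign_by_direction = FALSE) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_expression_table(records)
  }
  records <- as.data.frame(records)
  records$z <- z_from_p(records$p_raw, records$log_fc, sign_by_direction)
  keep <- records$p_raw <= p_cutoff & abs(records$z) >= z_cutoff
  structure(list(dataset_id = dataset_id, records = records,
                 significant_ids = records$probe_id[keep],
                 p_cutoff = p_cutoff, z_cutoff = z_cutoff),
            class = "dataset_screen")
}

#' @export
print.dataset_screen <- function(x, ...) {
  cat(sprintf("dataset_screen %s: %d records, %d candidates (p <= %g, |z| >= %g)\n",
              x$dataset_id, nrow(x$records), length(x$significant_ids),
              x$p_cutoff, x$z_cutoff))
  invisible(x)
}

#' Re-apply the candidate criteria to a screen
#'
#' @param screen A `dataset_screen`.
#' @param p_cutoff,z_cutoff Thresholds; default to those stored in the screen.
#' @return Character vector of significant probe ids.
#' @export
select_candidates <- function(screen, p_cutoff = screen$p_cutoff,
                              z_cutoff = screen$z_cutoff) {
  r <- screen$records
  r$probe_id[r$p_raw <= p_cutoff & abs(r$z) >= z_cutoff]
}

#' Genes significant in two or more datasets
#'
#' Gene symbols are harmonized case-insensitively; duplicate probe ids inside
#' one dataset are deduplicated keeping the smallest raw p (reported via a
#' message). Only genes significant in at least two distinct datasets are
#' returned, with one evidence row per (dataset, probe).
#'
#' @param screens List of `dataset_screen` objects.
#' @return Data frame `gene`, `dataset_id`, `probe_id`, `p_adj`, sorted by
#'   gene then dataset.
#' @export
cross_dataset_overlap <- function(screens) {
  evidence <- lapply(screens, function(s) {
    r <- s$records[s$records$probe_id %in% s$significant_ids, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    dup <- duplicated(r$probe_id)
    if (any(dup)) {
      message(s$dataset_id, ": deduplicated ", sum(dup),
              " duplicate probe id(s), keeping smallest p")
      r <- r[order(r$probe_id, r$p_raw), ]
      r <- r[!duplicated(r$probe_id), ]
    }
    data.frame(gene = toupper(r$gene_symbol), dataset_id = s$dataset_id,
               probe_id = r$probe_id, p_adj = r$p_adj)
  })
  ev <- do.call(rbind, evidence)
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame(gene = character(0), dataset_id = character(0),
                      probe_id = character(0), p_adj = numeric(0)))
  }
  n_sets <- tapply(ev$dataset_id, ev$gene, function(d) length(unique(d)))
  keep <- names(n_sets)[n_sets >= 2]
  out <- ev[ev$gene %in% keep, , drop = FALSE]
  out <- out[order(out$gene, out$dataset_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
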