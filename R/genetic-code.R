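# Genetic code handling and per-code cached lookup structures.

NUCLEOTIDES <- c("A", "C", "G", "T")
GAP_CODON <- "---"

# cache of derived lookup tables, keyed by the code itself
.code_cache <- new.env(parent = emptyenv())

#' Standard nuclear genetic code
#'
#' Returns the standard genetic code (translation table 1) as a named
#' character vector of length 64: names are trinucleotide codons over
#' `A,C,G,T`, values are one-letter amino-acid symbols with `"*"` marking
#' the three stop codons (TAA, TAG, TGA).
#'
#' @return Named character vector of length 64.
#' @seealso [read_genetic_code()] for loading a non-standard code.
#' @export
#' @examples
#' code <- standard_genetic_code()
#' code[["ATG"]]
standard_genetic_code <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  validate_genetic_code(code)
}

#' Read a genetic-code override table
#'
#' Reads a plain-text genetic code: one `codon<TAB>amino-acid` pair per line
#' (`*` for stop), 64 lines, comments starting with `#` allowed.
#'
#' @param path Path to the table.
#' @return Named character vector of length 64.
#' @export
read_genetic_code <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed genetic-code line(s): ", paste(lines[bad], collapse = "; "))
  }
  code <- vapply(parts, `[`, "", 2L)
  names(code) <- toupper(vapply(parts, `[`, "", 1L))
  validate_genetic_code(code)
}

validate_genetic_code <- function(code) {
  if (length(code) != 64L) {
    stop("a genetic code must have exactly 64 codon entries, got ", length(code))
  }
  all_codons <- apply(expand.grid(NUCLEOTIDES, NUCLEOTIDES, NUCLEOTIDES,
                                  stringsAsFactors = FALSE)[, 3:1],
                      1L, paste0, collapse = "")
  if (!setequal(names(code), all_codons)) {
    stop("genetic code must cover all 64 codons over {A,C,G,T} exactly once")
  }
  if (!any(code == "*")) stop("genetic code has no stop codon")
  code[all_codons]
}

#' Translate codons
#'
#' Maps ungapped trinucleotides to amino-acid symbols under a genetic code.
#' Gap or ambiguous codons are never skipped silently: depending on
#' `on_untranslatable` they raise an error or yield `NA`.
#'
#' @param codons Character vector of trinucleotides.
#' @param code Genetic code from [standard_genetic_code()] (default) or
#'   [read_genetic_code()].
#' @param on_untranslatable `"error"` (default) or `"NA"`.
#' @return Character vector of amino-acid symbols (`"*"` for stop).
#' @export
#' @examples
#' translate_codons(c("ATG", "TTT", "TAA"))
translate_codons <- function(codons, code = standard_genetic_code(),
                             on_untranslatable = c("error", "NA")) {
  on_untranslatable <- match.arg(on_untranslatable)
  codons <- toupper(codons)
  aa <- unname(code[codons])
  bad <- is.na(aa)
  if (any(bad)) {
    if (on_untranslatable == "error") {
      stop("untranslatable codon(s): ",
           paste(unique(codons[bad]), collapse = ", "))
    }
  }
  aa
}

# Derived per-code structures: sense codon list, NG86 site table, and the
# one-step mutation graph used by both the counting and the GY94 machinery.
code_info <- function(code) {
  key <- paste(code, collapse = "")
  hit <- get0(key, envir = .code_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  codons <- names(code)
  sense <- codons[code != "*"]
  ns <- length(sense)
  sense_index <- stats::setNames(seq_len(ns), sense)

  # single-base neighbours of every codon
  codon_chars <- do.call(rbind, strsplit(codons, ""))
  rownames(codon_chars) <- codons

  # NG86 fractional sites per sense codon
  sites <- matrix(0, nrow = ns, ncol = 2,
                  dimnames = list(sense, c("S", "N")))
  for (cd in sense) {
    aa <- code[[cd]]
    s_total <- 0
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      muts <- vapply(setdiff(NUCLEOTIDES, ref), function(nt) {
        x <- cd
        substr(x, pos, pos) <- nt
        x
      }, "")
      maa <- code[muts]
      nonstop <- maa != "*"
      if (any(nonstop)) {
        s_total <- s_total + sum(maa[nonstop] == aa) / sum(nonstop)
      }
    }
    sites[cd, ] <- c(s_total, 3 - s_total)
  }

  # one-difference sense-codon pairs with transition / synonymy flags
  from <- integer(0); to <- integer(0)
  is_ts <- logical(0); is_syn <- logical(0)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(ns)) {
    ci <- sense[i]
    for (pos in 1:3) {
      ref <- substr(ci, pos, pos)
      for (nt in setdiff(NUCLEOTIDES, ref)) {
        cj <- ci
        substr(cj, pos, pos) <- nt
        j <- sense_index[cj]
        if (is.na(j)) next
        from <- c(from, i); to <- c(to, unname(j))
        is_ts <- c(is_ts, transitions[[ref]] == nt)
        is_syn <- c(is_syn, code[[ci]] == code[[cj]])
      }
    }
  }

  info <- list(code = code, codons = codons, sense = sense,
               sense_index = sense_index, n_sense = ns, sites = sites,
               pairs = data.frame(from = from, to = to,
                                  ts = is_ts, syn = is_syn))
  assign(key, info, envir = .code_cache)
  info
}
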