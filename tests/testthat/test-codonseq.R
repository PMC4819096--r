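test_that("genetic code is valid and translation behaves", {
  code <- standard_genetic_code()
  expect_length(code, 64)
  expect_setequal(names(code)[code == "*"], c("TAA", "TAG", "TGA"))
  expect_length(unique(code[code != "*"]), 20)

  expect_equal(translate_codons("ATG"), "M")
  expect_equal(translate_codons("TAA"), "*")
  expect_equal(translate_codons("TTT"), "F")
  expect_error(translate_codons("---"), "untranslatable")
  expect_error(translate_codons("ANG"), "untranslatable")
  expect_equal(translate_codons("NNN", on_untranslatable = "NA"),
               NA_character_)
})

test_that("a genetic-code override file round-trips", {
  code <- standard_genetic_code()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(code), code, sep = "\t"), path)
  expect_identical(read_genetic_code(path), code)
})

test_that("NG86 sites match known codons and conserve to 3", {
  expect_equal(codon_sites("ATG"), c(S_sites = 0, N_sites = 3))
  expect_equal(codon_sites("TGG"), c(S_sites = 0, N_sites = 3))
  expect_equal(codon_sites("TTT"), c(S_sites = 1 / 3, N_sites = 8 / 3))
  expect_error(codon_sites("TAA"), "stop")

  code <- standard_genetic_code()
  sense <- names(code)[code != "*"]
  for (cd in sense) {
    s <- codon_sites(cd, code)
    expect_equal(unname(s[1] + s[2]), 3)
  }
})

test_that("pathway-averaged differences match examples and are symmetric", {
  expect_equal(codon_differences("TTT", "TTC"),
               c(S_diff = 1, N_diff = 0), ignore_attr = TRUE)
  expect_equal(codon_differences("AAA", "AAA"),
               c(S_diff = 0, N_diff = 0), ignore_attr = TRUE)
  # two pathways: TTT->GTT->GTA (1 syn after nonsyn? no: both counted),
  # average of (1,1) and (0,2)
  expect_equal(codon_differences("TTT", "GTA"),
               c(S_diff = 0.5, N_diff = 1.5), ignore_attr = TRUE)

  code <- standard_genetic_code()
  set.seed(42)
  sense <- names(code)[code != "*"]
  for (i in 1:50) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    expect_equal(codon_differences(a, b, code),
                 codon_differences(b, a, code))
  }
})

test_that("pathway counts equal the exhaustive pathway oracle on all sense pairs", {
  code <- standard_genetic_code()
  sense <- names(code)[code != "*"]
  for (a in sense) {
    for (b in sense) {
      got <- codon_differences(a, b, code)
      want <- oracle_pathway_counts(a, b, code)
      expect_equal(unname(got[["S_diff"]]), unname(want[["S"]]),
                   tolerance = 1e-12)
      expect_equal(unname(got[["N_diff"]]), unname(want[["N"]]),
                   tolerance = 1e-12)
      expect_identical(attr(got, "countable"), want[["n_paths"]] > 0)
      # pathway conservation: S + N equals positional Hamming distance
      if (want[["n_paths"]] > 0) {
        hd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
        expect_equal(unname(got[["S_diff"]] + got[["N_diff"]]), hd)
      }
    }
  }
})

test_that("codon_alignment validates shape, alphabet and frame", {
  expect_error(codon_alignment(c(a = "ATG", b = "ATGA")), "equal length")
  expect_error(codon_alignment(c(a = "ATGA", b = "ATGA")), "divisible by 3")
  expect_error(codon_alignment(c(a = "ATN", b = "ATG")), "outside")
  expect_error(codon_alignment(c(a = "AT-GCC", b = "ATGGCC")),
               "frame-breaking")
  expect_error(codon_alignment(c("ATG", "ATG")), "named")

  aln <- codon_alignment(c(a = "ATG---", b = "ATGGCC"))
  expect_equal(aln$codons["a", ], c("ATG", "---"))
  expect_equal(aln$length_nt, 6L)
})

test_that("FASTA round-trip preserves the alignment", {
  aln <- codon_alignment(c(human = "ATGTTTAAACCC", mouse = "ATGTTC---CCC"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln, path)
  back <- read_codon_alignment(path)
  expect_identical(as.character(back), as.character(aln))
})

test_that("coverage filter keeps exactly the columns at or above threshold", {
  # 10 taxa, 4 codon columns at coverages 1.0, 0.5, 0.3, 0.2
  gap_pattern <- list(c1 = rep(FALSE, 10),
                      c2 = rep(c(FALSE, TRUE), 5),
                      c3 = c(rep(FALSE, 3), rep(TRUE, 7)),
                      c4 = c(rep(FALSE, 2), rep(TRUE, 8)))
  seqs <- vapply(1:10, function(i) {
    paste0(vapply(gap_pattern, function(g) {
      if (g[i]) "---" else "ATG"
    }, ""), collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:10)
  aln <- codon_alignment(seqs)
  filt <- filter_columns_by_coverage(aln, 0.35)
  expect_equal(ncol(filt$codons), 2L)
  expect_equal(attr(filt, "removed_columns"), c(3L, 4L))

  # fully ungapped alignment unchanged at any threshold
  full <- codon_alignment(c(a = "ATGTTT", b = "ATGTTC"))
  expect_equal(ncol(filter_columns_by_coverage(full, 1)$codons), 2L)
  # all-gap columns always removed
  gappy <- codon_alignment(c(a = "---ATG", b = "---ATG"))
  expect_equal(ncol(filter_columns_by_coverage(gappy, 0.35)$codons), 1L)
  expect_error(filter_columns_by_coverage(gappy, 0), "min_coverage")
})

test_that("pairwise counts sum per-codon values and respect symmetry", {
  # identical 10-codon sequences
  s <- paste(rep("ATG", 10), collapse = "")
  cnt <- pairwise_codon_counts(codon_alignment(c(a = s, b = s)))
  expect_equal(cnt$S_diff, 0)
  expect_equal(cnt$N_diff, 0)
  expect_equal(cnt$S_sites + cnt$N_sites, 30)

  # one synonymous change
  cnt2 <- pairwise_codon_counts(codon_alignment(c(a = "TTTATG",
                                                  b = "TTCATG")))
  expect_equal(cnt2$S_diff, 1)
  expect_equal(cnt2$N_diff, 0)

  # engineered 5-codon pair: totals equal per-codon oracle sums
  a <- c("TTT", "AAA", "GGG", "TTT", "ATG")
  b <- c("GTA", "AAG", "GGG", "TTC", "ATG")
  cnt3 <- pairwise_codon_counts(seq_a = a, seq_b = b)
  code <- standard_genetic_code()
  want_s <- sum(vapply(1:5, function(i) {
    oracle_pathway_counts(a[i], b[i], code)[["S"]]
  }, 0))
  want_n <- sum(vapply(1:5, function(i) {
    oracle_pathway_counts(a[i], b[i], code)[["N"]]
  }, 0))
  expect_equal(cnt3$S_diff, want_s)
  expect_equal(cnt3$N_diff, want_n)

  # symmetry in sequence arguments
  cnt4 <- pairwise_codon_counts(seq_a = b, seq_b = a)
  expect_equal(cnt4$S_diff, cnt3$S_diff)
  expect_equal(cnt4$N_diff, cnt3$N_diff)
  expect_equal(cnt4$S_sites, cnt3$S_sites)

  # gap and stop columns are skipped and tallied
  cnt5 <- pairwise_codon_counts(seq_a = c("ATG", "---", "TAA"),
                                seq_b = c("ATG", "AAA", "AAA"))
  expect_equal(cnt5$codons_compared, 1L)
  expect_equal(cnt5$skipped, 2L)
  expect_error(pairwise_codon_counts(seq_a = "---", seq_b = "ATG"),
               "no comparable")
})
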