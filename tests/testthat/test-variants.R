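test_that("coding changes classify by codon translation", {
  expect_equal(classify_coding_change("TTTAAA", 3, "T", "C")$effect,
               "synonymous")
  r <- classify_coding_change("TTTAAA", 1, "T", "G")
  expect_equal(r$effect, "missense")
  expect_equal(r$ref_aa, "F")
  expect_equal(r$alt_aa, "V")
  expect_equal(r$residue_position, 1)
  expect_equal(classify_coding_change("TGGAAA", 3, "G", "A")$effect,
               "nonsense")
  expect_error(classify_coding_change("TTTAAA", 2, "A", "C"),
               "reference mismatch at CDS position 2")
  expect_error(classify_coding_change("TTTA", 1, "T", "C"), "divisible")
  expect_error(classify_coding_change("TTT", 9, "T", "C"), "outside")
})

test_that("classification agrees with full-CDS translation diffing", {
  code <- standard_genetic_code()
  set.seed(17)
  sense <- names(code)[code != "*"]
  cds <- paste0(sample(sense, 30, replace = TRUE), collapse = "")
  for (i in 1:80) {
    pos <- sample(nchar(cds), 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_coding_change(cds, pos, ref, alt)$effect
    # oracle: translate both full sequences and diff the proteins
    mut <- cds
    substr(mut, pos, pos) <- alt
    tr <- function(s) {
      vapply(seq(1, nchar(s), 3),
             function(j) code[[substr(s, j, j + 2)]], "")
    }
    p0 <- tr(cds); p1 <- tr(mut)
    want <- if (identical(p0, p1)) "synonymous"
            else if (any(p1 != p0 & p1 == "*")) "nonsense"
            else "missense"
    expect_equal(got, want)
  }
})

test_that("SIFT calls use the inclusive 0.05 boundary", {
  expect_equal(sift_call(0.05), "damaging")
  expect_equal(sift_call(0.051), "tolerated")
  expect_equal(sift_call(0), "damaging")
  expect_equal(sift_call(1), "tolerated")
  expect_error(sift_call(1.2), "\\[0, 1\\]")
  expect_error(sift_call(-0.1), "\\[0, 1\\]")
})

test_that("consensus tolerance follows the two-tool rule", {
  expect_equal(consensus_tolerance(0.4, "benign"), "tolerated_consensus")
  expect_equal(consensus_tolerance(0.01, "probably_damaging", "high"),
               "damaging_consensus")
  # low-confidence probably_damaging is excluded from the damaging consensus
  expect_equal(consensus_tolerance(0.01, "probably_damaging", "low"),
               "discordant")
  expect_equal(consensus_tolerance(0.01, "benign"), "discordant")
  expect_equal(consensus_tolerance(0.4, "possibly_damaging"), "discordant")
  expect_true(is.na(consensus_tolerance(NA, "benign")))
  expect_true(is.na(consensus_tolerance(0.4, NA)))
  expect_error(consensus_tolerance(0.4, "bad_call"), "unknown PolyPhen")
})

test_that("tolerance summaries partition variants and ignore input order", {
  v <- data.frame(
    gene = "VGF",
    effect = "missense",
    tolerance = c("tolerated_consensus", "tolerated_consensus",
                  "damaging_consensus", "discordant", NA))
  s <- tolerance_summary(v)
  expect_equal(s$n_variants, 4)
  expect_equal(s$n_tolerated_consensus + s$n_damaging_consensus +
                 s$n_discordant, s$n_variants)
  expect_equal(s$n_missing_prediction, 1)
  expect_equal(s$fraction_tolerated, 0.5)
  s_perm <- tolerance_summary(v[sample(nrow(v)), ])
  expect_equal(s, s_perm, ignore_attr = TRUE)
})

test_that("gene tolerance comparison reuses the exact Fisher test", {
  s <- data.frame(gene = c("VGF", "CALR"),
                  n_damaging_consensus = c(12, 3),
                  n_tolerated_consensus = c(3, 12))
  cmp <- compare_gene_tolerance(s)
  expect_equal(cmp$p_two_sided, oracle_fet_p(12, 3, 3, 12), tolerance = 1e-9)

  same <- data.frame(gene = c("A", "B"),
                     n_damaging_consensus = c(5, 5),
                     n_tolerated_consensus = c(7, 7))
  expect_equal(compare_gene_tolerance(same)$p_two_sided, 1)
  expect_error(compare_gene_tolerance(s[1, ]), "at least two")
})

test_that("MK polymorphism counting honors validation and nonsense flags", {
  v <- data.frame(effect = c("missense", "missense", "synonymous",
                             "nonsense", "synonymous"),
                  validated = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(mk_polymorphism_counts(v), c(Pn = 1, Ps = 2))
  expect_equal(mk_polymorphism_counts(v, validated_only = FALSE),
               c(Pn = 2, Ps = 2))
  expect_equal(mk_polymorphism_counts(v, include_nonsense = TRUE),
               c(Pn = 2, Ps = 2))
})

test_that("variant tables round-trip and annotate", {
  cds <- "ATGTTTAAACCC"
  df <- data.frame(gene = "X", variant_id = c("rs1", "rs2"),
                   cds_position = c(6, 7), ref = c("T", "A"),
                   alt = c("C", "C"), sift_score = c(0.3, 0.01),
                   polyphen_call = c("benign", "probably_damaging"),
                   polyphen_confidence = c("high", "high"),
                   validated = c(TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- annotate_variants(read_variant_table(path), cds)
  expect_equal(v$effect, c("synonymous", "missense"))
  expect_equal(v$residue_position, c(2, 3))
  expect_equal(v$tolerance, c("tolerated_consensus", "damaging_consensus"))
})
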