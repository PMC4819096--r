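# End-to-end orchestration: expression screen -> per-gene MK test, site-model
# LRT, running dN/dS with regions and variants, tolerance summary -> ranked
# candidate report.

#' Pipeline configuration
#'
#' Bundles input paths and thresholds for [run_pipeline()]. Thresholds are
#' validated against their documented ranges and echoed into every output's
#' metadata.
#'
#' @param expression Named character vector/list: dataset id -> path of a
#'   differential-expression TSV ([read_expression_table()] schema).
#' @param genes Named list: gene symbol -> list with elements `alignment`
#'   (FASTA path) and `variants` (TSV path, [read_variant_table()] schema).
#' @param tree Path to a newick tree covering the alignment taxa.
#' @param regions Optional path to a region TSV with columns
#'   `gene, name, start, end` (1-based inclusive residues).
#' @param mk_pair Two taxon labels used for the divergence comparison
#'   (reference first); default `c("human", "mouse")`.
#' @param p_cutoff Raw-p gate for the screen (default 0.001).
#' @param z_cutoff Absolute Z criterion (default 5.5).
#' @param alpha Significance level for MK and LRT (default 0.05).
#' @param sift_cutoff SIFT damaging threshold (default 0.05).
#' @param window,pseudocount Running dN/dS settings (defaults 10, 0.5).
#' @param K Beta discretization categories (default 10).
#' @param min_coverage Column-coverage filter (default 0.35).
#' @param site_model_null,site_model_alt Nested site-model pair fitted per
#'   gene (defaults `"M1a"`/`"M2a"`).
#' @param seed Integer seed used for optimizer start jitter.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(expression, genes, tree, regions = NULL,
                       mk_pair = c("human", "mouse"), p_cutoff = 0.001,
                       z_cutoff = 5.5, alpha = 0.05, sift_cutoff = 0.05,
                       window = 10, pseudocount = 0.5, K = 10,
                       min_coverage = 0.35, site_model_null = "M1a",
                       site_model_alt = "M2a", seed = 1, out_dir = NULL) {
  stopifnot(p_cutoff > 0, p_cutoff <= 1, z_cutoff >= 0,
            alpha > 0, alpha < 1, sift_cutoff >= 0, sift_cutoff <= 1,
            window >= 0, pseudocount >= 0, K >= 1,
            min_coverage > 0, min_coverage <= 1, length(mk_pair) == 2)
  structure(list(expression = as.list(expression), genes = genes,
                 tree = tree, regions = regions, mk_pair = mk_pair,
                 p_cutoff = p_cutoff, z_cutoff = z_cutoff, alpha = alpha,
                 sift_cutoff = sift_cutoff, window = window,
                 pseudocount = pseudocount, K = K,
                 min_coverage = min_coverage,
                 site_model_null = site_model_null,
                 site_model_alt = site_model_alt,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

analyze_gene <- function(gene, spec, tree, regions, config) {
  aln <- read_codon_alignment(spec$alignment)
  aln <- filter_columns_by_coverage(aln, config$min_coverage)
  ref <- config$mk_pair[1]; other <- config$mk_pair[2]
  if (!all(config$mk_pair %in% aln$taxa)) {
    stop("alignment for ", gene, " lacks taxa ",
         paste(config$mk_pair, collapse = "/"))
  }
  counts <- pairwise_codon_counts(aln, ref, other)

  variants <- read_variant_table(spec$variants)
  cds <- gsub("-", "", as.character(aln)[[ref]])
  variants <- annotate_variants(variants, cds)
  poly <- mk_polymorphism_counts(variants)
  mk <- mk_test(poly[["Pn"]], poly[["Ps"]], counts, alpha = config$alpha)

  gene_tree <- ape::keep.tip(tree, aln$taxa)
  cmp <- compare_site_models(aln, gene_tree, null = config$site_model_null,
                             alt = config$site_model_alt, K = config$K,
                             alpha = config$alpha,
                             jitter_seed = derive_seed(config$seed, 7L))
  pos_sites <- neb_positive_sites(cmp$alt_fit)

  # per-codon counts reindexed to reference residues (reference gaps dropped)
  ref_ungapped <- aln$codons[ref, ] != GAP_CODON
  per_codon <- counts$per_codon[ref_ungapped, , drop = FALSE]
  track <- running_dnds(per_codon, window = config$window,
                        pseudocount = config$pseudocount)
  gene_regions <- regions[regions$gene == gene, , drop = FALSE]
  region_summary <- summarize_regions(
    track, peptide_regions(gene_regions$name, gene_regions$start,
                           gene_regions$end),
    global_omega = counts$omega)
  overlay <- overlay_variants(
    track, peptide_regions(gene_regions$name, gene_regions$start,
                           gene_regions$end),
    variants)
  variants$gene <- gene
  tol <- tolerance_summary(variants)

  list(gene = gene, alignment = aln, counts = counts, variants = variants,
       mk = mk, site_models = cmp, positive_sites = pos_sites,
       track = track, region_summary = region_summary, overlay = overlay,
       tolerance = tol)
}

#' Run the full candidate-gene pipeline
#'
#' Executes the stages in dependency order: per-dataset expression screen and
#' cross-dataset overlap, then per gene the divergence counting, MK test,
#' nested site-model LRT, running dN/dS with regions and variant overlay, and
#' tolerance summary; finally assembles a ranked candidate report. A failure
#' in one gene is isolated: the other genes complete and the failure is
#' recorded.
#'
#' Candidates are ranked lexicographically (an artifact convention): MK
#' significance first, then LRT significance, then consensus-damaging variant
#' fraction, then MK p-value, then gene name.
#'
#' @param config A [run_config()].
#' @return Object of class `candidate_report`: list with `report` (ranked
#'   data frame), `screens`, `overlap`, `genes` (per-gene results),
#'   `failures` (named character vector of error messages), `config`.
#'   When `config$out_dir` is set, writes `report.tsv`, `screen_candidates.tsv`,
#'   `overlap.tsv`, `region_summary.tsv`, `tolerance.tsv`, `tracks.tsv`,
#'   `overlays.tsv` and `metadata.json` (the only file carrying a timestamp).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  screens <- lapply(names(config$expression), function(d) {
    expression_screen(config$expression[[d]], dataset_id = d,
                      p_cutoff = config$p_cutoff, z_cutoff = config$z_cutoff)
  })
  names(screens) <- names(config$expression)
  overlap <- cross_dataset_overlap(screens)

  screen_evidence <- do.call(rbind, lapply(screens, function(s) {
    r <- s$records[s$records$probe_id %in% s$significant_ids, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    data.frame(gene = toupper(r$gene_symbol), dataset_id = s$dataset_id,
               probe_id = r$probe_id, p_raw = r$p_raw, p_adj = r$p_adj,
               z = r$z)
  }))

  tree <- ape::read.tree(config$tree)
  regions <- if (!is.null(config$regions)) {
    utils::read.delim(config$regions, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), name = character(0),
               start = integer(0), end = integer(0))
  }

  genes <- list(); failures <- character(0)
  for (g in names(config$genes)) {
    res <- tryCatch(analyze_gene(g, config$genes[[g]], tree, regions, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[g] <- conditionMessage(res)
    } else {
      genes[[g]] <- res
    }
  }

  rows <- lapply(genes, function(r) {
    ev <- screen_evidence[screen_evidence$gene == toupper(r$gene), ,
                          drop = FALSE]
    tol <- r$tolerance
    frac_dam <- if (nrow(tol) && tol$n_variants[1] > 0) {
      tol$n_damaging_consensus[1] / tol$n_variants[1]
    } else 0
    data.frame(
      gene = r$gene,
      n_datasets_significant = length(unique(ev$dataset_id)),
      min_p_adj = if (nrow(ev)) min(ev$p_adj) else NA_real_,
      mk_p = r$mk$fet$p_two_sided,
      neutrality_index = r$mk$neutrality_index,
      mk_significant = r$mk$significant,
      lrt_statistic = r$site_models$lrt$statistic,
      lrt_significant = r$site_models$lrt$significant,
      n_positive_sites = nrow(r$positive_sites),
      fraction_damaging = frac_dam,
      fraction_tolerated = if (nrow(tol)) tol$fraction_tolerated[1] else NA,
      n_conserved_regions = sum(r$region_summary$conserved, na.rm = TRUE))
  })
  report <- do.call(rbind, rows)
  if (!is.null(report) && nrow(report)) {
    ord <- order(-report$mk_significant, -report$lrt_significant,
                 -report$fraction_damaging, report$mk_p, report$gene)
    report <- report[ord, , drop = FALSE]
    report$rank <- seq_len(nrow(report))
    rownames(report) <- NULL
  }

  out <- structure(list(report = report, screens = screens,
                        overlap = overlap, screen_evidence = screen_evidence,
                        genes = genes, failures = failures, config = config),
                   class = "candidate_report")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate_report:", length(x$genes), "gene(s) analyzed,",
      length(x$failures), "failure(s)\n")
  if (is.null(x$report) || nrow(x$report) == 0) {
    cat("  no candidates\n")
  } else {
    print(x$report[, c("rank", "gene", "mk_p", "neutrality_index",
                       "lrt_statistic", "fraction_damaging")])
  }
  if (length(x$failures)) {
    cat("failures:\n")
    for (g in names(x$failures)) cat("  ", g, ": ", x$failures[g], "\n")
  }
  invisible(x)
}

num_fmt <- function(df) {
  # fixed, locale-independent formatting so identical runs are byte-identical
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.10g", df[[nm]])
  }
  df
}

#' Write a candidate report to disk
#'
#' All analysis tables are written deterministically (re-running with the
#' same inputs and seed is byte-identical); the timestamp lives only in
#' `metadata.json` alongside a verbatim echo of the configuration.
#'
#' @param x A `candidate_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(x$report) && nrow(x$report)) {
    write_tsv(num_fmt(x$report), file.path(dir, "report.tsv"))
  } else {
    writeLines("# no candidates", file.path(dir, "report.tsv"))
  }
  if (!is.null(x$screen_evidence) && NROW(x$screen_evidence)) {
    write_tsv(num_fmt(x$screen_evidence),
              file.path(dir, "screen_candidates.tsv"))
  }
  write_tsv(num_fmt(x$overlap), file.path(dir, "overlap.tsv"))
  bind_gene <- function(field) {
    do.call(rbind, lapply(x$genes, function(r) {
      df <- as.data.frame(r[[field]])
      if (nrow(df)) cbind(gene = r$gene, df) else NULL
    }))
  }
  for (f in c("region_summary", "tolerance", "track", "overlay")) {
    df <- bind_gene(if (f == "track") "track" else f)
    if (!is.null(df)) {
      write_tsv(num_fmt(df),
                file.path(dir, paste0(sub("track", "tracks",
                                          sub("overlay", "overlays", f)),
                                      ".tsv")))
    }
  }
  meta <- list(timestamp = format(Sys.time(), tz = "UTC"),
               package_version = as.character(utils::packageVersion("evoscreen")),
               seed = x$config$seed,
               config = x$config[setdiff(names(x$config), "out_dir")],
               failures = as.list(x$failures))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Generate a complete synthetic study
#'
#' Writes every input the pipeline consumes — expression tables with a
#' planted candidate spiked in several datasets, codon alignments simulated
#' on a shared tree, SNP tables, peptide regions, and the tree — with known
#' ground truth. The planted candidate gene gets a strongly conserved
#' divergence history combined with an excess of damaging nonsynonymous
#' polymorphism (a significant MK departure); background genes' polymorphism
#' spectrum mirrors their own realized divergence spectrum, the neutral
#' expectation.
#'
#' @param dir Directory to write into (created).
#' @param seed Integer master seed; all generators derive their streams from
#'   it.
#' @param n_universe Size of the expression gene universe (default 2000).
#' @param n_datasets Expression datasets (default 4).
#' @param n_codons Codons per simulated gene alignment (default 120).
#' @param n_background Background genes analyzed alongside the candidate
#'   (default 2).
#' @return A [run_config()] pointing at the generated files; the planted
#'   candidate symbol is in attribute `"candidate"`.
#' @export
simulate_study <- function(dir, seed = 1, n_universe = 2000, n_datasets = 4,
                           n_codons = 120, n_background = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sprintf("G%05d", seq_len(n_background + 1))
  candidate <- genes[1]

  # expression: spike the analyzed genes plus a few decoys in >= 2 datasets
  decoys <- sprintf("G%05d", seq(n_background + 2, n_background + 6))
  tabs <- simulate_expression_tables(
    n_genes = n_universe, n_datasets = n_datasets,
    spike_genes = c(genes, decoys), spike_datasets = 2,
    seed = derive_seed(seed, 1L))
  expr_paths <- vapply(names(tabs), function(d) {
    p <- file.path(dir, paste0(d, ".tsv"))
    write_tsv(tabs[[d]], p)
    p
  }, "")

  tree_txt <- paste0(
    "((human:0.06,chimp:0.06):0.12,((mouse:0.18,rat:0.18):0.10,",
    "(dog:0.16,cat:0.16):0.08):0.05,(cow:0.20,pig:0.20):0.06);")
  tree_path <- file.path(dir, "tree.nwk")
  writeLines(tree_txt, tree_path)
  tree <- ape::read.tree(text = tree_txt)

  gene_specs <- list(); regions <- NULL
  for (i in seq_along(genes)) {
    g <- genes[i]
    gseed <- derive_seed(seed, 10L + i)
    omega_div <- if (g == candidate) 0.10 else 0.35
    sim <- simulate_codon_alignment(tree, n_codons, kappa = 2,
                                    omega = omega_div, seed = gseed)
    aln_path <- file.path(dir, paste0(g, "_alignment.fasta"))
    write_codon_alignment(sim$alignment, aln_path)

    cds <- as.character(sim$alignment)[["human"]]
    if (g == candidate) {
      # excess poorly tolerated nonsynonymous polymorphism
      snps <- simulate_snp_table(
        cds, n_variants = 45,
        effect_mix = c(synonymous = 0.15, missense = 0.85),
        sift_sampler = function(n) stats::runif(n, 0, 0.04),
        polyphen_probs = c(0.05, 0.1, 0.85),
        p_validated = 1, seed = gseed)
    } else {
      # polymorphism mirroring this gene's own divergence spectrum
      cnt <- pairwise_codon_counts(sim$alignment, "human", "mouse")
      tot <- cnt$N_diff + cnt$S_diff
      mix <- if (tot > 0) {
        c(synonymous = cnt$S_diff / tot, missense = cnt$N_diff / tot)
      } else {
        c(synonymous = 0.5, missense = 0.5)
      }
      snps <- simulate_snp_table(
        cds, n_variants = 40, effect_mix = mix,
        sift_sampler = function(n) stats::runif(n, 0.1, 1),
        polyphen_probs = c(0.8, 0.15, 0.05),
        p_validated = 1, seed = gseed)
    }
    snps$gene <- g
    var_path <- file.path(dir, paste0(g, "_variants.tsv"))
    write_tsv(snps[c("gene", "variant_id", "cds_position", "ref", "alt",
                     "sift_score", "polyphen_call", "polyphen_confidence",
                     "validated")], var_path)
    gene_specs[[g]] <- list(alignment = aln_path, variants = var_path)

    pepb_start <- as.integer(round(n_codons * 0.6))
    regions <- rbind(regions, data.frame(
      gene = g,
      name = c("PEP-A", "PEP-A-core", "PEP-B"),
      start = c(10L, 14L, pepb_start),
      end = c(30L, 24L, min(pepb_start + 20L, n_codons))))
  }
  regions_path <- file.path(dir, "regions.tsv")
  write_tsv(regions, regions_path)

  cfg <- run_config(expression = as.list(expr_paths), genes = gene_specs,
                    tree = tree_path, regions = regions_path, seed = seed)
  attr(cfg, "candidate") <- candidate
  cfg
}
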