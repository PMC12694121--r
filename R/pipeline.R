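#' Simulate a complete BSA-seq dataset on disk
#'
#' Runs [simulate_f2()] and [emit_dataset()] end to end.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return List `truth`, `manifest`, `paths`, `pools`, `gene_models`.
#' @export
run_simulate <- function(config, out_dir) {
  truth <- simulate_f2(config)
  emitted <- emit_dataset(truth, config, out_dir)
  c(list(truth = truth), emitted)
}

#' Run the full association scan pipeline
#'
#' Filter the pooled VCF, compute per-site SNP-index / Delta / ED
#' statistics, call candidate regions with both methods, intersect them,
#' pick candidate SNPs, annotate their location and coding effect, extract
#' candidate genes and (optionally) prioritise them by tissue expression.
#'
#' @param vcf,gff,fasta Input file paths (or pre-read objects for `gff` /
#'   `fasta`: a gene-model tibble / `DNAStringSet`).
#' @param sample_map Sample-to-role map for [read_pooled_vcf()].
#' @param filter_cfg A [filter_config()].
#' @param scan_cfg A [scan_config()].
#' @param expression Optional expression matrix (path or tibble).
#' @param target_tissue Tissue used for prioritisation (default `"spike"`).
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV.
#' @return Object of class `bsa_scan_result` with components `records`,
#'   `scan`, `delta_windows`, `delta_regions`, `ed_regions`,
#'   `ed_threshold`, `intersection`, `candidate_snps`, `annotated`,
#'   `genes`, `prioritized`, `counts` (the stage-by-stage tally chain) and
#'   the configurations used.
#' @export
run_scan <- function(vcf, gff, fasta,
                     sample_map = c(P_WT = "parent_wt", P_MUT = "parent_mut",
                                    POOL_SHORT = "pool_short",
                                    POOL_LONG = "pool_long"),
                     filter_cfg = filter_config(),
                     scan_cfg = scan_config(),
                     expression = NULL, target_tissue = "spike",
                     out_dir = NULL) {
  records <- read_pooled_vcf(vcf, sample_map)
  gene_models <- if (is_tibble(gff)) gff else read_gff(gff)
  genome <- as_genome(fasta)

  filtered <- filter_variants(records, filter_cfg)
  scan <- compute_scan(filtered, scan_cfg)
  scan_kept <- filter_offspring_index(scan, scan_cfg$offspring_index_floor,
                                      scan_cfg$index_floor_mode)

  # Delta(SNP-index) windowed scan
  windows <- smooth_delta(scan_kept, scan_cfg$delta_window_bp,
                          scan_cfg$delta_step_bp,
                          scan_cfg$min_markers_per_region)
  delta_thr <- if (nrow(windows) == 0L) {
    NA_real_
  } else if (scan_cfg$delta_mode == "absolute") {
    scan_cfg$delta_threshold
  } else {
    quantile(windows$mean_abs_delta, scan_cfg$delta_threshold,
             na.rm = TRUE, names = FALSE)
  }
  delta_regions <- if (nrow(windows) == 0L) empty_region_tibble() else
    call_regions(windows, delta_thr, "mean_abs_delta",
                 scan_cfg$min_markers_per_region, scan_cfg$max_gap_bp,
                 method = "snp_index")

  # ED scan
  fitted <- if (nrow(scan_kept) > 0L) {
    fit_ed(scan_kept, scan_cfg$ed_power, scan_cfg$ed_span)
  } else {
    mutate(scan_kept, fitted_ed = numeric(0))
  }
  ed_thr <- if (all(is.na(fitted$fitted_ed))) NA_real_ else
    ed_threshold(fitted$fitted_ed, scan_cfg$ed_k)
  ed_regions <- if (is.na(ed_thr)) empty_region_tibble() else
    call_regions(fitted, ed_thr, "fitted_ed",
                 scan_cfg$min_markers_per_region, scan_cfg$max_gap_bp,
                 method = "ed")
  ed_candidates <- select_candidate_snps(fitted, ed_regions,
                                         scan_cfg$maf_min, scan_cfg$ed_min)

  intersection <- intersect_region_sets(delta_regions, ed_regions)
  snps_final <- snps_in_regions(ed_candidates, intersection)

  annotated <- if (nrow(snps_final) > 0L) {
    annotate_effects(mutate(snps_final, variant_class = "SNP"),
                     gene_models, genome)
  } else {
    NULL
  }
  snps_for_genes <- if (is.null(annotated)) snps_final else
    left_join(snps_final,
              annotated[, c("chrom", "pos", "gene_id")],
              by = c("chrom", "pos"))
  genes <- genes_in_regions(intersection, gene_models,
                            snps = snps_for_genes)
  prioritized <- NULL
  if (!is.null(expression) && nrow(genes) > 0L) {
    expr <- if (is_tibble(expression)) expression else
      read_expression_matrix(expression)
    prioritized <- prioritize_by_expression(genes, expr, target_tissue)
  }

  counts <- tibble(
    stage = c("input_variants", "snps", "indels", "after_site_filters",
              "scan_sites", "after_index_floor", "delta_regions",
              "ed_regions", "intersection_regions", "candidate_snps",
              "candidate_genes"),
    n = c(nrow(records), sum(records$variant_class == "SNP"),
          sum(records$variant_class == "InDel"), nrow(filtered),
          nrow(scan), nrow(scan_kept), nrow(delta_regions),
          nrow(ed_regions), nrow(intersection), nrow(snps_final),
          nrow(genes))
  )

  res <- structure(list(
    records = records, filter_tally = attr(filtered, "filter_tally"),
    scan = scan_kept, delta_windows = windows,
    delta_threshold = delta_thr, delta_regions = delta_regions,
    fitted = fitted, ed_threshold = ed_thr, ed_regions = ed_regions,
    ed_candidates = ed_candidates,
    intersection = intersection, candidate_snps = snps_final,
    annotated = annotated, genes = genes, prioritized = prioritized,
    counts = counts, filter_cfg = filter_cfg, scan_cfg = scan_cfg
  ), class = "bsa_scan_result")
  if (!is.null(out_dir)) write_scan_outputs(res, out_dir)
  res
}

write_scan_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) readr::write_tsv(df, file.path(out_dir, name))
  }
  region_cols <- function(df) {
    if (nrow(df) == 0L) return(df)
    select(df, Chrom = "chrom", Start = "start", End = "end",
           `Length (bp)` = "length_bp", any_of(c("n_markers", "method")))
  }
  w(res$fitted, "scan.tsv")
  w(region_cols(res$delta_regions), "delta_regions.tsv")
  w(region_cols(res$ed_regions), "ed_regions.tsv")
  w(region_cols(res$intersection), "intersection_regions.tsv")
  w(res$candidate_snps, "candidate_snps.tsv")
  w(res$annotated, "candidate_snp_effects.tsv")
  w(res$genes, "candidate_genes.tsv")
  w(res$prioritized, "prioritized_genes.tsv")
  w(res$counts, "run_log_counts.tsv")
  w(res$filter_tally, "filter_tally.tsv")
  invisible(out_dir)
}

#' @export
print.bsa_scan_result <- function(x, ...) {
  cat("<bsa_scan_result>\n")
  print(x$counts, n = Inf)
  invisible(x)
}

#' @export
tidy.bsa_scan_result <- function(x, ...) {
  bind_rows(x$delta_regions, x$ed_regions, x$intersection)
}

#' @export
glance.bsa_scan_result <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "n")
}

#' Design and validate KASP assays for candidate SNPs
#'
#' For each locus, extracts the 150 bp flanks from the genome, designs an
#' allele-specific assay under the given constraints and -- when
#' fluorescence readings are supplied -- calls genotypes and tests the
#' genotype-phenotype association.
#'
#' @param loci Tibble `chrom`, `pos`, `ref`, `alt`.
#' @param genome FASTA path, named character or `DNAStringSet`.
#' @param constraints A [kasp_constraints()].
#' @param fluorescence Optional tibble `sample_id`, `fam`, `hex` (one
#'   marker) for genotyping; design-only mode without it.
#' @param phenotypes Optional phenotype tibble for the association test.
#' @param flank_bp Flank half-width (default 150).
#' @return Object of class `kasp_result`: `assays` (list of
#'   [design_kasp()] results), `report` (tibble, one row per locus),
#'   `genotypes`, `association`.
#' @export
run_kasp <- function(loci, genome, constraints = kasp_constraints(),
                     fluorescence = NULL, phenotypes = NULL,
                     flank_bp = 150L) {
  g <- as_genome(genome)
  assays <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    pos <- loci$pos[i]
    snp_id <- sprintf("KASP-%s-%d", chrom, pos)
    lo <- pos - flank_bp
    hi <- pos + flank_bp
    if (is.null(g[[chrom]]) || lo < 1L || hi > length(g[[chrom]])) {
      assays[[i]] <- structure(
        list(snp_id = snp_id, feasible = FALSE, primers = NULL,
             product_length = NA_integer_, flank_copies = NA_integer_,
             tm_spread = NA_real_, reasons = "flank outside the genome"),
        class = "kasp_assay")
      next
    }
    flank <- as.character(Biostrings::subseq(g[[chrom]], lo, hi))
    assays[[i]] <- design_kasp(flank, c(loci$ref[i], loci$alt[i]), g,
                               constraints, snp_id = snp_id)
  }
  report <- map_dfr(assays, function(a) {
    tibble(snp_id = a$snp_id, feasible = a$feasible,
           product_length = a$product_length,
           flank_copies = a$flank_copies,
           tm_spread = a$tm_spread,
           reasons = paste(a$reasons, collapse = "; "))
  })
  genotypes <- NULL
  association <- NULL
  if (!is.null(fluorescence)) {
    genotypes <- call_genotypes(fluorescence)
    if (!is.null(phenotypes)) {
      association <- association_test(genotypes, phenotypes)
    }
  }
  structure(list(assays = assays, report = report,
                 genotypes = genotypes, association = association),
            class = "kasp_result")
}

#' @export
print.kasp_result <- function(x, ...) {
  cat("<kasp_result>", sum(x$report$feasible), "of", nrow(x$report),
      "assay(s) feasible\n")
  print(x$report)
  if (!is.null(x$association)) print(x$association)
  invisible(x)
}
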