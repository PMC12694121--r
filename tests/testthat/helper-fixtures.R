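# shared fixture builders; everything is generated in code at test time

quiet_filter <- function(...) suppressMessages(filter_variants(...))
quiet_scan <- function(...) suppressMessages(compute_scan(...))

# random pooled variant records with homozygous divergent parents
random_records <- function(n, seed = 1, depth = 40L) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  rand_depth <- function() rpois(n, depth)
  short_alt <- rbinom(n, depth, runif(n))
  long_alt <- rbinom(n, depth, runif(n))
  tibble::tibble(
    chrom = sample(c("c1", "c2"), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = ref, alt = alt,
    variant_class = "SNP",
    wt_ref = rand_depth(), wt_alt = 0L,
    mut_ref = 0L, mut_alt = rand_depth(),
    short_ref = depth - short_alt, short_alt = short_alt,
    long_ref = depth - long_alt, long_alt = long_alt
  ) |> dplyr::arrange(chrom, pos)
}

# toy gene with 1-4 exons, CDS length a multiple of 3, on either strand
mk_toy_gene <- function(chrom = "c1", gene_id = "g1", strand = "+",
                        n_exons = NULL, first_start = NULL) {
  n_ex <- n_exons %||% sample(1:4, 1)
  ex_len <- sample(60:300, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(50:400, n_ex - 1, replace = TRUE) else integer(0)
  start <- first_start %||% sample(500:1500, 1)
  starts <- start + cumsum(c(0, utils::head(ex_len, -1) + gaps))
  ends <- starts + ex_len - 1
  trim <- sum(ex_len) %% 3
  cds_e <- ends
  cds_e[n_ex] <- cds_e[n_ex] - trim
  tibble::tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".1"), chrom = chrom,
    strand = strand,
    type = c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_ex)),
    start = c(start, start, starts, starts),
    end = c(max(ends), max(ends), ends, cds_e),
    annotation = NA_character_)
}

random_genome_string <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent oracle: rebuild the whole mutant CDS, translate both proteins
oracle_coding_effect <- function(pos, ref, alt, gm, genome) {
  seg <- gm[gm$type == "CDS", ]
  seg <- seg[order(seg$start), ]
  strand <- seg$strand[1]
  splice_seq <- function(g) {
    paste(substring(g, seg$start, seg$end), collapse = "")
  }
  g1 <- genome
  substr(g1, pos, pos) <- alt
  s0 <- splice_seq(genome)
  s1 <- splice_seq(g1)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (strand == "-") {
    s0 <- rc(s0)
    s1 <- rc(s1)
  }
  tr <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(s),
                          no.init.codon = TRUE)), "")[[1]]
  p0 <- tr(s0)
  p1 <- tr(s1)
  d <- which(p0 != p1)
  if (length(d) == 0) "synonymous"
  else if (p1[d[1]] == "*") "stopgain"
  else if (p0[d[1]] == "*") "stoploss"
  else "nonsynonymous"
}

# rejection-sample a flank on which assay design succeeds
feasible_flank <- function(seed) {
  set.seed(seed)
  repeat {
    flank <- paste(sample(c("A", "C", "G", "T"), 301, replace = TRUE),
                   collapse = "")
    ctr <- substr(flank, 151, 151)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ctr), 1)
    assay <- design_kasp(flank, c(ctr, alt))
    if (assay$feasible) return(list(flank = flank, alleles = c(ctr, alt),
                                    assay = assay))
  }
}

# one seeded desk-scale scan replicate; returns recovery indicators and
# the region counts needed by the null-control property
scan_replicate <- function(seed, causal = TRUE) {
  cfg <- sim_config(seed = seed,
                    additive_effect = if (causal) 2.1 else 0,
                    dominance = if (causal) 2.1 else 0)
  truth <- simulate_f2(cfg)
  rec <- simulate_records(truth, cfg)
  sck <- filter_offspring_index(quiet_scan(quiet_filter(rec)))
  w <- smooth_delta(sck)
  thr_q <- stats::quantile(w$mean_abs_delta, 0.95, na.rm = TRUE,
                           names = FALSE)
  delta_q <- call_regions(w, thr_q, "mean_abs_delta", method = "snp_index")
  delta_abs <- call_regions(w, 0.95, "mean_abs_delta", method = "snp_index")
  fit <- fit_ed(sck)
  ed_reg <- call_regions(fit, ed_threshold(fit$fitted_ed), "fitted_ed",
                         method = "ed")
  ix <- intersect_region_sets(delta_q, ed_reg)
  contains_causal <- function(reg, rank_col) {
    if (nrow(reg) == 0) return(FALSE)
    top <- reg[which.max(reg[[rank_col]]), ]
    top$chrom == cfg$causal_chrom &&
      top$start <= cfg$causal_pos && top$end >= cfg$causal_pos
  }
  list(delta_top = contains_causal(delta_q, "peak_stat"),
       ed_top = contains_causal(ed_reg, "peak_stat"),
       intersection_top = contains_causal(ix, "length_bp"),
       n_delta_abs = nrow(delta_abs),
       n_ed = nrow(ed_reg))
}

# minimal VCF writer for reader tests
write_fixture_vcf <- function(path, rows,
                              format = "GT:AD:DP",
                              samples = c("P_WT", "P_MUT", "POOL_SHORT",
                                          "POOL_LONG")) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=c1,length=1000000>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(samples, collapse = "\t")))
  writeLines(c(header, rows), path)
}

# published reference tables shipped with the package
ed_region_table <- function() {
  readr::read_tsv(system.file("extdata", "spike_length_ed_regions.tsv",
                              package = "bsamapr"),
                  show_col_types = FALSE)
}
combined_region_table <- function() {
  readr::read_tsv(system.file("extdata", "spike_length_combined_regions.tsv",
                              package = "bsamapr"),
                  show_col_types = FALSE)
}
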