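#' Write a simulated BSA-seq dataset to disk
#'
#' Materialises an [simulate_f2()] truth set as the five files the analysis
#' pipeline consumes: a VCF 4.2 with per-sample allele depths (AD) for the
#' two parents and the two tail pools, a FASTA reference for the toy genome,
#' a GFF3 gene annotation (toy gene models, one of which contains the causal
#' site in its CDS), a phenotype TSV and a truth JSON. Pool allele
#' frequencies are the mean mutant-allele dosage of the pooled plants / 2
#' (equimolar pooling); parents are homozygous (frequencies 0 and 1).
#'
#' @param truth An `f2_truth` object.
#' @param config The [sim_config()] used to simulate it.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `manifest` (tibble of file kinds, paths and
#'   record counts), `paths` (named list), `pools` (the tail-pool plant ids)
#'   and `gene_models` (the emitted annotation as a tibble).
#' @export
emit_dataset <- function(truth, config = truth$config, out_dir) {
  stopifnot(inherits(truth, "f2_truth"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    abort(paste("cannot create output directory", out_dir),
          class = "bsamapr_io_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed %% 2147480000L + 1017L)

  pools <- select_tail_pools(truth, config$pool_size)
  mk <- truth$markers
  freqs <- list(
    parent_wt  = rep(0, nrow(mk)),
    parent_mut = rep(1, nrow(mk)),
    pool_short = colMeans(truth$genotypes[pools$short, , drop = FALSE]) / 2,
    pool_long  = colMeans(truth$genotypes[pools$long, , drop = FALSE]) / 2
  )
  quads <- lapply(freqs, function(f) {
    sim_depth_quads(f, config$mean_depth, config$error_rate, mk$ref, mk$alt)
  })

  paths <- list(
    vcf = file.path(out_dir, "variants.vcf"),
    gff = file.path(out_dir, "annotation.gff3"),
    fasta = file.path(out_dir, "reference.fa"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    truth = file.path(out_dir, "truth.json")
  )

  genome <- random_genome(config, mk)
  Biostrings::writeXStringSet(genome, paths$fasta, width = 70L)

  gene_models <- simulate_gene_models(config)
  write_gff3(gene_models, paths$gff)

  write_pooled_vcf(mk, quads, config, paths$vcf)

  readr::write_tsv(truth$phenotypes, paths$phenotypes)

  jsonlite::write_json(
    list(causal = truth$causal,
         plant_ids = rownames(truth$genotypes),
         markers = mk,
         genotypes = unname(apply(truth$genotypes, 1L, identity,
                                  simplify = FALSE)),
         phenotypes = truth$phenotypes,
         pools = pools),
    paths$truth, auto_unbox = TRUE, digits = NA)

  manifest <- tibble(
    kind = names(paths),
    path = unlist(paths, use.names = FALSE),
    n_records = c(nrow(mk), nrow(gene_models), length(genome),
                  nrow(truth$phenotypes), 1L)
  )
  invisible(list(manifest = manifest, paths = paths, pools = pools,
                 gene_models = gene_models))
}

# random reference patched so each marker position carries its ref base
random_genome <- function(config, markers) {
  seqs <- lapply(names(config$chrom_lengths), function(chrom) {
    len <- config$chrom_lengths[[chrom]]
    s <- sample(BASES, len, replace = TRUE)
    idx <- markers$pos[markers$chrom == chrom]
    s[idx] <- markers$ref[markers$chrom == chrom]
    paste(s, collapse = "")
  })
  Biostrings::DNAStringSet(setNames(unlist(seqs),
                                    names(config$chrom_lengths)))
}

# toy gene models tiled every 100 kb; the gene nearest the causal site is
# shifted so the causal position lands inside its CDS
simulate_gene_models <- function(config, spacing = 1e5) {
  domains <- c("Protein kinase domain", "Leucine-rich repeat domain superfamily",
               "Tubulin", "Transcription factor GRAS",
               "RING-type E3 ubiquitin transferase", "ABC transporter-like",
               "F-box domain-containing protein", "PAZ domain",
               "Aspartic peptidase A1 family", "TIFY/JAZ family",
               "Helix-loop-helix DNA-binding domain superfamily",
               "Lysine methyltransferase")
  res <- list()
  for (chrom in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[chrom]]
    starts <- seq(spacing / 2, len - 3000, by = spacing)
    if (chrom == config$causal_chrom) {
      # causal site at offset 500 of the nearest gene: inside its first CDS
      i <- which.min(abs(starts - config$causal_pos))
      starts[i] <- config$causal_pos - 500
    }
    strand <- rep(c("+", "-"), length.out = length(starts))
    for (k in seq_along(starts)) {
      s <- as.integer(starts[k])
      gid <- sprintf("TOY%s%04d", gsub("[^0-9A-Za-z]", "", chrom), k)
      tid <- paste0(gid, ".1")
      res[[length(res) + 1L]] <- tibble(
        gene_id = gid, transcript_id = tid, chrom = chrom,
        strand = strand[k],
        type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS"),
        start = s + c(0L, 0L, 0L, 1600L, 200L, 1600L),
        end = s + c(2799L, 2799L, 999L, 2799L, 999L, 2599L),
        annotation = sample(domains, 1L)
      )
    }
  }
  bind_rows(res)
}

write_gff3 <- function(gene_models, path) {
  attr_of <- function(row) {
    switch(row$type,
      gene = sprintf("ID=%s;description=%s", row$gene_id, row$annotation),
      mRNA = sprintf("ID=%s;Parent=%s", row$transcript_id, row$gene_id),
      sprintf("Parent=%s", row$transcript_id))
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(gene_models)), function(i) {
               r <- gene_models[i, ]
               paste(r$chrom, "bsamapr", r$type, r$start, r$end, ".",
                     r$strand, ".", attr_of(r), sep = "\t")
             }, character(1)))
  writeLines(lines, path)
}

# VCF 4.2 with GT:AD:DP for the four named samples
write_pooled_vcf <- function(markers, quads, config, path) {
  sample_field <- function(quad, gt, ref, alt) {
    i <- seq_len(nrow(quad))
    ad_ref <- quad[cbind(i, match(ref, BASES))]
    ad_alt <- quad[cbind(i, match(alt, BASES))]
    sprintf("%s:%d,%d:%d", gt, ad_ref, ad_alt, ad_ref + ad_alt)
  }
  gts <- c(parent_wt = "0/0", parent_mut = "1/1",
           pool_short = "0/1", pool_long = "0/1")
  cols <- lapply(ROLES, function(role) {
    sample_field(quads[[role]], gts[[role]], markers$ref, markers$alt)
  })
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(config$chrom_lengths),
            as.integer(config$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "P_WT\tP_MUT\tPOOL_SHORT\tPOOL_LONG"))
  body <- paste(markers$chrom, markers$pos, ".", markers$ref, markers$alt,
                ".", "PASS", ".", "GT:AD:DP",
                cols[[1L]], cols[[2L]], cols[[3L]], cols[[4L]], sep = "\t")
  writeLines(c(header, body), path)
}
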