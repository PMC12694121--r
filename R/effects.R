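# location categories, most to least specific; combined classes first
LOCATION_PRIORITY <- c("exonic;splicing", "exonic", "splicing",
                       "UTR5;UTR3", "UTR5", "UTR3", "intronic",
                       "upstream;downstream", "upstream", "downstream",
                       "intergenic")

#' Locate variants relative to gene models
#'
#' Assigns each variant one category from the closed set `exonic`,
#' `intronic`, `UTR5`, `UTR3`, `upstream`, `downstream`,
#' `upstream;downstream`, `splicing`, `exonic;splicing`, `UTR5;UTR3`,
#' `intergenic`. Flanks are `flank_bp` (2 kb) either side of the gene,
#' strand-aware; splice sites are the first `splice_bp` (2) intronic bases
#' at each exon/intron boundary. A variant exonic in one transcript and at a
#' splice site of another transcript of the same gene is `exonic;splicing`;
#' a variant upstream of one gene and downstream of another is
#' `upstream;downstream`. When several genes give calls of different
#' specificity the most gene-proximal category wins and the contributing
#' genes are reported.
#'
#' @param records Variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param gene_models Gene-model tibble from [read_gff()].
#' @param flank_bp Upstream/downstream flank width (default 2000).
#' @param splice_bp Intronic splice window at exon boundaries (default 2).
#' @param per_gene Return one row per (variant, gene) instead of the
#'   combined per-variant call.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `gene_id` (";"-collapsed
#'   when several genes contribute; `NA` for intergenic), `location`.
#' @export
locate_variant <- function(records, gene_models, flank_bp = 2000L,
                           splice_bp = 2L, per_gene = FALSE) {
  models_by_chrom <- split(gene_models, gene_models$chrom)
  missing_chrom <- setdiff(unique(records$chrom), names(models_by_chrom))
  if (length(missing_chrom) > 0L) {
    warn(paste("no gene models for chromosome(s):",
               paste(missing_chrom, collapse = ", ")))
  }
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    pos <- records$pos[i]
    gm <- models_by_chrom[[records$chrom[i]]]
    calls <- if (is.null(gm)) tibble(gene_id = character(),
                                     location = character())
             else locate_in_genes(pos, gm, flank_bp, splice_bp)
    if (per_gene) {
      if (nrow(calls) == 0L) {
        calls <- tibble(gene_id = NA_character_, location = "intergenic")
      }
      out[[i]] <- bind_cols(records[rep(i, nrow(calls)),
                                    c("chrom", "pos", "ref", "alt")], calls)
    } else {
      comb <- combine_location_calls(calls)
      out[[i]] <- bind_cols(records[i, c("chrom", "pos", "ref", "alt")],
                            comb)
    }
  }
  bind_rows(out)
}

# per-gene location calls for one position on one chromosome
locate_in_genes <- function(pos, gm, flank_bp, splice_bp) {
  genes <- unique(gm$gene_id[gm$type == "gene"])
  res <- list()
  for (g in genes) {
    rows <- gm[gm$gene_id == g & !is.na(gm$gene_id), , drop = FALSE]
    grow <- rows[rows$type == "gene", , drop = FALSE][1L, ]
    strand <- grow$strand
    tx_labels <- character()
    for (tid in unique(rows$transcript_id[rows$type %in% c("exon", "CDS")])) {
      ex <- rows[rows$type == "exon" & rows$transcript_id == tid, ,
                 drop = FALSE]
      cds <- rows[rows$type == "CDS" & rows$transcript_id == tid, ,
                  drop = FALSE]
      if (nrow(ex) == 0L) next
      lab <- locate_in_transcript(pos, ex, cds, strand, splice_bp)
      if (!is.na(lab)) tx_labels <- c(tx_labels, lab)
    }
    label <- combine_transcript_labels(tx_labels)
    if (is.na(label) && pos >= grow$start - flank_bp &&
        pos <= grow$end + flank_bp) {
      before <- pos < grow$start
      after <- pos > grow$end
      if (before || after) {
        upstream_side <- if (strand == "+") before else after
        label <- if (upstream_side) "upstream" else "downstream"
      }
      # a short gene can put the variant inside both flanks of itself only
      # if it lies within the gene body, which genic labels already cover
    }
    if (!is.na(label)) {
      res[[length(res) + 1L]] <- tibble(gene_id = g, location = label)
    }
  }
  if (length(res) == 0L) tibble(gene_id = character(),
                                location = character())
  else bind_rows(res)
}

locate_in_transcript <- function(pos, ex, cds, strand, splice_bp) {
  tx_start <- min(ex$start)
  tx_end <- max(ex$end)
  if (pos < tx_start || pos > tx_end) return(NA_character_)
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (in_exon) {
    if (nrow(cds) == 0L) return("exonic")
    if (any(pos >= cds$start & pos <= cds$end)) return("exonic")
    if (strand == "+") {
      if (pos < min(cds$start)) "UTR5" else "UTR3"
    } else {
      if (pos > max(cds$end)) "UTR5" else "UTR3"
    }
  } else {
    dist_left <- pos - ex$end    # > 0 when the exon ends before pos
    dist_right <- ex$start - pos # > 0 when the exon starts after pos
    d <- min(c(dist_left[dist_left > 0], dist_right[dist_right > 0]))
    if (d <= splice_bp) "splicing" else "intronic"
  }
}

combine_transcript_labels <- function(labels) {
  if (length(labels) == 0L) return(NA_character_)
  u <- unique(labels)
  if (all(c("exonic", "splicing") %in% u)) return("exonic;splicing")
  if (all(c("UTR5", "UTR3") %in% u)) return("UTR5;UTR3")
  u[order(match(u, LOCATION_PRIORITY))][1L]
}

combine_location_calls <- function(calls) {
  genic <- c("exonic;splicing", "exonic", "splicing", "UTR5;UTR3",
             "UTR5", "UTR3", "intronic")
  if (nrow(calls) == 0L) {
    return(tibble(gene_id = NA_character_, location = "intergenic"))
  }
  is_genic <- calls$location %in% genic
  if (any(is_genic)) {
    g <- calls[is_genic, , drop = FALSE]
    if (all(c("exonic", "splicing") %in% g$location)) {
      best <- "exonic;splicing"
      contrib <- g$gene_id[g$location %in% c("exonic", "splicing")]
    } else {
      best <- g$location[order(match(g$location, LOCATION_PRIORITY))][1L]
      contrib <- g$gene_id[g$location == best]
    }
    return(tibble(gene_id = paste(unique(contrib), collapse = ";"),
                  location = best))
  }
  u <- unique(calls$location)
  if (all(c("upstream", "downstream") %in% u) ||
      "upstream;downstream" %in% u) {
    return(tibble(gene_id = paste(unique(calls$gene_id), collapse = ";"),
                  location = "upstream;downstream"))
  }
  tibble(gene_id = paste(unique(calls$gene_id), collapse = ";"),
         location = u[1L])
}

# -- coding effects ---------------------------------------------------------

as_genome <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    g <- reference
  } else if (is.character(reference) && length(reference) == 1L &&
             is.null(names(reference)) && file.exists(reference)) {
    g <- Biostrings::readDNAStringSet(reference)
  } else if (is.character(reference) && !is.null(names(reference))) {
    g <- Biostrings::DNAStringSet(reference)
  } else {
    abort("reference must be a FASTA path, named character or DNAStringSet",
          class = "bsamapr_value_error")
  }
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Coding effect of variants inside coding sequence
#'
#' For SNPs, translates the reference and mutated codon (standard nuclear
#' code; minus-strand transcripts are reverse-complemented) and classifies
#' the change as `synonymous`, `nonsynonymous`, `stopgain` or `stoploss`.
#' For InDels, the classification follows the length rule: in-frame changes
#' are `nonframeshift insertion`/`nonframeshift deletion`, the rest
#' `frameshift insertion`/`frameshift deletion`. Transcripts whose CDS
#' length is not a multiple of 3, or whose reference base disagrees with the
#' supplied genome at the variant position, give `unknown` -- annotation
#' failures never abort the pipeline. Variants outside any CDS give `n/a`.
#'
#' @param records Variant tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`).
#' @param gene_models Gene-model tibble from [read_gff()].
#' @param reference Genome: FASTA path, named character vector or
#'   `DNAStringSet`.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `gene_id`, `transcript_id`,
#'   `effect`, `aa_ref`, `aa_alt`, `aa_pos`.
#' @export
coding_effect <- function(records, gene_models, reference) {
  genome <- as_genome(reference)
  cds_by_chrom <- split(gene_models[gene_models$type == "CDS", , drop = FALSE],
                        gene_models$chrom[gene_models$type == "CDS"])
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    cds <- cds_by_chrom[[rec$chrom]]
    hit_tx <- if (is.null(cds)) character() else
      unique(cds$transcript_id[rec$pos >= cds$start & rec$pos <= cds$end])
    if (length(hit_tx) == 0L) {
      out[[i]] <- tibble(gene_id = NA_character_,
                         transcript_id = NA_character_, effect = "n/a",
                         aa_ref = NA_character_, aa_alt = NA_character_,
                         aa_pos = NA_integer_)
    } else {
      tid <- sort(hit_tx)[1L]
      seg <- cds[cds$transcript_id == tid, , drop = FALSE]
      out[[i]] <- coding_effect_one(rec, seg, genome)
    }
  }
  bind_cols(records[, c("chrom", "pos", "ref", "alt")], bind_rows(out))
}

coding_effect_one <- function(rec, seg, genome) {
  gid <- seg$gene_id[1L]
  tid <- seg$transcript_id[1L]
  strand <- seg$strand[1L]
  res <- function(effect, aa_ref = NA_character_, aa_alt = NA_character_,
                  aa_pos = NA_integer_) {
    tibble(gene_id = gid, transcript_id = tid, effect = effect,
           aa_ref = aa_ref, aa_alt = aa_alt, aa_pos = aa_pos)
  }
  vclass <- rec$variant_class %||% if (nchar(rec$ref) == 1L &&
                                       nchar(rec$alt) == 1L) "SNP" else "InDel"
  if (vclass == "InDel" ||
      nchar(rec$ref) != 1L || nchar(rec$alt) != 1L) {
    len_diff <- nchar(rec$alt) - nchar(rec$ref)
    if (len_diff == 0L) return(res("unknown"))
    kind <- if (len_diff > 0L) "insertion" else "deletion"
    frame <- if (abs(len_diff) %% 3L == 0L) "nonframeshift" else "frameshift"
    return(res(paste(frame, kind)))
  }
  chrom_seq <- genome[[rec$chrom]]
  if (is.null(chrom_seq)) return(res("unknown"))
  seg <- seg[order(seg$start), , drop = FALSE]
  cds_seq <- paste(vapply(seq_len(nrow(seg)), function(j) {
    as.character(Biostrings::subseq(chrom_seq, seg$start[j], seg$end[j]))
  }, character(1)), collapse = "")
  if (nchar(cds_seq) %% 3L != 0L) return(res("unknown"))
  # genomic ref must match the reference sequence
  if (as.character(Biostrings::subseq(chrom_seq, rec$pos, rec$pos)) !=
      rec$ref) {
    return(res("unknown"))
  }
  seg_i <- which(rec$pos >= seg$start & rec$pos <= seg$end)[1L]
  plus_index <- sum(pmax(seg$end[seq_len(seg_i - 1L)] -
                           seg$start[seq_len(seg_i - 1L)] + 1L, 0L)) +
    (rec$pos - seg$start[seg_i] + 1L)
  if (strand == "-") {
    cds_seq <- revcomp(cds_seq)
    cds_pos <- nchar(cds_seq) - plus_index + 1L
    alt_base <- revcomp(rec$alt)
  } else {
    cds_pos <- plus_index
    alt_base <- rec$alt
  }
  codon_i <- (cds_pos - 1L) %/% 3L + 1L
  offset <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(cds_seq, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt_base
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return(res("unknown"))
  effect <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stopgain"
    else if (aa_ref == "*") "stoploss"
    else "nonsynonymous"
  res(effect, aa_ref, aa_alt, codon_i)
}

#' Annotate variants with location and coding effect
#'
#' Combines [locate_variant()] and [coding_effect()] into the standard
#' annotation table: every variant gets a location category, and variants in
#' coding sequence additionally get an effect call with the amino-acid
#' change.
#'
#' @inheritParams coding_effect
#' @param gene_models Gene-model tibble.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `gene_id`, `location`,
#'   `effect`, `aa_ref`, `aa_alt`, `aa_pos`.
#' @export
annotate_effects <- function(records, gene_models, reference) {
  loc <- locate_variant(records, gene_models)
  eff <- coding_effect(records, gene_models, reference)
  bind_cols(loc,
            eff[, c("effect", "aa_ref", "aa_alt", "aa_pos")])
}
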