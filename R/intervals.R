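#' Length of 1-based inclusive genomic intervals
#'
#' `end - start + 1`, the convention under which every published
#' candidate-region table used by this package reproduces its printed
#' lengths exactly.
#'
#' @param start,end Numeric vectors, `1 <= start <= end`.
#' @return Numeric vector of lengths in bp.
#' @examples
#' region_length(673837810, 674334747)  # 496938
#' @export
region_length <- function(start, end) {
  if (any(start < 1) || any(end < start)) {
    abort("intervals must satisfy 1 <= start <= end",
          class = "bsamapr_value_error")
  }
  end - start + 1
}

#' Total length of a disjoint region set
#'
#' @param regions Tibble with `chrom`, `start`, `end`. Overlap within the
#'   set is an error: region lists are disjoint by construction.
#' @return Total bp.
#' @export
total_length <- function(regions) {
  if (nrow(regions) == 0L) return(0)
  by_chrom <- split(regions, regions$chrom)
  for (df in by_chrom) {
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1L && any(df$start[-1L] <= head(df$end, -1L))) {
      abort("regions overlap within the set", class = "bsamapr_value_error")
    }
  }
  sum(region_length(regions$start, regions$end))
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
}

granges_to_regions <- function(gr, method = "intersection") {
  df <- as.data.frame(gr)
  tibble(chrom = as.character(df$seqnames), start = df$start,
         end = df$end,
         length_bp = region_length(df$start, df$end),
         method = method) |>
    arrange(.data$chrom, .data$start)
}

#' Intersect two candidate-region sets
#'
#' Returns the maximal intervals contained in some interval of `a` and some
#' interval of `b` (1-based inclusive coordinates). Commutative and
#' idempotent for disjoint sorted inputs; the typical use is combining the
#' regions called by the Delta(SNP-index) and ED scans.
#'
#' @param a,b Region tibbles (`chrom`, `start`, `end`), each internally
#'   disjoint.
#' @return Region tibble with `length_bp` and `method = "intersection"`.
#' @examples
#' a <- tibble::tibble(chrom = "5A", start = 691443224, end = 696644520)
#' b <- tibble::tibble(chrom = "5A", start = 691500001, end = 695000001)
#' intersect_region_sets(a, b)
#' @export
intersect_region_sets <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(granges_to_regions(GenomicRanges::GRanges()))
  }
  # Seqinfo merging warns when the two sets cover different chromosomes;
  # that is an expected, valid input here
  gr <- suppressWarnings(
    GenomicRanges::intersect(regions_to_granges(a), regions_to_granges(b),
                             ignore.strand = TRUE))
  granges_to_regions(gr)
}

#' Assign candidate SNPs to the regions containing them
#'
#' @param loci Tibble of SNPs (`chrom`, `pos`, ...).
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @return The loci falling inside a region (inclusive bounds), with
#'   `region_start`/`region_end` columns identifying the host region.
#' @export
snps_in_regions <- function(loci, regions) {
  if (nrow(loci) == 0L || nrow(regions) == 0L) {
    return(mutate(loci[0L, , drop = FALSE],
                  region_start = numeric(), region_end = numeric()))
  }
  out <- list()
  for (i in seq_len(nrow(regions))) {
    inside <- loci$chrom == regions$chrom[i] &
      loci$pos >= regions$start[i] & loci$pos <= regions$end[i]
    if (any(inside)) {
      out[[length(out) + 1L]] <- mutate(
        loci[inside, , drop = FALSE],
        region_start = regions$start[i], region_end = regions$end[i])
    }
  }
  if (length(out) == 0L) {
    return(mutate(loci[0L, , drop = FALSE],
                  region_start = numeric(), region_end = numeric()))
  }
  bind_rows(out) |> arrange(.data$chrom, .data$pos)
}

#' Candidate genes of a region set
#'
#' A gene is a candidate if it contains a candidate SNP lying inside a
#' region, or if it is the annotated gene of such a SNP (via a `gene_id`
#' column on `snps`). When `snps` is `NULL`, every gene overlapping a region
#' is returned.
#'
#' @param regions Region tibble.
#' @param gene_models Gene-model tibble from [read_gff()].
#' @param snps Optional candidate-SNP tibble (`chrom`, `pos`, optionally
#'   `gene_id`).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `annotation`,
#'   `n_snps`.
#' @export
genes_in_regions <- function(regions, gene_models, snps = NULL) {
  genes <- gene_models |>
    filter(.data$type == "gene") |>
    distinct(.data$gene_id, .data$chrom, .data$start, .data$end,
             .data$annotation)
  if (is.null(snps)) {
    hit <- purrr::pmap_lgl(genes, function(gene_id, chrom, start, end, ...) {
      any(regions$chrom == chrom & regions$start <= end &
            regions$end >= start)
    })
    return(mutate(genes[hit, , drop = FALSE], n_snps = NA_integer_))
  }
  snps_in <- snps_in_regions(snps, regions)
  n_span <- purrr::pmap_int(genes, function(gene_id, chrom, start, end, ...) {
    sum(snps_in$chrom == chrom & snps_in$pos >= start & snps_in$pos <= end |
          (if ("gene_id" %in% names(snps_in))
             !is.na(snps_in$gene_id) & snps_in$gene_id == gene_id
           else FALSE))
  })
  genes |>
    mutate(n_snps = n_span) |>
    filter(.data$n_snps > 0L)
}

#' Prioritize candidate genes by tissue expression
#'
#' Operationalises "predominantly expressed in the target tissue" as:
#' target-tissue expression at least `min_ratio` times the maximum over all
#' other tissues AND at least `min_expr` expression units. Genes missing
#' from the matrix are flagged with a warning and ranked last.
#'
#' @param genes Tibble with a `gene_id` column (e.g. from
#'   [genes_in_regions()]).
#' @param expression Wide expression tibble from [read_expression_matrix()].
#' @param target_tissue Name of the tissue column of interest.
#' @param min_ratio Required ratio to the best other tissue (default 0.8).
#' @param min_expr Expression floor in matrix units (default 0.5).
#' @return The input genes ranked by target-tissue specificity, with columns
#'   `target_expr`, `max_other_expr`, `specificity` and logical
#'   `predominant`.
#' @export
prioritize_by_expression <- function(genes, expression, target_tissue,
                                     min_ratio = 0.8, min_expr = 0.5) {
  if (nrow(expression) == 0L) {
    abort("empty expression matrix", class = "bsamapr_config_error")
  }
  if (!target_tissue %in% names(expression)) {
    abort(paste("tissue", target_tissue, "absent from expression matrix"),
          class = "bsamapr_config_error")
  }
  other <- setdiff(names(expression), c("gene_id", target_tissue))
  expr <- expression |>
    mutate(target_expr = .data[[target_tissue]],
           max_other_expr = do.call(pmax, c(as.list(expression[other]), 0))) |>
    select("gene_id", "target_expr", "max_other_expr")
  out <- left_join(genes, expr, by = "gene_id")
  if (any(is.na(out$target_expr))) {
    warn(sprintf("%d gene(s) missing from the expression matrix",
                 sum(is.na(out$target_expr))))
  }
  out |>
    mutate(
      specificity = .data$target_expr / (.data$max_other_expr + 1e-9),
      predominant = !is.na(.data$target_expr) &
        .data$target_expr >= min_ratio * .data$max_other_expr &
        .data$target_expr >= min_expr
    ) |>
    arrange(desc(.data$predominant), desc(.data$specificity),
            desc(.data$target_expr))
}
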