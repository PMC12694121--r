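#' Read a four-sample pooled VCF into a variant tibble
#'
#' Parses a VCF 4.2 whose samples carry per-allele depths (`AD`) and maps the
#' sample names onto the four roles of a BSA-seq experiment: wild-type
#' parent, mutant parent, short-spike offspring pool ("ab") and long-spike
#' offspring pool ("aa"). One row per biallelic site; multiallelic rows are
#' skipped with a warning (the parent-vs-parent scheme is strictly
#' biallelic).
#'
#' @param path Path to the VCF.
#' @param sample_map Named character vector mapping VCF sample names to roles
#'   `"parent_wt"`, `"parent_mut"`, `"pool_short"`, `"pool_long"`.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class` (`"SNP"`/`"InDel"`) and eight depth columns
#'   `wt_ref`, `wt_alt`, `mut_ref`, `mut_alt`, `short_ref`, `short_alt`,
#'   `long_ref`, `long_alt`.
#' @examples
#' \dontrun{
#' rec <- read_pooled_vcf("variants.vcf")
#' }
#' @export
read_pooled_vcf <- function(path,
                            sample_map = c(P_WT = "parent_wt",
                                           P_MUT = "parent_mut",
                                           POOL_SHORT = "pool_short",
                                           POOL_LONG = "pool_long")) {
  if (!file.exists(path)) {
    abort(paste("VCF not found:", path), class = "bsamapr_io_error")
  }
  if (!all(sample_map %in% ROLES) || !setequal(sample_map, ROLES)) {
    abort("sample_map must assign each of the four roles exactly once",
          class = "bsamapr_config_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_variant_tibble())
  }
  samples <- colnames(vcf@gt)[-1L]
  missing <- setdiff(names(sample_map), samples)
  if (length(missing) > 0L) {
    abort(paste("samples absent from VCF:", paste(missing, collapse = ", ")),
          class = "bsamapr_format_error")
  }
  has_ad <- vapply(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE),
                  function(f) "AD" %in% f, logical(1))
  if (!all(has_ad)) {
    abort("VCF FORMAT lacks the AD (allele depth) field",
          class = "bsamapr_format_error")
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("skipping %d multiallelic site(s)", sum(multi)))
  }
  keep <- !multi
  ad <- vcfR::extract.gt(vcf, element = "AD")[keep, , drop = FALSE]
  parse_ad <- function(x, which) {
    parts <- strsplit(x, ",", fixed = TRUE)
    out <- suppressWarnings(
      vapply(parts, function(p) as.integer(p[which]), integer(1),
             USE.NAMES = FALSE))
    tidyr::replace_na(out, 0L)
  }
  roles <- setNames(names(sample_map), sample_map)  # role -> sample name
  depth_cols <- list()
  for (role in ROLES) {
    col <- ad[, roles[[role]]]
    short <- c(parent_wt = "wt", parent_mut = "mut",
               pool_short = "short", pool_long = "long")[[role]]
    depth_cols[[paste0(short, "_ref")]] <- parse_ad(col, 1L)
    depth_cols[[paste0(short, "_alt")]] <- parse_ad(col, 2L)
  }
  ref <- fix$REF[keep]
  alt <- fix$ALT[keep]
  tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = ref, alt = alt,
    variant_class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L &
                             ref %in% BASES & alt %in% BASES,
                           "SNP", "InDel"),
    !!!depth_cols
  )
}

empty_variant_tibble <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), variant_class = character(),
         wt_ref = integer(), wt_alt = integer(),
         mut_ref = integer(), mut_alt = integer(),
         short_ref = integer(), short_alt = integer(),
         long_ref = integer(), long_alt = integer())
}

#' Site-level filter configuration
#'
#' @param min_depth Minimum per-sample total depth (default 5x, applied to
#'   each of the four samples).
#' @param parent_homozygosity Minimum major-allele depth fraction for a
#'   parent to count as homozygous.
#' @param require_parent_divergence Drop sites where the two parents are
#'   fixed for the same allele.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 5L, parent_homozygosity = 0.9,
                          require_parent_divergence = TRUE) {
  stopifnot(min_depth >= 0, parent_homozygosity >= 0,
            parent_homozygosity <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 parent_homozygosity = parent_homozygosity,
                 require_parent_divergence = require_parent_divergence),
            class = "filter_config")
}

#' Apply depth and parental filters to pooled variant records
#'
#' Retains sites where every sample reaches `min_depth` total coverage, each
#' parent is effectively homozygous (major-allele depth fraction at or above
#' `parent_homozygosity`) and the two parents are fixed for different
#' alleles. Each rejected site is attributed to the first rule it fails, so
#' the tally plus the retained count always equals the input count.
#'
#' @param records A variant tibble from [read_pooled_vcf()].
#' @param cfg A [filter_config()].
#' @return The retained rows, with the rejection tally attached as attribute
#'   `"filter_tally"` (see [filter_tally()]).
#' @export
filter_variants <- function(records, cfg = filter_config()) {
  wt_tot <- records$wt_ref + records$wt_alt
  mut_tot <- records$mut_ref + records$mut_alt
  short_tot <- records$short_ref + records$short_alt
  long_tot <- records$long_ref + records$long_alt

  low_depth <- wt_tot < cfg$min_depth | mut_tot < cfg$min_depth |
    short_tot < cfg$min_depth | long_tot < cfg$min_depth

  major_frac <- function(ref, alt, tot) {
    ifelse(tot == 0L, 0, pmax(ref, alt) / tot)
  }
  het_parent <- major_frac(records$wt_ref, records$wt_alt, wt_tot) <
      cfg$parent_homozygosity |
    major_frac(records$mut_ref, records$mut_alt, mut_tot) <
      cfg$parent_homozygosity

  wt_allele <- ifelse(records$wt_ref >= records$wt_alt, "ref", "alt")
  mut_allele <- ifelse(records$mut_ref >= records$mut_alt, "ref", "alt")
  not_divergent <- cfg$require_parent_divergence & wt_allele == mut_allele

  reason <- dplyr::case_when(
    low_depth ~ "low_depth",
    het_parent ~ "heterozygous_parent",
    not_divergent ~ "parents_not_divergent",
    TRUE ~ NA_character_
  )
  tally <- tibble(
    rule = c("low_depth", "heterozygous_parent", "parents_not_divergent"),
    n_removed = c(sum(reason == "low_depth", na.rm = TRUE),
                  sum(reason == "heterozygous_parent", na.rm = TRUE),
                  sum(reason == "parents_not_divergent", na.rm = TRUE))
  )
  out <- records[is.na(reason), , drop = FALSE]
  attr(out, "filter_tally") <- tally
  inform(sprintf("filter_variants: %d of %d site(s) retained",
                 nrow(out), nrow(records)))
  out
}

#' Rejection tally of a filtered variant tibble
#'
#' @param records Output of [filter_variants()].
#' @return Tibble `rule`, `n_removed`.
#' @export
filter_tally <- function(records) {
  attr(records, "filter_tally") %||%
    abort("no filter tally attached; was this produced by filter_variants()?")
}

#' Classify a base substitution as transition or transversion
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) changes are
#' transitions; all others are transversions. Vectorised and symmetric in
#' its arguments.
#'
#' @param ref,alt Single bases.
#' @return Character vector `"transition"`/`"transversion"`.
#' @examples
#' classify_substitution("G", "A")
#' @export
classify_substitution <- function(ref, alt) {
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    abort("ref and alt must be single bases A/C/G/T",
          class = "bsamapr_value_error")
  }
  if (any(ref == alt)) {
    abort("ref and alt must differ", class = "bsamapr_value_error")
  }
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine),
         "transition", "transversion")
}

#' Read a GFF3 gene annotation into a flat gene-model tibble
#'
#' Keeps `gene`, `mRNA`, `exon` and `CDS` features and resolves each feature
#' to its gene via the `Parent` chain, assuming the conventional
#' gene -> mRNA -> exon/CDS nesting. Coordinates are 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble `gene_id`, `transcript_id`, `chrom`, `strand`, `type`,
#'   `start`, `end`, `annotation` (the gene's description attribute, if any).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) {
    abort(paste("GFF3 not found:", path), class = "bsamapr_io_error")
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   abort(paste("malformed GFF3:", conditionMessage(e)),
                         class = "bsamapr_format_error")
                 })
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% c("gene", "mRNA", "exon", "CDS"), , drop = FALSE]
  first_chr <- function(x) {
    vapply(x, function(v) if (length(v) >= 1L) as.character(v[[1L]])
           else NA_character_, character(1))
  }
  parent <- if ("Parent" %in% names(df)) first_chr(df$Parent)
            else rep(NA_character_, nrow(df))
  id <- if ("ID" %in% names(df)) as.character(df$ID)
        else rep(NA_character_, nrow(df))
  descr <- if ("description" %in% names(df)) as.character(df$description)
           else rep(NA_character_, nrow(df))

  mrna <- df$type == "mRNA"
  tx_gene <- setNames(parent[mrna], id[mrna])        # transcript -> gene
  gene_descr <- setNames(descr[df$type == "gene"], id[df$type == "gene"])

  transcript_id <- ifelse(df$type %in% c("exon", "CDS"), parent,
                          ifelse(mrna, id, NA_character_))
  gene_id <- ifelse(df$type == "gene", id,
                    ifelse(mrna, parent,
                           unname(tx_gene[parent])))
  tibble(
    gene_id = gene_id,
    transcript_id = transcript_id,
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    type = as.character(df$type),
    start = df$start, end = df$end,
    annotation = unname(gene_descr[gene_id])
  )
}

#' Read a phenotype table
#'
#' Expects a two-column TSV `plant_id<TAB>spike_length_cm` with a header.
#'
#' @param path Path to the TSV.
#' @return Tibble `plant_id` (character), `spike_length_cm` (numeric).
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2L) {
    abort("phenotype table needs two columns: plant id and spike length",
          class = "bsamapr_format_error")
  }
  names(df)[1:2] <- c("plant_id", "spike_length_cm")
  val <- suppressWarnings(as.numeric(df$spike_length_cm))
  bad <- which(is.na(val) & !is.na(df$spike_length_cm))
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric spike length at data line %d", bad[1L]),
          class = "bsamapr_format_error")
  }
  tibble(plant_id = df$plant_id, spike_length_cm = val)
}

#' Read a gene x tissue expression matrix
#'
#' First column gene id, remaining columns one numeric expression value per
#' tissue.
#'
#' @param path Path to the TSV.
#' @return Tibble with `gene_id` and one numeric column per tissue.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2L) {
    abort("expression matrix needs a gene id column plus >= 1 tissue",
          class = "bsamapr_format_error")
  }
  names(df)[1L] <- "gene_id"
  for (j in 2:ncol(df)) {
    val <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(val) & !is.na(df[[j]]))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric expression value at data line %d, column %s",
                    bad[1L], names(df)[j]),
            class = "bsamapr_format_error")
    }
    df[[j]] <- val
  }
  as_tibble(df)
}
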