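#' Configuration of the association scan
#'
#' @param delta_threshold Threshold on the windowed |Delta(SNP-index)|. In
#'   `"absolute"` mode it is the statistic value itself (the conventional
#'   0.95); in `"quantile"` mode it is the genome-wide quantile of the
#'   windowed statistic above which windows are called. The absolute reading
#'   only fires for additively scored traits (a fully linked locus under
#'   complete dominance tops out at |Delta| = 2/3 with tail pools), so the
#'   quantile mode is the practical choice for dominant traits.
#' @param delta_mode `"absolute"` or `"quantile"` (see above).
#' @param offspring_index_floor Sites with SNP-index below this floor are
#'   removed before association (default 0.30).
#' @param index_floor_mode Remove a site when `"both"` pools (default) or
#'   when `"any"` pool falls below the floor.
#' @param ed_power Power applied to ED before smoothing (1 keeps the raw-ED
#'   scale on which the conventional thresholds are stated).
#' @param delta_window_bp,delta_step_bp Fixed-grid window and step for the
#'   Delta scan; window boundaries fall at multiples of the step + 1.
#' @param ed_span Local-regression span for the fitted ED curve.
#' @param ed_k The ED threshold is median + `ed_k` * SD of fitted values.
#' @param min_markers_per_region Minimum supporting markers for a called
#'   region (also masks windows with fewer markers).
#' @param max_gap_bp Above-threshold runs closer than this are merged.
#' @param maf_min,ed_min Candidate-SNP criteria: main-allele frequency in the
#'   mutant (long-spike) pool above `maf_min` and raw ED above `ed_min`.
#' @param index_parent Which parent's allele the SNP-index counts ("wt", the
#'   female parent of the modelled cross, or "mut"). Delta flips sign under
#'   the swap; region calling uses |Delta| and is orientation-invariant.
#' @return A `scan_config` list.
#' @export
scan_config <- function(delta_threshold = 0.95,
                        delta_mode = c("absolute", "quantile"),
                        offspring_index_floor = 0.30,
                        index_floor_mode = c("both", "any"),
                        ed_power = 1,
                        delta_window_bp = 5e5,
                        delta_step_bp = 5e5,
                        ed_span = 0.1,
                        ed_k = 3,
                        min_markers_per_region = 3L,
                        max_gap_bp = 1e6,
                        maf_min = 0.75,
                        ed_min = 0.50,
                        index_parent = c("wt", "mut")) {
  stopifnot(delta_threshold >= 0, delta_threshold <= 1,
            offspring_index_floor >= 0, offspring_index_floor <= 1,
            ed_power > 0, delta_window_bp > 0, delta_step_bp > 0,
            ed_span > 0, ed_span <= 1, ed_k >= 0,
            min_markers_per_region >= 1, max_gap_bp >= 0,
            maf_min >= 0, maf_min <= 1, ed_min >= 0)
  structure(list(
    delta_threshold = delta_threshold,
    delta_mode = match.arg(delta_mode),
    offspring_index_floor = offspring_index_floor,
    index_floor_mode = match.arg(index_floor_mode),
    ed_power = ed_power,
    delta_window_bp = delta_window_bp, delta_step_bp = delta_step_bp,
    ed_span = ed_span, ed_k = ed_k,
    min_markers_per_region = as.integer(min_markers_per_region),
    max_gap_bp = max_gap_bp,
    maf_min = maf_min, ed_min = ed_min,
    index_parent = match.arg(index_parent)
  ), class = "scan_config")
}

# which of ref/alt each parent carries, by depth majority
parent_alleles <- function(records) {
  list(wt = ifelse(records$wt_ref >= records$wt_alt, "ref", "alt"),
       mut = ifelse(records$mut_ref >= records$mut_alt, "ref", "alt"))
}

#' Per-pool SNP-index
#'
#' The SNP-index of a pool is M / (M + P), where M is the pool's read depth
#' on the allele of the designated parent (`index_parent`, by default the
#' wild-type female parent) and P its depth on the other parent's allele.
#' Reads matching neither parental allele are excluded. Sites where
#' M + P = 0 return `NA`.
#'
#' @param records Variant tibble (see [read_pooled_vcf()]).
#' @param pool `"long"` (the "aa" long-spike pool) or `"short"` ("ab").
#' @param index_parent `"wt"` or `"mut"`.
#' @return Numeric vector in \[0, 1\] (or `NA`).
#' @examples
#' rec <- tibble::tibble(wt_ref = 20L, wt_alt = 0L, mut_ref = 0L,
#'                       mut_alt = 20L, short_ref = 10L, short_alt = 30L,
#'                       long_ref = 30L, long_alt = 10L)
#' snp_index(rec, "long")  # 30/40
#' @export
snp_index <- function(records, pool = c("long", "short"),
                      index_parent = c("wt", "mut")) {
  pool <- match.arg(pool)
  index_parent <- match.arg(index_parent)
  al <- parent_alleles(records)
  m_allele <- al[[index_parent]]
  ref_d <- records[[paste0(pool, "_ref")]]
  alt_d <- records[[paste0(pool, "_alt")]]
  m <- ifelse(m_allele == "ref", ref_d, alt_d)
  p_allele <- al[[setdiff(c("wt", "mut"), index_parent)]]
  p <- ifelse(p_allele == "ref", ref_d, alt_d)
  # if parents share an allele the index is left NA; such sites are
  # removed by the parental-divergence filter upstream
  tot <- m + p
  out <- ifelse(tot > 0L & m_allele != p_allele, m / tot, NA_real_)
  out
}

#' Delta(SNP-index): long-pool index minus short-pool index
#'
#' @inheritParams snp_index
#' @return Numeric vector in \[-1, 1\] (or `NA` where either index is
#'   undefined).
#' @export
delta_snp_index <- function(records, index_parent = c("wt", "mut")) {
  index_parent <- match.arg(index_parent)
  snp_index(records, "long", index_parent) -
    snp_index(records, "short", index_parent)
}

#' Euclidean distance between pooled base-frequency vectors
#'
#' `sqrt(sum over A,C,G,T of (f_mut - f_wt)^2)`, where the two arguments are
#' base-frequency quadruples (each non-negative, summing to 1) of the mutant
#' (long-spike) and wild-type (short-spike) pools. Symmetric; ranges from 0
#' (identical pools) to sqrt(2) (fixed for different bases).
#'
#' @param freqs_mut,freqs_wt Numeric vectors of length 4 (A, C, G, T order)
#'   or 4-column matrices with one row per site.
#' @return Numeric vector of distances.
#' @examples
#' euclidean_distance(c(1, 0, 0, 0), c(0, 1, 0, 0))  # sqrt(2)
#' @export
euclidean_distance <- function(freqs_mut, freqs_wt) {
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 4L, byrow = TRUE) else as.matrix(x)
  }
  m <- as_mat(freqs_mut)
  w <- as_mat(freqs_wt)
  check <- function(x, name) {
    if (ncol(x) != 4L || any(x < 0) || any(abs(rowSums(x) - 1) > 1e-6)) {
      abort(paste(name, "must be non-negative quadruple(s) summing to 1"),
            class = "bsamapr_value_error")
    }
  }
  check(m, "freqs_mut")
  check(w, "freqs_wt")
  sqrt(rowSums((m - w)^2))
}

# base-frequency quadruple matrix for one pool, from ref/alt depths
pool_freq_quad <- function(records, pool) {
  ref_d <- records[[paste0(pool, "_ref")]]
  alt_d <- records[[paste0(pool, "_alt")]]
  tot <- ref_d + alt_d
  n <- nrow(records)
  m <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
  ok <- tot > 0L & records$ref %in% BASES & records$alt %in% BASES
  i <- which(ok)
  m[cbind(i, match(records$ref[i], BASES))] <- ref_d[i] / tot[i]
  m[cbind(i, match(records$alt[i], BASES))] <-
    m[cbind(i, match(records$alt[i], BASES))] + alt_d[i] / tot[i]
  m[!ok, ] <- NA_real_
  m
}

#' Compute per-site association statistics
#'
#' Builds the scan table: per-pool SNP-index, Delta(SNP-index), the
#' Euclidean distance between the two pools' base-frequency vectors, and the
#' main-allele frequency of the mutant (long-spike) pool. SNP sites where
#' either pool has zero depth on the parental alleles are dropped with a
#' message.
#'
#' @param records Filtered variant tibble.
#' @param config A [scan_config()].
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `index_aa` (long pool),
#'   `index_ab` (short pool), `delta`, `ed`, `maf_mut`.
#' @export
compute_scan <- function(records, config = scan_config()) {
  records <- filter(records, .data$variant_class == "SNP")
  idx_aa <- snp_index(records, "long", config$index_parent)
  idx_ab <- snp_index(records, "short", config$index_parent)
  drop <- is.na(idx_aa) | is.na(idx_ab)
  if (any(drop)) {
    inform(sprintf(
      "compute_scan: dropping %d site(s) with undefined SNP-index",
      sum(drop)))
  }
  records <- records[!drop, , drop = FALSE]
  idx_aa <- idx_aa[!drop]
  idx_ab <- idx_ab[!drop]
  fm <- pool_freq_quad(records, "long")
  fw <- pool_freq_quad(records, "short")
  long_tot <- records$long_ref + records$long_alt
  tibble(
    chrom = records$chrom, pos = records$pos,
    ref = records$ref, alt = records$alt,
    index_aa = idx_aa, index_ab = idx_ab,
    delta = idx_aa - idx_ab,
    ed = euclidean_distance(fm, fw),
    maf_mut = pmax(records$long_ref, records$long_alt) / long_tot
  ) |> arrange(.data$chrom, .data$pos)
}

#' Remove sites with uninformative offspring SNP-index
#'
#' Drops sites whose SNP-index is below `floor` in both pools (default) or
#' in any pool (`mode = "any"`). The both-pool rule removes sites that are
#' uninformative in the whole cross while keeping one-sided extremes.
#'
#' @param points Scan tibble from [compute_scan()].
#' @param floor Index floor (default 0.30).
#' @param mode `"both"` or `"any"`.
#' @return Retained rows, with attribute `"n_removed"`.
#' @export
filter_offspring_index <- function(points, floor = 0.30,
                                   mode = c("both", "any")) {
  mode <- match.arg(mode)
  low_aa <- points$index_aa < floor
  low_ab <- points$index_ab < floor
  remove <- if (mode == "both") low_aa & low_ab else low_aa | low_ab
  out <- points[!remove, , drop = FALSE]
  attr(out, "n_removed") <- sum(remove)
  out
}
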