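#' Call above-threshold candidate regions along the genome
#'
#' Scans a per-position (or per-window) statistic for maximal runs of
#' above-threshold entries; runs separated by at most `max_gap_bp` are
#' merged, and merged regions supported by fewer than `min_markers` markers
#' are dropped. For windowed input (columns `window_start`/`window_end`) a
#' region spans the union of its windows and the reported end is the last
#' window end + 1, the boundary convention of fixed-grid windowed scans; for
#' site-level input the region spans the first to last above-threshold site.
#'
#' @param x Tibble sorted by `chrom` and position: either windowed (from
#'   [smooth_delta()], with an `n_markers` column) or site-level (with a
#'   `pos` column).
#' @param threshold Entries with statistic strictly above this are called.
#' @param stat Name of the statistic column (e.g. `"mean_abs_delta"`,
#'   `"fitted_ed"`).
#' @param min_markers Minimum supporting markers per region.
#' @param max_gap_bp Merge distance between above-threshold runs.
#' @param method Label stored in the output (`"snp_index"`, `"ed"`, ...).
#' @return Tibble `chrom`, `start`, `end`, `length_bp`, `n_markers`,
#'   `peak_stat`, `method`; zero rows if nothing passes.
#' @export
call_regions <- function(x, threshold, stat, min_markers = 3L,
                         max_gap_bp = 1e6, method = "scan") {
  windowed <- "window_start" %in% names(x)
  v <- x[[stat]]
  above <- !is.na(v) & v > threshold
  hits <- x[above, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_region_tibble())
  hits$.stat <- v[above]
  if (windowed) {
    hits$.start <- hits$window_start
    hits$.end <- hits$window_end
    if (!"n_markers" %in% names(hits)) hits$n_markers <- 1L
  } else {
    hits$.start <- hits$pos
    hits$.end <- hits$pos
    hits$n_markers <- 1L
  }
  res <- hits |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$.start)
      gap <- df$.start[-1L] - head(df$.end, -1L) - 1
      region_id <- cumsum(c(0, gap > max_gap_bp))
      df |>
        mutate(.region = region_id) |>
        group_by(.data$.region) |>
        summarise(start = min(.data$.start),
                  end = max(.data$.end) + if (windowed) 1 else 0,
                  n_markers = sum(.data$n_markers),
                  peak_stat = max(.data$.stat), .groups = "drop") |>
        select(-any_of(".region"))
    }) |>
    ungroup() |>
    filter(.data$n_markers >= min_markers) |>
    mutate(length_bp = .data$end - .data$start + 1, method = method) |>
    select("chrom", "start", "end", "length_bp", "n_markers",
           "peak_stat", "method") |>
    arrange(.data$chrom, .data$start)
  res
}

empty_region_tibble <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         length_bp = numeric(), n_markers = integer(),
         peak_stat = numeric(), method = character())
}

#' Select candidate SNPs inside called regions
#'
#' Keeps scan points that fall inside a candidate region (inclusive bounds)
#' and satisfy the two candidate-SNP criteria: main-allele frequency in the
#' mutant (long-spike) pool strictly above `maf_min` and raw ED strictly
#' above `ed_min`.
#'
#' @param points Scan tibble (needs `chrom`, `pos`, `maf_mut`, `ed`).
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param maf_min,ed_min Selection thresholds (defaults 0.75 and 0.50).
#' @return The selected scan rows.
#' @export
select_candidate_snps <- function(points, regions, maf_min = 0.75,
                                  ed_min = 0.50) {
  inside <- points_in_regions(points, regions)
  filter(inside, .data$maf_mut > maf_min, .data$ed > ed_min)
}

# rows of `points` lying inside any region (inclusive bounds)
points_in_regions <- function(points, regions) {
  if (nrow(points) == 0L || nrow(regions) == 0L) {
    return(points[0L, , drop = FALSE])
  }
  hit <- rep(FALSE, nrow(points))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (points$chrom == regions$chrom[i] &
                    points$pos >= regions$start[i] &
                    points$pos <= regions$end[i])
  }
  points[hit, , drop = FALSE]
}
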