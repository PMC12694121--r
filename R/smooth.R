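#' Windowed means of Delta(SNP-index) on a fixed genomic grid
#'
#' Averages the per-site Delta within fixed windows whose boundaries fall at
#' multiples of `step_bp` + 1 (so merged window runs reproduce the round
#' region boundaries conventional for windowed SNP-index scans). A window
#' `k` spans positions `k*step_bp + 1 .. k*step_bp + window_bp`; windows
#' with fewer than `min_markers` markers are masked (`NA` means).
#'
#' @param points Scan tibble (needs `chrom`, `pos`, `delta`).
#' @param window_bp,step_bp Window width and grid step in bp. With
#'   `step_bp < window_bp` the windows overlap.
#' @param min_markers Mask windows with fewer markers than this.
#' @return Tibble `chrom`, `window_start`, `window_end`, `n_markers`,
#'   `mean_delta`, `mean_abs_delta`.
#' @export
smooth_delta <- function(points, window_bp = 5e5, step_bp = 5e5,
                         min_markers = 3L) {
  stopifnot(window_bp > 0, step_bp > 0, step_bp <= window_bp)
  res <- points |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      if (nrow(df) == 0L) return(tibble())
      k_max <- floor((max(df$pos) - 1) / step_bp)
      grid <- 0:k_max
      out <- map_dfr(grid, function(k) {
        lo <- k * step_bp + 1
        hi <- k * step_bp + window_bp
        inside <- df$pos >= lo & df$pos <= hi
        n <- sum(inside)
        tibble(window_start = lo, window_end = hi, n_markers = n,
               mean_delta = if (n > 0L) mean(df$delta[inside]) else NA_real_,
               mean_abs_delta = if (n > 0L) abs(mean(df$delta[inside]))
                                else NA_real_)
      })
      out <- out[out$n_markers > 0L, , drop = FALSE]
      out$mean_delta[out$n_markers < min_markers] <- NA_real_
      out$mean_abs_delta[out$n_markers < min_markers] <- NA_real_
      out
    }) |>
    ungroup()
  res
}

#' Smooth the per-site ED statistic along each chromosome
#'
#' Fits a tricube-weighted local linear regression (degree-1 loess, exact
#' "direct" surface) of `ed^power` on position, separately per chromosome,
#' and attaches the fitted value to every site. Chromosomes with fewer than
#' `min_points` sites are skipped with a warning (`fitted_ed` stays `NA`).
#'
#' @param points Scan tibble (needs `chrom`, `pos`, `ed`).
#' @param power Power applied to ED before fitting (default 1).
#' @param span Local-regression span (fraction of sites in each
#'   neighbourhood).
#' @param min_points Minimum sites per chromosome to attempt a fit.
#' @return `points` with a `fitted_ed` column appended.
#' @export
fit_ed <- function(points, power = 1, span = 0.1, min_points = 10L) {
  points |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      df$fitted_ed <- NA_real_
      if (nrow(df) < max(2L, min_points)) {
        warn(sprintf("fit_ed: chromosome %s has %d site(s); skipped",
                     key$chrom, nrow(df)))
        return(df)
      }
      # loess needs enough neighbours for a degree-1 fit
      eff_span <- max(span, min(1, 5 / nrow(df)))
      fit <- loess(y ~ x,
                   data = data.frame(x = df$pos, y = df$ed^power),
                   span = eff_span, degree = 1, family = "gaussian",
                   surface = "direct")
      df$fitted_ed <- unname(predict(fit))
      df
    }) |>
    ungroup()
}

#' ED association threshold: median + k * SD of fitted values
#'
#' The standard deviation is the population form (n denominator), matching
#' the convention of fitted-value thresholds in pooled-sequencing scans.
#'
#' @param fitted_values Numeric vector of fitted ED values (NAs dropped).
#' @param k Multiplier (default 3).
#' @return The threshold value.
#' @examples
#' ed_threshold(c(0, 0, 0, 0, 10), k = 3)  # 0 + 3 * 4 = 12
#' @export
ed_threshold <- function(fitted_values, k = 3) {
  x <- fitted_values[!is.na(fitted_values)]
  if (length(x) == 0L) {
    abort("no fitted values supplied", class = "bsamapr_value_error")
  }
  sd_pop <- sqrt(mean((x - mean(x))^2))
  median(x) + k * sd_pop
}
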