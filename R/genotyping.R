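#' Call genotypes from two-channel KASP fluorescence
#'
#' Samples whose total signal falls below `ntc_floor` times the median total
#' are no-template controls (`NTC`). The remaining samples are clustered on
#' the normalised channel ratio `fam / (fam + hex)` by 3-means with
#' deterministic quantile initialisation, and clusters are mapped to
#' genotypes by ratio ordering: FAM-dominant cluster = allele-1 homozygote,
#' HEX-dominant = allele-2 homozygote, intermediate = heterozygote. If the
#' three cluster centres are not separated by at least `min_separation` the
#' samples are returned `undetermined` with a warning.
#'
#' @param fluorescence Tibble `sample_id`, `fam`, `hex`.
#' @param ntc_floor NTC cut as a fraction of the median total signal.
#' @param min_separation Minimum ratio distance between adjacent cluster
#'   centres.
#' @return Tibble `sample_id`, `fam`, `hex`, `ratio`, `call` with calls in
#'   `hom_allele1`, `het`, `hom_allele2`, `NTC`, `undetermined`.
#' @export
call_genotypes <- function(fluorescence, ntc_floor = 0.2,
                           min_separation = 0.1) {
  fl <- fluorescence
  total <- fl$fam + fl$hex
  is_ntc <- total == 0 | total < ntc_floor * median(total)
  fl$ratio <- ifelse(is_ntc, NA_real_, fl$fam / total)
  fl$call <- ifelse(is_ntc, "NTC", NA_character_)
  x <- fl$ratio[!is_ntc]
  if (length(x) == 0L) {
    return(fl[, c("sample_id", "fam", "hex", "ratio", "call")])
  }
  if (length(x) < 6L) {
    abort("need at least 6 non-NTC samples to cluster",
          class = "bsamapr_value_error")
  }
  centers <- unname(quantile(x, c(0.05, 0.5, 0.95), type = 7))
  undet <- function(msg) {
    warn(msg)
    fl$call[is.na(fl$call)] <- "undetermined"
    fl[, c("sample_id", "fam", "hex", "ratio", "call")]
  }
  if (length(unique(centers)) < 3L) {
    return(undet("fewer than 3 distinguishable clusters"))
  }
  km <- kmeans(x, centers = matrix(centers, ncol = 1L), iter.max = 100L)
  ord <- order(km$centers[, 1L], decreasing = TRUE)  # high FAM ratio first
  if (min(diff(sort(km$centers[, 1L]))) < min_separation) {
    return(undet("cluster centres closer than min_separation"))
  }
  labels <- c("hom_allele1", "het", "hom_allele2")[match(km$cluster, ord)]
  fl$call[!is_ntc] <- labels
  fl[, c("sample_id", "fam", "hex", "ratio", "call")]
}

#' Genotype-phenotype association test
#'
#' Two-sample Student's t-test (pooled variance) of the trait between the
#' two homozygote classes; heterozygotes are summarised but excluded from
#' the test, mirroring the two-group comparison of a dominant-trait KASP
#' validation.
#'
#' @param calls Genotype-call tibble from [call_genotypes()].
#' @param phenotypes Tibble `plant_id`/`sample_id` + `spike_length_cm` (the
#'   first column is matched to `sample_id`).
#' @return Object of class `kasp_assoc`: group summaries, `t`, `df`,
#'   `p_value`; `tidy()`/`glance()` methods available. If a homozygote
#'   class has fewer than 2 samples the test is skipped with a message and
#'   the statistics are `NA`.
#' @export
association_test <- function(calls, phenotypes) {
  ph <- phenotypes
  names(ph)[1L] <- "sample_id"
  value_col <- names(ph)[2L]
  df <- inner_join(calls, ph, by = "sample_id")
  groups <- df |>
    filter(.data$call %in% c("hom_allele1", "het", "hom_allele2")) |>
    group_by(.data$call) |>
    summarise(n = dplyr::n(), mean = mean(.data[[value_col]]),
              sd = sd(.data[[value_col]]), .groups = "drop")
  g1 <- df[[value_col]][df$call == "hom_allele1"]
  g2 <- df[[value_col]][df$call == "hom_allele2"]
  if (length(g1) < 2L || length(g2) < 2L) {
    inform("association test skipped: fewer than 2 samples in a homozygote class")
    tt <- NULL
  } else {
    tt <- t.test(g1, g2, var.equal = TRUE)
  }
  structure(list(
    groups = groups,
    t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value,
    n1 = length(g1), n2 = length(g2)
  ), class = "kasp_assoc")
}

#' @export
print.kasp_assoc <- function(x, ...) {
  cat("<kasp_assoc> homozygote-class Student's t-test\n")
  print(x$groups)
  cat(sprintf("t = %.3f, df = %.0f, p = %.3g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.kasp_assoc <- function(x, ...) {
  m1 <- x$groups$mean[x$groups$call == "hom_allele1"]
  m2 <- x$groups$mean[x$groups$call == "hom_allele2"]
  tibble(estimate = (if (length(m1) && length(m2)) m1 - m2 else NA_real_),
         statistic = x$t, df = x$df, p.value = x$p_value,
         n1 = x$n1, n2 = x$n2)
}

#' @export
glance.kasp_assoc <- function(x, ...) {
  tibble(statistic = x$t, df = x$df, p.value = x$p_value,
         n_groups = nrow(x$groups))
}

#' Summarise a phenotype table by group
#'
#' Per-group mean, SD and count; percent change of every group relative to
#' the baseline (`(mean_b - mean_a) / mean_a * 100`); pairwise Student's
#' t-tests against the baseline; and a Shapiro-Wilk normality check per
#' group (the conventional check that a segregating population's trait
#' distribution is consistent with a quantitative, polygenic basis).
#'
#' @param table Tibble with a numeric value column and a group column.
#' @param value,group Column names (defaults `spike_length_cm`, `group`).
#' @param baseline Reference group for percent change and tests (default:
#'   first group in order of appearance).
#' @return Object of class `phenotype_summary` with tibbles `groups`,
#'   `comparisons` and the baseline name.
#' @export
phenotype_summary <- function(table, value = "spike_length_cm",
                              group = "group", baseline = NULL) {
  v <- table[[value]]
  g <- as.character(table[[group]])
  stopifnot(is.numeric(v), !is.null(g))
  levels <- unique(g)
  baseline <- baseline %||% levels[1L]
  groups <- map_dfr(levels, function(lev) {
    x <- v[g == lev]
    tibble(group = lev, n = length(x), mean = mean(x),
           sd = if (length(x) >= 2L) sd(x) else NA_real_,
           shapiro_w = if (length(x) >= 3L && length(x) <= 5000L &&
                             sd(x) > 0)
             shapiro.test(x)$statistic[[1L]] else NA_real_,
           shapiro_p = if (length(x) >= 3L && length(x) <= 5000L &&
                             sd(x) > 0)
             shapiro.test(x)$p.value else NA_real_)
  })
  base_mean <- groups$mean[groups$group == baseline]
  comparisons <- map_dfr(setdiff(levels, baseline), function(lev) {
    x <- v[g == baseline]
    y <- v[g == lev]
    can_test <- length(x) >= 2L && length(y) >= 2L
    # constant data has no valid t statistic; report the summary without it
    tt <- if (can_test) tryCatch(t.test(y, x, var.equal = TRUE),
                                 error = function(e) NULL) else NULL
    can_test <- can_test && !is.null(tt)
    tibble(group = lev, baseline = baseline,
           percent_change = (mean(y) - mean(x)) / mean(x) * 100,
           t = if (can_test) unname(tt$statistic) else NA_real_,
           p_value = if (can_test) tt$p.value else NA_real_)
  })
  structure(list(groups = groups, comparisons = comparisons,
                 baseline = baseline),
            class = "phenotype_summary")
}

#' @export
print.phenotype_summary <- function(x, ...) {
  cat("<phenotype_summary> baseline:", x$baseline, "\n")
  print(x$groups)
  if (nrow(x$comparisons) > 0L) print(x$comparisons)
  invisible(x)
}

#' @export
tidy.phenotype_summary <- function(x, ...) x$comparisons

#' @export
glance.phenotype_summary <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), baseline = x$baseline,
         n_total = sum(x$groups$n))
}
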