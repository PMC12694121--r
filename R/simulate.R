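#' Simulate an F2 population segregating a major spike-length locus
#'
#' Draws genotypes for `n_f2` plants at every marker of the toy genome by
#' independent meioses of a fully heterozygous F1 (both parents homozygous and
#' divergent at all marker sites), with Haldane recombination along each
#' chromosome, and assigns each plant a trait value
#' `base_mean + additive_effect * [hom mutant] + dominance * [het] + N(0, env_sd)`.
#'
#' Marker positions are drawn uniformly per chromosome (one marker is forced
#' onto the causal position, keeping exactly `n_sites` markers per
#' chromosome). Each marker receives a parent-discriminating substitution:
#' with probability `ems_fraction` a G->A or C->T transition (the EMS
#' spectrum), otherwise one of the ten remaining ordered substitutions.
#'
#' @param config A [sim_config()].
#' @return An object of class `f2_truth`: a list with `genotypes` (integer
#'   matrix, plants x markers, counting copies of the mutant allele),
#'   `phenotypes` (tibble `plant_id`, `spike_length_cm`), `markers` (tibble
#'   with chrom, pos, map position in cM, ref/alt alleles and `is_causal`),
#'   `causal` (list chrom/pos/marker_id) and the `config` used.
#' @examples
#' truth <- simulate_f2(sim_config(n_f2 = 40, n_sites = 25, seed = 1))
#' dim(truth$genotypes)
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  markers <- make_marker_map(config)
  n <- config$n_f2
  geno <- matrix(0L, nrow = n, ncol = nrow(markers))
  for (chrom in names(config$chrom_lengths)) {
    idx <- which(markers$chrom == chrom)
    r <- haldane_r(diff(markers$cm[idx]))
    geno[, idx] <- sim_gametes(n, r) + sim_gametes(n, r)
  }
  plant_ids <- sprintf("F2_%04d", seq_len(n))
  marker_ids <- sprintf("%s_%d", markers$chrom, markers$pos)
  dimnames(geno) <- list(plant_ids, marker_ids)

  g_causal <- geno[, which(markers$is_causal)]
  trait <- config$base_mean +
    ifelse(g_causal == 2L, config$additive_effect,
           ifelse(g_causal == 1L, config$dominance, 0)) +
    rnorm(n, 0, config$env_sd)

  structure(list(
    genotypes = geno,
    phenotypes = tibble(plant_id = plant_ids, spike_length_cm = trait),
    markers = mutate(markers, marker_id = marker_ids, .before = 1),
    causal = list(chrom = config$causal_chrom, pos = config$causal_pos,
                  marker_id = marker_ids[which(markers$is_causal)]),
    config = config
  ), class = "f2_truth")
}

#' @export
print.f2_truth <- function(x, ...) {
  cat("<f2_truth>", nrow(x$genotypes), "F2 plants,",
      ncol(x$genotypes), "markers on",
      length(unique(x$markers$chrom)), "chromosomes\n")
  cat("  causal locus:", x$causal$marker_id, "\n")
  cat("  spike length:", sprintf("%.2f-%.2f cm",
      min(x$phenotypes$spike_length_cm), max(x$phenotypes$spike_length_cm)),
      "\n")
  invisible(x)
}

# Haldane map function: recombination fraction from distance in cM
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# n gametes along a chromosome with recombination fractions r between
# adjacent markers; returns an n x (length(r) + 1) 0/1 allele matrix
sim_gametes <- function(n, r) {
  m <- length(r) + 1L
  a0 <- rbinom(n, 1L, 0.5)
  if (m == 1L) return(matrix(a0, ncol = 1L))
  sw <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)), nrow = n)
  sw_cum <- if (ncol(sw) == 1L) sw else t(apply(sw, 1L, cumsum))
  (a0 + cbind(0L, sw_cum)) %% 2L
}

make_marker_map <- function(config) {
  maps <- lapply(names(config$chrom_lengths), function(chrom) {
    len <- config$chrom_lengths[[chrom]]
    if (chrom == config$causal_chrom) {
      pool <- setdiff(seq_len(len), config$causal_pos)
      pos <- sort(c(sample(pool, config$n_sites - 1L), config$causal_pos))
    } else {
      pos <- sort(sample(len, config$n_sites))
    }
    tibble(chrom = chrom, pos = as.integer(pos),
           cm = pos / 1e6 * config$cm_per_mb,
           is_causal = chrom == config$causal_chrom &
             pos == config$causal_pos)
  })
  markers <- bind_rows(maps)
  bind_cols(markers, draw_substitutions(nrow(markers), config$ems_fraction))
}

# EMS-biased substitution spectrum: G->A / C->T with prob ems_fraction,
# otherwise uniform over the ten remaining ordered base substitutions
draw_substitutions <- function(n, ems_fraction) {
  all_pairs <- expand.grid(ref = BASES, alt = BASES,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$ref != all_pairs$alt, ]
  ems <- paste(all_pairs$ref, all_pairs$alt) %in% c("G A", "C T")
  is_ems <- runif(n) < ems_fraction
  i_ems <- sample(which(ems), n, replace = TRUE)
  i_oth <- sample(which(!ems), n, replace = TRUE)
  i <- ifelse(is_ems, i_ems, i_oth)
  tibble(ref = all_pairs$ref[i], alt = all_pairs$alt[i])
}

#' Select the extreme-phenotype tail pools
#'
#' Picks the `pool_size` plants with the longest spikes (long pool, "aa") and
#' the `pool_size` with the shortest (short pool, "ab"). Ties are broken by
#' plant id so the selection is deterministic.
#'
#' @param truth An [simulate_f2()] result.
#' @param pool_size Plants per pool; defaults to the simulated config's value.
#' @return A list with character vectors `long` and `short` of plant ids.
#' @examples
#' truth <- simulate_f2(sim_config(n_f2 = 40, n_sites = 25, seed = 1))
#' pools <- select_tail_pools(truth, 5)
#' length(intersect(pools$long, pools$short)) # disjoint
#' @export
select_tail_pools <- function(truth, pool_size = truth$config$pool_size) {
  stopifnot(inherits(truth, "f2_truth"))
  ph <- truth$phenotypes
  if (2L * pool_size > nrow(ph)) {
    abort("pool_size too large: the two tails must be disjoint",
          class = "bsamapr_size_error")
  }
  long <- ph$plant_id[order(-ph$spike_length_cm, ph$plant_id)][1:pool_size]
  short <- ph$plant_id[order(ph$spike_length_cm, ph$plant_id)][1:pool_size]
  list(long = long, short = short)
}

#' Simulate pooled base depths at one site
#'
#' Sequencing model: total depth ~ Poisson(`mean_depth`); mutant-allele reads
#' ~ Binomial(depth, `allele_freq`); each read is miscalled with probability
#' `error_rate`, landing uniformly on one of the two bases that are not the
#' site's segregating alleles.
#'
#' @param allele_freq Mutant-allele frequency in the pool, in \[0, 1\].
#' @param config A [sim_config()] (supplies `mean_depth`, `error_rate`).
#' @param ref,alt The wild-type and mutant allele bases.
#' @return Named integer vector of A, C, G, T read counts.
#' @examples
#' simulate_pool_depths(0.5, sim_config(seed = 2))
#' @export
simulate_pool_depths <- function(allele_freq, config, ref = "G", alt = "A") {
  stopifnot(allele_freq >= 0, allele_freq <= 1, ref %in% BASES,
            alt %in% BASES, ref != alt)
  m <- sim_depth_quads(allele_freq, config$mean_depth, config$error_rate,
                       ref, alt)
  setNames(as.integer(m[1L, ]), BASES)
}

# vectorised depth model over sites: freq, ref, alt recycled to length n
sim_depth_quads <- function(freq, mean_depth, error_rate, ref, alt) {
  n <- length(freq)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  depth <- rpois(n, mean_depth)
  n_alt <- rbinom(n, depth, freq)
  n_ref <- depth - n_alt
  err_ref <- rbinom(n, n_ref, error_rate)
  err_alt <- rbinom(n, n_alt, error_rate)
  n_err <- err_ref + err_alt
  # split errors between the two non-allele bases
  err_b1 <- rbinom(n, n_err, 0.5)
  m <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  i <- seq_len(n)
  m[cbind(i, match(ref, BASES))] <- n_ref - err_ref
  m[cbind(i, match(alt, BASES))] <- n_alt - err_alt
  others <- vapply(i, function(k) setdiff(BASES, c(ref[k], alt[k])),
                   character(2))
  m[cbind(i, match(others[1L, ], BASES))] <-
    m[cbind(i, match(others[1L, ], BASES))] + err_b1
  m[cbind(i, match(others[2L, ], BASES))] <-
    m[cbind(i, match(others[2L, ], BASES))] + (n_err - err_b1)
  m
}

#' Build a pooled variant tibble directly from a simulated truth set
#'
#' Draws pooled and parental read depths for every marker exactly as
#' [emit_dataset()] would write them to VCF, but returns the in-memory
#' variant tibble instead, which is convenient for replicate studies that
#' never need the files.
#'
#' @param truth An `f2_truth` object.
#' @param config The [sim_config()] used to simulate it.
#' @return A variant tibble in the [read_pooled_vcf()] layout.
#' @export
simulate_records <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "f2_truth"))
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
  i <- seq_len(nrow(mk))
  ad <- function(role, which) {
    q <- quads[[role]]
    q[cbind(i, match(if (which == "ref") mk$ref else mk$alt, BASES))]
  }
  tibble(
    chrom = mk$chrom, pos = mk$pos, ref = mk$ref, alt = mk$alt,
    variant_class = "SNP",
    wt_ref = ad("parent_wt", "ref"), wt_alt = ad("parent_wt", "alt"),
    mut_ref = ad("parent_mut", "ref"), mut_alt = ad("parent_mut", "alt"),
    short_ref = ad("pool_short", "ref"),
    short_alt = ad("pool_short", "alt"),
    long_ref = ad("pool_long", "ref"), long_alt = ad("pool_long", "alt")
  )
}

#' Simulate two-channel KASP fluorescence for known genotypes
#'
#' Places the three genotype classes at canonical endpoint positions in
#' (FAM, HEX) signal space -- allele-1 homozygotes FAM-dominant, allele-2
#' homozygotes HEX-dominant, heterozygotes intermediate -- adds Gaussian
#' noise, and appends no-template controls near the origin.
#'
#' @param genotypes Integer vector of allele-2 dosages (0, 1, 2), optionally
#'   named by sample id.
#' @param noise_sd Standard deviation of the signal noise (signal units;
#'   cluster separation is ~0.9 units).
#' @param n_ntc Number of no-template controls appended.
#' @param seed Optional seed.
#' @return Tibble `sample_id`, `fam`, `hex`, `true_genotype`.
#' @export
simulate_fluorescence <- function(genotypes, noise_sd = 0.05, n_ntc = 2L,
                                  seed = NULL) {
  stopifnot(all(genotypes %in% 0:2))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(genotypes) %||% sprintf("S%03d", seq_along(genotypes))
  centers <- rbind(`0` = c(1.0, 0.12), `1` = c(0.6, 0.6), `2` = c(0.12, 1.0))
  xy <- centers[as.character(genotypes), , drop = FALSE] +
    matrix(rnorm(2L * length(genotypes), 0, noise_sd), ncol = 2L)
  out <- tibble(sample_id = ids,
                fam = pmax(xy[, 1L], 0), hex = pmax(xy[, 2L], 0),
                true_genotype = as.integer(genotypes))
  if (n_ntc > 0L) {
    ntc <- tibble(sample_id = sprintf("NTC%02d", seq_len(n_ntc)),
                  fam = abs(rnorm(n_ntc, 0.02, 0.01)),
                  hex = abs(rnorm(n_ntc, 0.02, 0.01)),
                  true_genotype = NA_integer_)
    out <- bind_rows(out, ntc)
  }
  out
}
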