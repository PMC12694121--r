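#' Configuration for the F2 pooled-sequencing simulator
#'
#' Bundles every tunable of the synthetic BSA-seq experiment: the size of the
#' F2 population and tail pools, the toy genome, the mutation spectrum of the
#' EMS-derived parent, the genetic architecture of the trait, and the
#' sequencing model.
#'
#' The defaults describe a desk-scale version of a wheat F2 mapping cross:
#' 200 plants scored for spike length, 30-plant extreme tails pooled and
#' sequenced to ~50x, a toy genome of three 2-Mb chromosomes with 500 marker
#' sites each, and a single dominant major locus on chromosome "1A" against a
#' Gaussian residual that absorbs the polygenic background. Recombination uses
#' a Haldane map at `cm_per_mb` centimorgan per megabase. The default of 200
#' makes the 6-Mb toy genome carry ~1200 cM of map, conserving the total
#' genetic length of a plant genome rather than its per-Mb recombination
#' density: a mapped locus then occupies a small fraction of the genome, as
#' in a real cross, which is what genome-wide association thresholds (e.g.
#' median + 3 SD of fitted values) implicitly assume.
#'
#' @param n_f2 Number of F2 plants.
#' @param pool_size Plants per extreme-phenotype pool.
#' @param mean_depth Expected pooled read depth per site (Poisson mean).
#' @param n_sites Marker count per chromosome.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param ems_fraction Fraction of mutant-parent alleles that are G:C->A:T
#'   transitions (EMS signature).
#' @param causal_chrom,causal_pos Location of the major spike-length locus.
#' @param additive_effect Spike length (cm) added in the homozygous mutant.
#' @param dominance Spike length (cm) added in the heterozygote. Defaults to
#'   `additive_effect` (complete dominance, as in the modelled cross).
#' @param env_sd Residual standard deviation (cm).
#' @param base_mean Homozygous wild-type spike-length mean (cm).
#' @param error_rate Per-read base-miscall probability. A miscalled read lands
#'   uniformly on one of the two bases that are not the site's segregating
#'   alleles, so sequencing error never converts one allele into the other.
#' @param cm_per_mb Recombination density, cM per Mb (Haldane map function).
#' @param seed Optional random seed; when set, all simulator output is
#'   reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_f2 = 50, n_sites = 40, seed = 1)
#' cfg$pool_size
#' @export
sim_config <- function(n_f2 = 200L,
                       pool_size = 30L,
                       mean_depth = 50,
                       n_sites = 500L,
                       chrom_lengths = c("1A" = 2e6, "2B" = 2e6, "3D" = 2e6),
                       ems_fraction = 0.9,
                       causal_chrom = "1A",
                       causal_pos = 1.25e6,
                       additive_effect = 2.1,
                       dominance = additive_effect,
                       env_sd = 0.8,
                       base_mean = 7.0,
                       error_rate = 0.001,
                       cm_per_mb = 200,
                       seed = NULL) {
  cfg <- list(
    n_f2 = as.integer(n_f2), pool_size = as.integer(pool_size),
    mean_depth = mean_depth, n_sites = as.integer(n_sites),
    chrom_lengths = chrom_lengths, ems_fraction = ems_fraction,
    causal_chrom = causal_chrom, causal_pos = causal_pos,
    additive_effect = additive_effect, dominance = dominance,
    env_sd = env_sd, base_mean = base_mean, error_rate = error_rate,
    cm_per_mb = cm_per_mb, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "bsamapr_config_error")
  counts <- c(n_f2 = cfg$n_f2, pool_size = cfg$pool_size,
              n_sites = cfg$n_sites)
  if (any(is.na(counts)) || any(counts <= 0L)) {
    bad("n_f2, pool_size and n_sites must all be positive counts")
  }
  if (2L * cfg$pool_size > cfg$n_f2) {
    bad("pool_size must not exceed n_f2 / 2 (pools are disjoint tails)")
  }
  if (cfg$mean_depth <= 0) bad("mean_depth must be positive")
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0)) {
    bad("chrom_lengths must be a named vector of positive lengths")
  }
  for (p in c("ems_fraction", "error_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad(paste(p, "must lie in [0, 1]"))
  }
  if (!cfg$causal_chrom %in% names(cfg$chrom_lengths)) {
    bad("causal_chrom is not one of the simulated chromosomes")
  }
  if (cfg$causal_pos < 1 ||
      cfg$causal_pos > cfg$chrom_lengths[[cfg$causal_chrom]]) {
    bad("causal_pos falls outside its chromosome")
  }
  if (cfg$env_sd < 0) bad("env_sd must be non-negative")
  if (cfg$cm_per_mb <= 0) bad("cm_per_mb must be positive")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  F2 plants:", x$n_f2, " pools:", x$pool_size, "x2",
      " depth:", x$mean_depth, "x\n")
  cat("  genome:", length(x$chrom_lengths), "chromosomes,",
      x$n_sites, "markers each;", x$cm_per_mb, "cM/Mb\n")
  cat("  causal locus:", x$causal_chrom, "@", format(x$causal_pos,
      big.mark = ","), "\n")
  cat("  trait: base", x$base_mean, "cm, +", x$additive_effect,
      "(hom), +", x$dominance, "(het), sd", x$env_sd, "cm\n")
  invisible(x)
}
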