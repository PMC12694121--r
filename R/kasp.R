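#' GC fraction of a primer or flank sequence
#'
#' @param seq Non-empty A/C/G/T string (vectorised).
#' @return Fraction of G+C bases.
#' @examples
#' gc_fraction("ATGC")  # 0.5
#' @export
gc_fraction <- function(seq) {
  if (any(nchar(seq) == 0L) || any(grepl("[^ACGT]", seq))) {
    abort("sequences must be non-empty A/C/G/T strings",
          class = "bsamapr_value_error")
  }
  vapply(strsplit(seq, ""), function(b) mean(b %in% c("G", "C")),
         numeric(1))
}

# unified nearest-neighbor parameters (SantaLucia & Hicks 2004):
# dH kcal/mol, dS cal/(mol K), duplex values keyed by the top-strand dinuc
NN_DH <- c(AA = -7.6, TT = -7.6, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -21.3, TT = -21.3, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer melting temperature (unified nearest-neighbor model)
#'
#' Computes Tm from unified nearest-neighbor enthalpy/entropy sums with
#' duplex initiation, terminal A:T penalties, a monovalent-salt entropy
#' correction `0.368 (N-1) ln[Na+]`, and the non-self-complementary
#' two-state formula `Tm = 1000 dH / (dS + R ln(C_T / 4)) - 273.15` with
#' `C_T` the total primer concentration.
#'
#' @param seq A/C/G/T string of length >= 8 (vectorised).
#' @param salt_mM Monovalent cation concentration in mM (default 50).
#' @param primer_nM Total primer concentration in nM (default 200).
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("TTGACCGTAGGCATCAAGTGCCTAT")
#' @export
melting_temperature <- function(seq, salt_mM = 50, primer_nM = 200) {
  if (any(nchar(seq) < 8L)) {
    abort("sequences shorter than 8 nt have no reliable two-state Tm",
          class = "bsamapr_value_error")
  }
  if (any(grepl("[^ACGT]", seq))) {
    abort("sequences must be A/C/G/T strings", class = "bsamapr_value_error")
  }
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    dinucs <- paste0(b[-n], b[-1L])
    dh <- 0.2 + sum(NN_DH[dinucs])
    ds <- -5.7 + sum(NN_DS[dinucs])
    for (endb in b[c(1L, n)]) {
      if (endb %in% c("A", "T")) {
        dh <- dh + 2.2
        ds <- ds + 6.9
      }
    }
    ds <- ds + 0.368 * (n - 1L) * log(salt_mM / 1000)
    1000 * dh / (ds + 1.987 * log(primer_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count exact occurrences of a flank in the genome (both strands)
#'
#' @param flank_seq A/C/G/T string.
#' @param genome FASTA path, named character vector or `DNAStringSet`.
#' @return Integer occurrence count over both strands.
#' @export
count_flank_copies <- function(flank_seq, genome) {
  g <- as_genome(genome)
  pat <- Biostrings::DNAString(flank_seq)
  rc <- Biostrings::reverseComplement(pat)
  sum(vapply(seq_along(g), function(i) {
    Biostrings::countPattern(pat, g[[i]]) +
      Biostrings::countPattern(rc, g[[i]])
  }, integer(1)))
}

#' Constraint set for KASP assay design
#'
#' Defaults encode the standard assay window: 19-30 nt primers, 80-150 bp
#' products, 59-65 degC melting temperatures, 40-60 % GC (applied to the
#' SNP flank for locus retention and, by common practice, to each primer --
#' disable the latter with `check_primer_gc = FALSE`), and fewer than
#' `max_copies` exact flank occurrences in the genome. Optional fluorescent
#' tail sequences are appended verbatim to the allele-specific primers and
#' excluded from all Tm/GC checks.
#'
#' @param primer_len,product_len,tm_range,gc_range Length-2 (min, max)
#'   windows.
#' @param max_copies Loci with this many flank copies or more are rejected
#'   (default 3, i.e. "fewer than three copies").
#' @param check_primer_gc Also apply `gc_range` to each primer.
#' @param salt_mM,primer_nM Conditions passed to [melting_temperature()].
#' @param tails Optional named character vector
#'   `c(allele1 = ..., allele2 = ...)` of 5' tail sequences.
#' @return A `kasp_constraints` list.
#' @export
kasp_constraints <- function(primer_len = c(19L, 30L),
                             product_len = c(80L, 150L),
                             tm_range = c(59, 65),
                             gc_range = c(0.40, 0.60),
                             max_copies = 3L,
                             check_primer_gc = TRUE,
                             salt_mM = 50, primer_nM = 200,
                             tails = NULL) {
  structure(list(primer_len = as.integer(primer_len),
                 product_len = as.integer(product_len),
                 tm_range = tm_range, gc_range = gc_range,
                 max_copies = as.integer(max_copies),
                 check_primer_gc = check_primer_gc,
                 salt_mM = salt_mM, primer_nM = primer_nM, tails = tails),
            class = "kasp_constraints")
}

#' Design a KASP assay for one SNP
#'
#' Enumerates allele-specific forward primers ending at the SNP (the two
#' differ only at their 3' terminal base, one per allele) and common reverse
#' primers on the opposite strand within the product-length window, keeps
#' the combinations satisfying every constraint, and returns the best under
#' a deterministic ranking: smallest Tm spread across the three primers,
#' then shortest product, then shortest primers. Infeasible loci give a
#' design-failure result (not an error) listing the violated constraints.
#'
#' @param flank A/C/G/T string of odd length with the SNP at its centre
#'   (conventionally 150 bp each side).
#' @param alleles Character vector of the two SNP bases; the first must
#'   match the flank's centre base.
#' @param genome Genome for the flank copy-number check (`NULL` skips it).
#' @param constraints A [kasp_constraints()].
#' @param snp_id Identifier stored in the assay.
#' @return An object of class `kasp_assay`: `snp_id`, `feasible`, `primers`
#'   (tibble role/sequence/length/gc/tm), `product_length`, `flank_copies`,
#'   `tm_spread`, `reasons` (when infeasible).
#' @export
design_kasp <- function(flank, alleles, genome = NULL,
                        constraints = kasp_constraints(),
                        snp_id = "snp") {
  cns <- constraints
  n <- nchar(flank)
  if (n %% 2L != 1L) {
    abort("flank must have odd length with the SNP at its centre",
          class = "bsamapr_value_error")
  }
  ctr <- (n + 1L) %/% 2L
  ctr_base <- substr(flank, ctr, ctr)
  if (length(alleles) != 2L || !all(alleles %in% BASES) ||
      alleles[1L] != ctr_base) {
    abort("alleles must be the two SNP bases, the first matching the flank centre",
          class = "bsamapr_value_error")
  }
  failure <- function(reasons) {
    structure(list(snp_id = snp_id, feasible = FALSE, primers = NULL,
                   product_length = NA_integer_, flank_copies = copies,
                   tm_spread = NA_real_, reasons = reasons),
              class = "kasp_assay")
  }

  copies <- if (is.null(genome)) NA_integer_ else
    count_flank_copies(flank, genome)
  locus_reasons <- character()
  flank_gc <- gc_fraction(flank)
  if (flank_gc < cns$gc_range[1L] || flank_gc > cns$gc_range[2L]) {
    locus_reasons <- c(locus_reasons, "flank GC outside range")
  }
  if (!is.na(copies) && copies >= cns$max_copies) {
    locus_reasons <- c(locus_reasons, "flank copy number too high")
  }
  if (length(locus_reasons) > 0L) return(failure(locus_reasons))

  tm_of <- function(s) melting_temperature(s, cns$salt_mM, cns$primer_nM)
  in_rng <- function(x, rng) x >= rng[1L] & x <= rng[2L]

  lens <- cns$primer_len[1L]:cns$primer_len[2L]
  # allele-specific forward primers: shared core, 3' base = allele
  fwd <- tidyr::expand_grid(L = lens)
  fwd$p1 <- vapply(fwd$L, function(L) {
    paste0(substr(flank, ctr - L + 1L, ctr - 1L), alleles[1L])
  }, character(1))
  fwd$p2 <- vapply(fwd$L, function(L) {
    paste0(substr(flank, ctr - L + 1L, ctr - 1L), alleles[2L])
  }, character(1))
  fwd$tm1 <- tm_of(fwd$p1)
  fwd$tm2 <- tm_of(fwd$p2)
  fwd$gc1 <- gc_fraction(fwd$p1)
  fwd$gc2 <- gc_fraction(fwd$p2)
  fwd$ok <- in_rng(fwd$tm1, cns$tm_range) & in_rng(fwd$tm2, cns$tm_range) &
    (!cns$check_primer_gc |
       (in_rng(fwd$gc1, cns$gc_range) & in_rng(fwd$gc2, cns$gc_range)))

  # reverse primers indexed by amplicon end e and primer length Lr
  combos <- tidyr::expand_grid(
    L = lens, P = cns$product_len[1L]:cns$product_len[2L], Lr = lens)
  combos$s <- ctr - combos$L + 1L
  combos$e <- combos$s + combos$P - 1L
  combos <- combos[combos$e <= n & combos$e - combos$Lr + 1L > ctr, ,
                   drop = FALSE]
  if (nrow(combos) == 0L) return(failure("no primer geometry fits the flank"))
  rev_tbl <- distinct(combos[, c("e", "Lr")])
  rev_tbl$seq <- vapply(seq_len(nrow(rev_tbl)), function(i) {
    revcomp(substr(flank, rev_tbl$e[i] - rev_tbl$Lr[i] + 1L, rev_tbl$e[i]))
  }, character(1))
  rev_tbl$tm <- tm_of(rev_tbl$seq)
  rev_tbl$gc <- gc_fraction(rev_tbl$seq)
  rev_tbl$ok <- in_rng(rev_tbl$tm, cns$tm_range) &
    (!cns$check_primer_gc | in_rng(rev_tbl$gc, cns$gc_range))

  combos <- left_join(combos, rev_tbl, by = c("e", "Lr")) |>
    left_join(fwd[, c("L", "tm1", "tm2", "ok")], by = "L",
              suffix = c("_rev", "_fwd"))
  valid <- combos[combos$ok_fwd & combos$ok_rev, , drop = FALSE]
  if (nrow(valid) == 0L) {
    reasons <- character()
    if (!any(fwd$ok)) reasons <- c(reasons,
      "no allele-specific primer within Tm/GC constraints")
    if (!any(rev_tbl$ok)) reasons <- c(reasons,
      "no common reverse primer within Tm/GC constraints")
    if (length(reasons) == 0L) reasons <- "no compatible primer combination"
    return(failure(reasons))
  }
  valid$tm_spread <- pmax(valid$tm1, valid$tm2, valid$tm) -
    pmin(valid$tm1, valid$tm2, valid$tm)
  best <- valid[order(valid$tm_spread, valid$P, valid$L, valid$Lr), ,
                drop = FALSE][1L, ]
  f <- fwd[fwd$L == best$L, ]
  tails <- cns$tails
  primers <- tibble(
    role = c("allele1_forward", "allele2_forward", "common_reverse"),
    allele = c(alleles, NA_character_),
    sequence = c(f$p1, f$p2, best$seq),
    tailed_sequence = c(
      if (!is.null(tails)) paste0(tails[[1L]], f$p1) else f$p1,
      if (!is.null(tails)) paste0(tails[[2L]], f$p2) else f$p2,
      best$seq),
    length = nchar(c(f$p1, f$p2, best$seq)),
    gc = gc_fraction(c(f$p1, f$p2, best$seq)),
    tm = c(f$tm1, f$tm2, best$tm)
  )
  structure(list(snp_id = snp_id, feasible = TRUE, primers = primers,
                 product_length = as.integer(best$P),
                 flank_copies = copies,
                 tm_spread = best$tm_spread, reasons = character()),
            class = "kasp_assay")
}

#' @export
print.kasp_assay <- function(x, ...) {
  cat("<kasp_assay>", x$snp_id,
      if (x$feasible) "(feasible)" else "(design failure)", "\n")
  if (x$feasible) {
    print(x$primers[, c("role", "sequence", "length", "gc", "tm")])
    cat("product:", x$product_length, "bp; Tm spread:",
        round(x$tm_spread, 2), "degC\n")
  } else {
    cat("reasons:", paste(x$reasons, collapse = "; "), "\n")
  }
  invisible(x)
}
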