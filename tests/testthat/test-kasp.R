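test_that("GC fraction is exact and validates its input", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction(c("AT", "GC")), c(0, 1))
  expect_error(gc_fraction("ATNX"), class = "bsamapr_value_error")
  expect_error(gc_fraction(""), class = "bsamapr_value_error")
})

test_that("nearest-neighbor Tm matches an independent reference implementation", {
  # expected values computed with an independent implementation of the
  # unified nearest-neighbor tables at 50 mM monovalent salt, 200 nM primer
  cases <- tibble::tibble(
    seq = c("GCTAGCTAGGATCCGATCGA", "ATGCATGCATGCATGCATGCA",
            "GGCCGGCCGGCCGGCCGGCC", "ATATATATATATATATATAT",
            "CAGTTCGGAAT", "TTGACCGTAGGCATCAAGTGCCTAT"),
    tm = c(54.318059, 58.743570, 76.344672, 25.978793, 28.940488,
           59.571647))
  got <- melting_temperature(cases$seq)
  expect_true(all(abs(got - cases$tm) < 0.5))
  # GC-rich primers melt higher than AT-rich ones of equal length
  expect_gt(melting_temperature("GGCCGGCCGGCCGGCCGGCC"),
            melting_temperature("ATATATATATATATATATAT"))
  expect_error(melting_temperature("ACGTAC"), class = "bsamapr_value_error")
  # higher salt stabilises the duplex
  expect_gt(melting_temperature("GCTAGCTAGGATCCGATCGA", salt_mM = 500),
            melting_temperature("GCTAGCTAGGATCCGATCGA", salt_mM = 50))
})

test_that("flank copy counting is exact on both strands", {
  insert <- "ACGTTAGCCGGAATTCGCGA"
  genome <- c(c1 = paste0(random_genome_string(5000, seed = 61), insert,
                          random_genome_string(5000)))
  expect_equal(count_flank_copies(insert, genome), 1)
  g3 <- c(c1 = paste0(insert, random_genome_string(2000), insert,
                      random_genome_string(2000),
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(insert)))))
  expect_equal(count_flank_copies(insert, g3), 3)

  # brute-force scan oracle on a 100 kb toy genome
  set.seed(62)
  big <- random_genome_string(1e5)
  probe <- substr(big, 5001, 5012)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe)))
  brute <- length(gregexpr(probe, big, fixed = TRUE)[[1]]) +
    if (gregexpr(rc, big, fixed = TRUE)[[1]][1] > 0)
      length(gregexpr(rc, big, fixed = TRUE)[[1]]) else 0
  expect_equal(count_flank_copies(probe, c(c1 = big)), brute)
})

test_that("designed assays satisfy every published constraint", {
  set.seed(70)
  n_checked <- 0
  for (s in 1:12) {
    fx <- feasible_flank(700 + s)
    a <- fx$assay
    p <- a$primers
    expect_true(a$feasible)
    # the two allele-specific primers differ only at the 3' terminal base
    f1 <- p$sequence[1]
    f2 <- p$sequence[2]
    expect_equal(nchar(f1), nchar(f2))
    expect_identical(substr(f1, 1, nchar(f1) - 1),
                     substr(f2, 1, nchar(f2) - 1))
    expect_equal(substr(f1, nchar(f1), nchar(f1)), fx$alleles[1])
    expect_equal(substr(f2, nchar(f2), nchar(f2)), fx$alleles[2])
    expect_true(all(p$length >= 19 & p$length <= 30))
    expect_true(all(p$tm >= 59 & p$tm <= 65))
    expect_true(all(p$gc >= 0.40 & p$gc <= 0.60))
    expect_true(a$product_length >= 80 && a$product_length <= 150)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 12)
})

test_that("design is deterministic and equals exhaustive enumeration", {
  fx <- feasible_flank(81)
  again <- design_kasp(fx$flank, fx$alleles)
  expect_identical(fx$assay$primers, again$primers)
  expect_identical(fx$assay$product_length, again$product_length)

  # independent exhaustive search with the same ranking
  cns <- kasp_constraints()
  ctr <- 151
  n <- 301
  best <- NULL
  for (L in 19:30) {
    f1 <- paste0(substr(fx$flank, ctr - L + 1, ctr - 1), fx$alleles[1])
    f2 <- paste0(substr(fx$flank, ctr - L + 1, ctr - 1), fx$alleles[2])
    tms <- melting_temperature(c(f1, f2))
    gcs <- gc_fraction(c(f1, f2))
    if (any(tms < 59 | tms > 65) || any(gcs < 0.4 | gcs > 0.6)) next
    for (P in 80:150) {
      e <- (ctr - L + 1) + P - 1
      if (e > n) next
      for (Lr in 19:30) {
        if (e - Lr + 1 <= ctr) next
        rseq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(substr(fx$flank, e - Lr + 1, e))))
        tmr <- melting_temperature(rseq)
        gcr <- gc_fraction(rseq)
        if (tmr < 59 || tmr > 65 || gcr < 0.4 || gcr > 0.6) next
        spread <- max(c(tms, tmr)) - min(c(tms, tmr))
        key <- c(spread, P, L, Lr)
        lex_less <- function(a, b) {
          d <- a - b
          i <- which(d != 0)
          length(i) > 0 && d[i[1]] < 0
        }
        if (is.null(best) || lex_less(key, best$key)) {
          best <- list(key = key, f1 = f1, f2 = f2, rseq = rseq, P = P)
        }
      }
    }
  }
  expect_equal(fx$assay$primers$sequence, c(best$f1, best$f2, best$rseq))
  expect_equal(fx$assay$product_length, best$P)
})

test_that("hopeless flanks fail with an explanatory reason", {
  at_flank <- paste(rep(c("A", "T"), length.out = 301), collapse = "")
  a <- design_kasp(at_flank, c("A", "G"))
  expect_false(a$feasible)
  expect_match(paste(a$reasons, collapse = " "), "GC|Tm")
  # a triplicated flank is rejected on copy number
  fx <- feasible_flank(83)
  g <- c(c1 = paste0(fx$flank, random_genome_string(500, seed = 84),
                     fx$flank, random_genome_string(500), fx$flank))
  a3 <- design_kasp(fx$flank, fx$alleles, genome = g)
  expect_false(a3$feasible)
  expect_match(paste(a3$reasons, collapse = " "), "copy")
})

test_that("genotype clustering recovers well-separated and noisy clusters", {
  fl <- simulate_fluorescence(rep(0:2, each = 30), noise_sd = 0.02,
                              seed = 90)
  calls <- call_genotypes(fl)
  truth <- c("hom_allele1", "het", "hom_allele2")[fl$true_genotype + 1]
  non_ntc <- !is.na(fl$true_genotype)
  expect_true(all(calls$call[non_ntc] == truth[non_ntc]))
  expect_true(all(calls$call[!non_ntc] == "NTC"))

  # all samples at the origin are no-template controls
  origin <- tibble::tibble(sample_id = sprintf("s%d", 1:8), fam = 0, hex = 0)
  expect_true(all(call_genotypes(origin)$call == "NTC"))

  # sigma = 5% of the cluster separation, 90 samples, 20 seeds
  acc <- vapply(1:20, function(s) {
    fl <- simulate_fluorescence(rep(0:2, each = 30), noise_sd = 0.044,
                                n_ntc = 0, seed = 1000 + s)
    calls <- call_genotypes(fl)
    mean(calls$call == c("hom_allele1", "het", "hom_allele2")[
      fl$true_genotype + 1])
  }, numeric(1))
  expect_gte(mean(acc), 0.99)
})

test_that("the association test is Student's t between homozygote classes", {
  calls <- tibble::tibble(
    sample_id = sprintf("s%d", 1:9),
    fam = 0, hex = 0, ratio = 0,
    call = rep(c("hom_allele1", "het", "hom_allele2"), each = 3))
  ph <- tibble::tibble(sample_id = sprintf("s%d", 1:9),
                       spike_length_cm = c(1, 2, 3, 9, 9, 9, 4, 5, 6))
  res <- association_test(calls, ph)
  # closed-form pooled-variance computation for {1,2,3} vs {4,5,6}
  sp2 <- (2 * 1 + 2 * 1) / 4
  t_exp <- (2 - 5) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_exp)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(abs(t_exp), 4, lower.tail = FALSE))
  expect_equal(tidy(res)$estimate, -3)

  # swapping the class labels flips t, not p
  calls_sw <- dplyr::mutate(calls, call = dplyr::recode(
    call, hom_allele1 = "hom_allele2", hom_allele2 = "hom_allele1"))
  res_sw <- association_test(calls_sw, ph)
  expect_equal(res_sw$t, -res$t)
  expect_equal(res_sw$p_value, res$p_value)

  # identical groups: no difference
  ph_eq <- tibble::tibble(sample_id = sprintf("s%d", 1:9),
                          spike_length_cm = c(1, 2, 3, 9, 9, 9, 1, 2, 3))
  res_eq <- association_test(calls, ph_eq)
  expect_equal(res_eq$t, 0)
  expect_equal(res_eq$p_value, 1)

  # degenerate class: skipped with a message
  calls_small <- calls[c(1, 4:9), ]
  expect_message(res_na <- association_test(calls_small, ph),
                 "skipped")
  expect_true(is.na(res_na$p_value))
})

test_that("phenotype summaries report percent change and normality", {
  tab <- tibble::tibble(
    spike_length_cm = c(rnorm(20, 10, 0.001), rnorm(20, 12.9, 0.001)),
    group = rep(c("wt", "mutant"), each = 20))
  s <- phenotype_summary(tab, baseline = "wt")
  expect_equal(s$comparisons$percent_change, 29, tolerance = 0.01)
  same <- phenotype_summary(tibble::tibble(
    spike_length_cm = c(rep(10, 10), rep(10.1, 10)),
    group = rep(c("a", "b"), each = 10)))
  expect_equal(same$comparisons$percent_change[1], 1, tolerance = 1e-6)
  zero <- phenotype_summary(tibble::tibble(
    spike_length_cm = c(9, 10, 11, 9, 10, 11),
    group = rep(c("a", "b"), each = 3)))
  expect_equal(zero$comparisons$percent_change, 0)

  # normal draws pass the normality check in at least 90% of seeds
  pass <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    tab <- tibble::tibble(spike_length_cm = rnorm(200, 9, 0.9),
                          group = "F2")
    phenotype_summary(tab)$groups$shapiro_p > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})
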