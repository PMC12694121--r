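mk_rec <- function(long_ref = 10L, long_alt = 30L, short_ref = 25L,
                   short_alt = 0L) {
  tibble::tibble(chrom = "c1", pos = 1L, ref = "G", alt = "A",
                 variant_class = "SNP",
                 wt_ref = 20L, wt_alt = 0L, mut_ref = 0L, mut_alt = 20L,
                 short_ref = short_ref, short_alt = short_alt,
                 long_ref = long_ref, long_alt = long_alt)
}

test_that("SNP-index is the depth fraction of the designated parent allele", {
  rec <- mk_rec()
  # wt (female) parent carries ref: M = 10, P = 30
  expect_equal(snp_index(rec, "long", "wt"), 0.25)
  expect_equal(snp_index(rec, "long", "mut"), 0.75)
  expect_equal(snp_index(rec, "short", "mut"), 0)
  expect_true(is.na(snp_index(mk_rec(long_ref = 0L, long_alt = 0L), "long")))
})

test_that("SNP-index equals a read-by-read tally on random depths", {
  set.seed(4)
  rec <- random_records(300, seed = 4)
  idx <- snp_index(rec, "long", "wt")
  oracle <- vapply(seq_len(nrow(rec)), function(i) {
    # enumerate the pool's reads and count those carrying each parent allele
    wt_allele <- if (rec$wt_ref[i] >= rec$wt_alt[i]) rec$ref[i] else rec$alt[i]
    mut_allele <- if (rec$mut_ref[i] >= rec$mut_alt[i]) rec$ref[i] else rec$alt[i]
    reads <- c(rep(rec$ref[i], rec$long_ref[i]),
               rep(rec$alt[i], rec$long_alt[i]))
    m <- sum(reads == wt_allele)
    p <- sum(reads == mut_allele)
    if (m + p == 0) NA_real_ else m / (m + p)
  }, numeric(1))
  expect_equal(idx, oracle)
})

test_that("Delta(SNP-index) is the pool difference and flips under pool swap", {
  rec <- mk_rec(long_ref = 0L, long_alt = 40L, short_ref = 40L,
                short_alt = 0L)
  # mutant-parent orientation: long pool all mutant, short all wild-type
  expect_equal(delta_snp_index(rec, "mut"), 1)
  rec_eq <- mk_rec(long_ref = 20L, long_alt = 20L, short_ref = 20L,
                   short_alt = 20L)
  expect_equal(delta_snp_index(rec_eq), 0)
  swapped <- rec
  swapped[, c("long_ref", "long_alt", "short_ref", "short_alt")] <-
    rec[, c("short_ref", "short_alt", "long_ref", "long_alt")]
  expect_equal(delta_snp_index(swapped, "mut"), -delta_snp_index(rec, "mut"))
})

test_that("scan statistics respect their ranges on random records", {
  rec <- random_records(500, seed = 6)
  scan <- quiet_scan(rec)
  expect_true(all(scan$index_aa >= 0 & scan$index_aa <= 1))
  expect_true(all(scan$index_ab >= 0 & scan$index_ab <= 1))
  expect_true(all(scan$delta >= -1 & scan$delta <= 1))
  expect_true(all(scan$ed >= 0 & scan$ed <= sqrt(2) + 1e-12))
  expect_equal(scan$delta, scan$index_aa - scan$index_ab)
})

test_that("offspring-index floor removes doubly uninformative sites", {
  pts <- tibble::tibble(chrom = "c1", pos = 1:4,
                        index_aa = c(0.2, 0.2, 0.5, 0.5),
                        index_ab = c(0.25, 0.9, 0.1, 0.6))
  both <- filter_offspring_index(pts, 0.30, "both")
  expect_equal(both$pos, c(2L, 3L, 4L))
  expect_equal(attr(both, "n_removed"), 1L)
  any_mode <- filter_offspring_index(pts, 0.30, "any")
  expect_equal(any_mode$pos, 4L)

  set.seed(7)
  rnd <- tibble::tibble(chrom = "c1", pos = 1:1000,
                        index_aa = runif(1000), index_ab = runif(1000))
  out <- filter_offspring_index(rnd, 0.30, "both")
  keep <- !(rnd$index_aa < 0.3 & rnd$index_ab < 0.3)
  expect_equal(out$pos, rnd$pos[keep])
})

test_that("Euclidean distance matches its closed-form examples", {
  expect_equal(euclidean_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), sqrt(2))
  expect_equal(euclidean_distance(c(0.3, 0.3, 0.2, 0.2),
                                  c(0.3, 0.3, 0.2, 0.2)), 0)
  expect_equal(euclidean_distance(c(0.75, 0, 0.25, 0),
                                  c(0.25, 0, 0.75, 0)), sqrt(0.5))
  # symmetry and range on random frequency quadruples
  set.seed(10)
  for (i in 1:50) {
    a <- diff(c(0, sort(runif(3)), 1))
    b <- diff(c(0, sort(runif(3)), 1))
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_lte(euclidean_distance(a, b), sqrt(2))
  }
  expect_error(euclidean_distance(c(1, 1, 0, 0), c(1, 0, 0, 0)),
               class = "bsamapr_value_error")
})

test_that("windowed Delta means sit on the fixed grid and match brute force", {
  pts <- tibble::tibble(chrom = "c1",
                        pos = c(2e5, 4e5, 6e5, 9e5, 1.4e6),
                        delta = c(0.9, 1.0, 0.2, 0.2, 0.2))
  w <- smooth_delta(pts, 5e5, 5e5, min_markers = 1)
  expect_equal(w$window_start, c(1, 5e5 + 1, 1e6 + 1))
  expect_equal(w$mean_delta[1], 0.95)

  const <- tibble::tibble(chrom = "c1", pos = seq(1e4, 2e6, by = 1e4),
                          delta = 0.37)
  wc <- smooth_delta(const, 5e5, 5e5, min_markers = 1)
  expect_true(all(wc$mean_delta == 0.37))

  set.seed(12)
  rnd <- tibble::tibble(chrom = "c1", pos = sort(sample.int(3e6, 400)),
                        delta = rnorm(400, 0, 0.2))
  wr <- smooth_delta(rnd, 5e5, 5e5, min_markers = 1)
  for (i in seq_len(nrow(wr))) {
    inside <- rnd$pos >= wr$window_start[i] & rnd$pos <= wr$window_end[i]
    expect_equal(wr$mean_delta[i], mean(rnd$delta[inside]))
    expect_equal(wr$n_markers[i], sum(inside))
  }
})

test_that("ED smoothing is exact tricube local linear regression", {
  # constant input gives a constant fit
  const <- tibble::tibble(chrom = "c1", pos = seq_len(60) * 1e4, ed = 0.2)
  expect_equal(fit_ed(const, span = 0.3)$fitted_ed, rep(0.2, 60))

  # a spike is contracted: fitted peak strictly between background and raw
  spike <- tibble::tibble(chrom = "c1", pos = seq_len(61) * 1e4,
                          ed = c(rep(0.1, 30), 1.0, rep(0.1, 30)))
  f <- fit_ed(spike, span = 0.3)$fitted_ed
  expect_gt(f[31], 0.1)
  expect_lt(f[31], 1.0)
  expect_equal(which.max(f), 31)

  # independent per-point tricube weighted least squares on a 50-point fixture
  set.seed(15)
  n <- 50
  x <- sort(runif(n, 0, 1e6))
  y <- 0.2 + 0.1 * sin(x / 1e5) + rnorm(n, 0, 0.02)
  pts <- tibble::tibble(chrom = "c1", pos = x, ed = y)
  span <- 0.3
  mine <- fit_ed(pts, power = 1, span = span)$fitted_ed
  oracle <- vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    lam <- sort(d)[floor(n * span)]
    w <- pmax(0, 1 - (d / lam)^3)^3
    X <- cbind(1, x - x[i])
    b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    b[1]
  }, numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-10)
})

test_that("the ED threshold is median + k population SD", {
  expect_equal(ed_threshold(c(0, 0, 0, 0, 10), k = 3), 12)
  expect_equal(ed_threshold(rep(0.3, 10), k = 3), 0.3)
  v <- c(0.1, 0.5, 0.2, 0.9)
  expect_equal(ed_threshold(v, k = 0), median(v))
  expect_error(ed_threshold(numeric(0)), class = "bsamapr_value_error")
})

test_that("region calling finds maximal runs, merges gaps, counts markers", {
  pts <- tibble::tibble(chrom = "c1",
                        pos = c(100, 200, 300, 400, 500, 10500,
                                6e5, 6e5 + 100, 6e5 + 200),
                        stat = c(rep(1, 5), 0, 1, 1, 1))
  none <- call_regions(dplyr::mutate(pts, stat = 0), 0.5, "stat")
  expect_equal(nrow(none), 0)

  two <- call_regions(pts, 0.5, "stat", min_markers = 3, max_gap_bp = 1000)
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(100, 6e5))
  expect_equal(two$end, c(500, 6e5 + 200))
  expect_equal(two$n_markers, c(5L, 3L))

  merged <- call_regions(pts, 0.5, "stat", min_markers = 3,
                         max_gap_bp = 1e6)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_markers, 8L)

  # brute-force run-length oracle on random site-level input
  set.seed(20)
  rnd <- tibble::tibble(chrom = "c1", pos = sort(sample.int(1e6, 200)),
                        stat = runif(200))
  got <- call_regions(rnd, 0.7, "stat", min_markers = 1, max_gap_bp = 5e4)
  above <- rnd[rnd$stat > 0.7, ]
  above$grp <- cumsum(c(0, diff(above$pos) - 1 > 5e4))
  expected <- dplyr::summarise(
    dplyr::group_by(above, grp),
    start = min(pos), end = max(pos), n = dplyr::n(), .groups = "drop")
  expect_equal(got$start, expected$start)
  expect_equal(got$end, expected$end)
  expect_equal(got$n_markers, expected$n)
  # regions never overlap and marker counts add up
  expect_true(all(diff(got$start) > 0))
  expect_true(all(got$end[-nrow(got)] < got$start[-1]))
  expect_equal(sum(got$n_markers), nrow(above))
})

test_that("windowed regions use the shared-boundary end convention", {
  w <- tibble::tibble(chrom = "c1",
                      window_start = c(1, 5e5 + 1, 1e6 + 1, 2e6 + 1),
                      window_end = c(5e5, 1e6, 1.5e6, 2.5e6),
                      n_markers = c(10L, 10L, 10L, 10L),
                      stat = c(1, 1, 0, 1))
  reg <- call_regions(w, 0.5, "stat", min_markers = 3, max_gap_bp = 0)
  expect_equal(reg$start, c(1, 2e6 + 1))
  expect_equal(reg$end, c(1e6 + 1, 2.5e6 + 1))
  expect_equal(reg$length_bp[1], 2 * 5e5 + 1)
})

test_that("candidate SNPs need high mutant-pool MAF and high ED", {
  pts <- tibble::tibble(chrom = "c1", pos = c(10, 20, 30, 1000),
                        maf_mut = c(0.8, 0.8, 0.6, 0.9),
                        ed = c(0.6, 0.4, 0.6, 0.9))
  reg <- tibble::tibble(chrom = "c1", start = 1, end = 100)
  sel <- select_candidate_snps(pts, reg)
  expect_equal(sel$pos, 10)
  # main-allele frequency from a depth quadruple: 40 of 50 reads
  rec <- mk_rec(long_ref = 40L, long_alt = 10L)
  expect_equal(quiet_scan(rec)$maf_mut, 0.8)
})
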