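# AVS-shaped helper: locus i of a SNP universe with its correlated set
avs_at <- function(universe, i, locus = paste0("L", i)) {
  structure(list(locus = locus, sentinel = universe$SNP[i],
                 members = universe$members[[i]]),
            class = "avs")
}

test_that("mapping_tally honours BED half-open coordinates exactly", {
  # three hand-placed SNPs at 1-based positions 100, 200, 300
  snps <- list(data.frame(CHR = "1", BP = 100L),
               data.frame(CHR = "1", BP = 200L),
               data.frame(CHR = "1", BP = 300L))
  # [p-1, p) covers the SNP; [p, p+1) does not
  peaks_in <- data.frame(chrom = "1", start = c(99L, 199L, 299L),
                         end = c(100L, 200L, 300L))
  peaks_out <- data.frame(chrom = "1", start = c(100L, 200L, 300L),
                          end = c(101L, 201L, 301L))
  expect_equal(mapping_tally(snps, peaks_in), 3L)
  expect_equal(mapping_tally(snps, peaks_out), 0L)
  # empty peak set -> 0; full coverage -> number of loci
  expect_equal(mapping_tally(snps, peaks_in[0, ]), 0L)
  wide <- data.frame(chrom = "1", start = 0L, end = 1000L)
  expect_equal(mapping_tally(snps, wide), 3L)
  # invariant to peak order and merging of overlapping intervals
  shuffled <- peaks_in[c(3, 1, 2), ]
  expect_equal(mapping_tally(snps, shuffled), 3L)
  merged <- data.frame(chrom = "1", start = c(99L, 199L),
                       end = c(100L, 301L))
  split2 <- data.frame(chrom = "1", start = c(99L, 199L, 250L),
                       end = c(100L, 260L, 301L))
  expect_equal(mapping_tally(snps, merged), mapping_tally(snps, split2))
  # chr-prefix normalization
  peaks_chr <- peaks_in; peaks_chr$chrom <- "chr1"
  expect_equal(mapping_tally(snps, peaks_chr), 3L)
})

test_that("matched-null sampling is seeded, matched, and degenerate-safe", {
  panel <- tiny_panel()
  universe <- build_snp_universe(panel)
  avs_list <- lapply(c(5L, 105L, 205L, 305L), function(i) avs_at(universe, i))
  peaks <- make_peak_fixture(panel, coverage_background = 0.2, seed = 50)
  n1 <- sample_matched_null(avs_list, universe, peaks, n_perm = 200, seed = 1)
  n1b <- sample_matched_null(avs_list, universe, peaks, n_perm = 200, seed = 1)
  n2 <- sample_matched_null(avs_list, universe, peaks, n_perm = 200, seed = 2)
  expect_identical(n1, n1b)
  expect_false(identical(n1, n2))
  expect_true(all(n1 >= 0 & n1 <= length(avs_list)))
  # degenerate universe (only the sentinels themselves, loosened bins):
  # every null tally equals the observed tally
  u1 <- universe[universe$SNP %in% vapply(avs_list, `[[`, "", "sentinel"), ]
  obs <- mapping_tally(avs_list, peaks, panel$variants)
  # within each matched bin only the AVS sentinel itself can be drawn
  nd <- sample_matched_null(avs_list, u1, peaks, n_perm = 50, seed = 3)
  expect_true(all(nd == obs))
})

test_that("vse_test sign conventions, floor, and never-zero p", {
  panel <- tiny_panel()
  universe <- build_snp_universe(panel)
  avs_list <- lapply(seq(5L, 395L, by = 40L), function(i) avs_at(universe, i))
  # planted total enrichment: observed is maximal -> p at the add-one floor
  enr <- unlist(lapply(avs_list, function(a) a$members$SNP))
  peaks <- make_peak_fixture(panel, enriched_set = enr,
                             coverage_background = 0.1, seed = 51)
  v <- vse_test(avs_list, peaks, universe, panel$variants,
                n_perm = 400, seed = 52)
  expect_equal(v$observed, length(avs_list))
  expect_equal(v$p_empirical, 1 / 401, tolerance = 1e-12)
  expect_gt(v$score, 2)
  # score is SDs from the null median by definition
  expect_equal(v$score,
               (v$observed - median(v$null_tallies)) / sd(v$null_tallies),
               tolerance = 1e-12)
  # translation invariance: shifting all coordinates changes nothing
  shift <- 1000L
  panel2 <- panel; panel2$variants$BP <- panel$variants$BP + shift
  u2 <- universe; u2$BP <- universe$BP + shift
  u2$members <- lapply(universe$members, function(d) {
    d$BP <- d$BP + shift; d
  })
  avs2 <- lapply(seq(5L, 395L, by = 40L), function(i) avs_at(u2, i))
  peaks2 <- peaks; peaks2$start <- peaks$start + shift
  peaks2$end <- peaks$end + shift
  v2 <- vse_test(avs2, peaks2, u2, panel2$variants, n_perm = 400, seed = 52)
  expect_equal(v2$observed, v$observed)
  expect_equal(v2$p_empirical, v$p_empirical, tolerance = 1e-12)
  # observed below the null median -> negative score, p > 0.5
  cold <- data.frame(chrom = "1",
                     start = panel$variants$BP[300:400] - 1L,
                     end = panel$variants$BP[300:400])
  avs_cold <- lapply(c(5L, 45L, 85L), function(i) avs_at(universe, i))
  vc <- vse_test(avs_cold, cold, universe, panel$variants,
                 n_perm = 400, seed = 53)
  if (!vc$score_undefined) expect_lte(vc$observed, median(vc$null_tallies))
  expect_gt(vc$p_empirical, 0.5)
  # small n_perm warns; p never zero by the add-one rule
  expect_warning(vse_test(avs_list, peaks, universe, panel$variants,
                          n_perm = 50, seed = 54), "n_perm")
})

test_that("cell_type_specificity scores by kernel-weighted fold-enrichment", {
  snps <- data.frame(CHR = "1", BP = c(1000L, 50000L))
  # SNP inside a peak of fold f scores exactly f
  marks <- list(ct1 = data.frame(chrom = "1", start = 990L, end = 1010L,
                                 fold = 7),
                ct2 = data.frame(chrom = "1", start = 990L, end = 1010L,
                                 fold = 7))
  universe_pos <- data.frame(CHR = "1", BP = seq(100L, 100000L, by = 100L))
  res <- cell_type_specificity(snps, marks, universe_pos, n_perm = 100, seed = 1)
  expect_equal(res$score, c(7, 7))   # second SNP is > 2.5 kb away: scores 0
  # identical peak sets give identical scores and p at fixed seed
  expect_equal(res$p[1], res$p[2])
  # zero-peak cell type: score 0, p 1, warning
  expect_warning(
    res0 <- cell_type_specificity(snps, list(none = data.frame()[0, ]),
                                  universe_pos, n_perm = 50, seed = 2),
    "zero peaks")
  expect_equal(res0$score, 0)
  expect_equal(res0$p, 1)
  # kernel edge: SNP exactly at bandwidth boundary scores 0
  far <- list(ct = data.frame(chrom = "1", start = 1000L, end = 1001L, fold = 3))
  snp_far <- data.frame(CHR = "1", BP = 1001L + 2501L)  # gap = bandwidth
  resf <- cell_type_specificity(snp_far, far, universe_pos, n_perm = 50, seed = 3)
  expect_equal(resf$score, 0)
})
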