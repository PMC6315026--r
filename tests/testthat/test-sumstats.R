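test_that("read_sumstats parses, derives and validates", {
  df <- toy_sumstats()
  ss <- read_sumstats(write_ss_fixture(df))
  expect_equal(nrow(ss), 3)
  expect_equal(ss$Z, df$BETA / df$SE, tolerance = 1e-12)
  expect_equal(ss$Z[1], 2.0)
  expect_equal(ss$P, 2 * pnorm(-abs(ss$Z)), tolerance = 1e-12)
  expect_false(any(ss$is_indel))

  # dialect mapping and missing-column error
  df2 <- df; names(df2)[names(df2) == "SE"] <- "stderr"
  p2 <- write_ss_fixture(df2)
  expect_error(read_sumstats(p2, dialect = c(SE = "SE")),
               "configuration error")
  ss2 <- read_sumstats(p2, dialect = c(SE = "stderr"))
  expect_equal(ss2$SE, df$SE)

  # indels flagged, not dropped
  df3 <- df; df3$A1[2] <- "AT"
  ss3 <- read_sumstats(write_ss_fixture(df3))
  expect_equal(ss3$is_indel, c(FALSE, TRUE, FALSE))

  # unparseable rows reported, not silently dropped
  df4 <- df; df4$BP <- as.character(df4$BP); df4$BP[3] <- "oops"
  expect_message(ss4 <- read_sumstats(write_ss_fixture(df4)), "unparseable")
  expect_equal(nrow(ss4), 2)
  expect_equal(nrow(attr(ss4, "bad_rows")), 1)
})

test_that("harmonize_pair applies all filters with reason precedence", {
  ref <- data.frame(SNP = paste0("rs", 1:8), A1 = "A", A2 = "G",
                    MAF = c(rep(0.3, 7), 0.04), stringsAsFactors = FALSE)
  base <- data.frame(SNP = paste0("rs", 1:8), CHR = "1",
                     BP = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L),
                     A1 = "A", A2 = "G", BETA = 0.1, SE = 0.05, Z = 2,
                     P = 2 * pnorm(-2), N_CAS = 100L, N_CON = 100L,
                     MAF = 0.25, INFO = 0.95, is_indel = FALSE,
                     inconsistent = FALSE, stringsAsFactors = FALSE)
  a <- base
  a$INFO[1] <- 0.85                      # -> info
  a$A1[2] <- "T"; a$A2[2] <- "A"         # -> strand_ambiguous
  a$A1[3] <- "A"; a$A2[3] <- "C"         # -> allele_mismatch
  a$MAF[4] <- 0.005                      # -> maf
  a$CHR[5] <- "6"; a$BP[5] <- 30e6       # -> hla
  b <- base
  b$A1[6] <- "G"; b$A2[6] <- "A"; b$BETA[6] <- -0.1; b$Z[6] <- -2  # swap
  h <- harmonize_pair(a, b, ref)
  tb <- h$report$n_removed_by_reason
  expect_equal(unname(tb[c("info", "strand_ambiguous", "allele_mismatch",
                           "maf", "hla", "reference_maf")]),
               rep(1L, 6), ignore_attr = TRUE)
  expect_setequal(h$report$retained, c("rs6", "rs7"))
  expect_equal(h$report$n_input,
               length(h$report$retained) + sum(tb))

  # swapped record flipped onto the reference allele; |Z| and P unchanged
  i <- match("rs6", h$b$SNP)
  expect_equal(h$b$Z[i], 2)
  expect_equal(h$b$A1[i], "A")
  expect_equal(h$b$P[i], 2 * pnorm(-2))

  # idempotence
  h2 <- harmonize_pair(h$a, h$b, ref)
  expect_equal(h2$a, h$a)
  expect_equal(h2$b, h$b)
  expect_equal(length(h2$report$retained), length(h$report$retained))

  # chi-square multiset invariant to reference allele ordering
  ref_sw <- ref; ref_sw$A1 <- ref$A2; ref_sw$A2 <- ref$A1
  h3 <- harmonize_pair(a, b, ref_sw)
  expect_equal(sort(h3$a$Z^2), sort(h$a$Z^2), tolerance = 1e-12)

  # empty intersection errors
  expect_error(harmonize_pair(a[1, ], b[2, ], ref), "no harmonized SNPs")
})

test_that("hwe_exact_test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-5)
  # spec example: direct enumeration over het in {1,3,...} with 11 minor alleles
  expect_equal(hwe_exact_test(3, 5, 2), hwe_oracle(3, 5, 2), tolerance = 1e-12)
  # property: agreement with the oracle for all tables with total <= 50
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    nAA <- sample(0:n, 1); nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
})

test_that("qc_genotypes filters individuals then SNPs with reasons", {
  set.seed(1)
  n <- 100
  g <- matrix(rbinom(n * 40, 2, 0.3), n, 40,
              dimnames = list(NULL, paste0("snp", 1:40)))
  g[2:7, 1] <- NA                                    # call rate 94% -> removed
  g[, 3] <- rep(c(0L, 2L), length.out = n)           # no hets -> HWE fail
  g[, 4] <- c(rep(1L, 1), rep(0L, n - 1))            # maf 0.5% -> removed
  g[1, 5:39] <- NA                                   # individual 1: low call rate
  rep1 <- qc_genotypes(g)
  expect_equal(attr(rep1, "removed_individuals"), 1L)
  tb <- rep1$n_removed_by_reason
  # with individual 1 gone, snp1 is missing in 6 of 99 -> call rate ~93.9%
  expect_equal(unname(tb[["call_rate"]]), 1)
  expect_equal(unname(tb[["hwe"]]), 1)
  expect_equal(unname(tb[["maf"]]), 1)
  expect_true("snp2" %in% rep1$retained)
  expect_equal(length(rep1$retained) + sum(tb), rep1$n_input)

  # perfect HWE proportions retained
  g2 <- matrix(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), 100, 1,
               dimnames = list(NULL, "s"))
  expect_equal(qc_genotypes(g2)$retained, "s")

  # individual filter first; all-individuals-removed is an explicit error
  g3 <- matrix(NA_integer_, 5, 2)
  expect_error(qc_genotypes(g3), "degenerate")
})

test_that("genomic inflation lambda and lambda_1000", {
  null_med <- qchisq(0.5, 1)
  r <- genomic_inflation(rep(null_med, 1000), 1000, 1000)
  expect_equal(r$lambda_gc, 1.0)
  # definitional fixed point at 1000/1000
  chi <- rep(null_med * 1.10, 1000)
  r2 <- genomic_inflation(chi, 1000, 1000)
  expect_equal(r2$lambda_1000, r2$lambda_gc, tolerance = 1e-12)
  # rescaling formula at 4000/4000
  r3 <- genomic_inflation(chi, 4000, 4000)
  expect_equal(r3$lambda_gc, 1.10, tolerance = 1e-12)
  expect_equal(r3$lambda_1000, 1.025, tolerance = 1e-12)
  # lambda_1000 closer to 1 whenever lambda > 1 and n > 1000/1000
  expect_lt(abs(r3$lambda_1000 - 1), abs(r3$lambda_gc - 1))
  # 90% least-significant convention and small-m warning
  r4 <- genomic_inflation(c(rep(null_med, 89), rep(100, 10)), 1000, 1000)
  expect_equal(r4$lambda_gc, 1.0)
  expect_equal(r4$n_snps_used, 89)
  expect_false(is.null(r4$warning))
})
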