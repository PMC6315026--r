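test_that("compute_ld_scores matches brute-force all-pairs summation", {
  cfg <- sim_config(m_snps = 60, ld_block_size = 6, n_ref = 300, seed = 31)
  panel <- make_ld_panel(cfg)
  # window >= chromosome length == all-pairs brute force, exactly
  sc <- compute_ld_scores(panel, window = 1e9)
  expect_equal(sc$L2, ld_score_oracle(panel$genotypes), tolerance = 1e-12)
  sc_raw <- compute_ld_scores(panel, window = 1e9, adjusted = FALSE)
  expect_equal(sc_raw$L2, ld_score_oracle(panel$genotypes, adjusted = FALSE),
               tolerance = 1e-12)
  # self term only: independent SNP has ell ~ 1 (unadjusted >= 1)
  expect_true(all(sc_raw$L2 >= 1))
  # windowed scores are bounded by all-pairs scores up to noise terms
  scw <- compute_ld_scores(panel, window = 5e4)
  expect_true(all(is.finite(scw$L2)))
  # categories = {all SNPs} reproduces the total
  sca <- compute_ld_scores(panel, window = 1e9,
                           categories = list(all = panel$variants$SNP))
  expect_equal(sca$L2_all, sca$L2, tolerance = 1e-12)
  # round-trip serialization
  pth <- tempfile(fileext = ".l2.tsv")
  write_ld_scores(sca, pth)
  expect_equal(read_ld_scores(pth), sca, tolerance = 1e-12)
  # zero-member category rejected
  expect_error(compute_ld_scores(panel, categories = list(empty = character())),
               "zero SNPs")
})

test_that("3-SNP toy panel LD scores equal hand summation", {
  set.seed(7)
  g <- cbind(rnorm(50), rnorm(50), rnorm(50))
  g[, 2] <- 0.8 * g[, 1] + 0.6 * g[, 2]
  panel <- list(variants = data.frame(SNP = c("a", "b", "c"), CHR = "1",
                                      BP = c(100L, 200L, 300L)),
                genotypes = g)
  sc <- compute_ld_scores(panel, window = 1e6, adjusted = FALSE)
  r2 <- cor(g)^2
  expect_equal(sc$L2, rowSums(r2), tolerance = 1e-12)
})

test_that("block_jackknife reproduces closed forms", {
  # constant statistic -> SE 0
  jk <- block_jackknife(function(i) 1.5, n = 100, n_blocks = 10)
  expect_equal(jk$se, 0)
  # two equal halves on the mean: SE = |difference of half-means| / 2
  x <- c(rnorm(50, 0), rnorm(50, 1))
  jk2 <- block_jackknife(function(i) mean(x[i]), n = 100, n_blocks = 2)
  halves <- c(mean(x[1:50]), mean(x[51:100]))
  expect_equal(jk2$se, abs(diff(halves)) / 2 * sqrt(1), tolerance = 1e-12)
  # iid mean with many blocks ~ analytic sigma/sqrt(n)
  set.seed(8)
  covered <- replicate(50, {
    y <- rnorm(2000, sd = 2)
    jk3 <- block_jackknife(function(i) mean(y[i]), n = 2000, n_blocks = 200)
    jk3$se
  })
  expect_equal(mean(covered), 2 / sqrt(2000), tolerance = 0.2 * 2 / sqrt(2000))
  # non-finite statistic names the offending block
  expect_error(block_jackknife(function(i) if (!(3 %in% i)) NaN else 1,
                               n = 10, n_blocks = 5), "block")
})

# shared simulation context for the regression fits
ldsc_ctx <- local({
  ctx <- NULL
  function() {
    if (is.null(ctx)) {
      cfg <- sim_config(m_snps = 4000, ld_block_size = 40,
                        n1_cases = 10000, n1_controls = 10000,
                        n2_cases = 5000, n2_controls = 5000,
                        h2_1 = 0.25, h2_2 = 0.25, rg = 0.5,
                        n_ref = 400, seed = 33)
      panel <- make_ld_panel(cfg)
      scores <- compute_ld_scores(panel)
      sim <- simulate_bivariate_sumstats(panel, seed = 34)
      h <- harmonize_pair(sim$ss1, sim$ss2, panel$variants, hla_region = NULL)
      ctx <<- list(cfg = cfg, panel = panel, scores = scores, sim = sim, h = h)
    }
    ctx
  }
})

test_that("fit_univariate: null behaviour, linearity, recovery", {
  ctx <- ldsc_ctx()
  ss <- ctx$h$a
  # all chi2 = 1 -> slope ~ 0, intercept ~ 1, h2 ~ 0
  ss0 <- ss; ss0$Z <- rep(1, nrow(ss))
  f0 <- fit_univariate(ss0, ctx$scores, m_snps = 4000, n_blocks = 50)
  expect_equal(f0$slope, 0, tolerance = 1e-10)
  expect_equal(f0$intercept, 1, tolerance = 1e-10)
  expect_equal(f0$h2_obs, 0, tolerance = 1e-10)
  # doubling chi2 doubles slope and intercept (weights recomputed but the
  # doubled fit is exactly 2x when we compare the linear fit on fixed weights)
  f1 <- fit_univariate(ss, ctx$scores, m_snps = 4000, n_blocks = 50)
  ssd <- ss; ssd$Z <- ss$Z * sqrt(2)
  i <- match(ssd$SNP, ctx$scores$SNP)
  keep <- f1$keep
  w <- f1$weights
  co <- crosstraitr:::wls(ctx$scores$L2[i][keep], 2 * ss$Z[keep]^2, w)
  expect_equal(co[["slope"]], 2 * f1$slope, tolerance = 1e-10)
  expect_equal(co[["intercept"]], 2 * f1$intercept, tolerance = 1e-10)
  # recovery within 2 jackknife SEs in this single replicate
  expect_lt(abs(f1$h2_obs - 0.25), 2.5 * f1$se_h2)
  # WLS with intercept preserves the weighted mean of fitted values
  ell <- ctx$scores$L2[i][keep]
  fitted <- f1$intercept + f1$slope * ell
  expect_equal(sum(w * fitted) / sum(w),
               sum(w * ss$Z[keep]^2) / sum(w), tolerance = 1e-10)
  # errors
  expect_error(fit_univariate(ss[1:40, ], ctx$scores, m_snps = 4000,
                              n_blocks = 50), "fewer SNPs than")
})

test_that("fit_cross_trait: self-correlation, recovery, sign flip", {
  ctx <- ldsc_ctx()
  h <- ctx$h
  # trait with itself -> rg ~ 1
  fs <- fit_cross_trait(h$a, h$a, ctx$scores, m_snps = 4000, n_blocks = 50)
  expect_equal(fs$rg, 1, tolerance = 0.05)
  # recovery of planted rg within ~2 jackknife SEs
  fx <- fit_cross_trait(h$a, h$b, ctx$scores, m_snps = 4000, n_blocks = 50)
  expect_lt(abs(fx$rg - 0.5), 2.5 * fx$se_rg)
  # global sign flip of trait-2 effects: rg -> -rg exactly
  b2 <- h$b; b2$Z <- -b2$Z; b2$BETA <- -b2$BETA
  ff <- fit_cross_trait(h$a, b2, ctx$scores, m_snps = 4000, n_blocks = 50)
  expect_equal(ff$rg, -fx$rg, tolerance = 1e-12)
  expect_equal(ff$se_rg, fx$se_rg, tolerance = 1e-12)
  # allele-relabelled trait 2 (swap + negate) is detected and un-flipped
  b3 <- h$b
  b3$A1 <- h$b$A2; b3$A2 <- h$b$A1; b3$Z <- -h$b$Z; b3$BETA <- -h$b$BETA
  fr <- fit_cross_trait(h$a, b3, ctx$scores, m_snps = 4000, n_blocks = 50)
  expect_equal(fr$rg, fx$rg, tolerance = 1e-12)
  # degenerate heritability -> flagged, not NaN
  a0 <- h$a; set.seed(1); a0$Z <- rnorm(nrow(a0)) * 0.1   # h2 << 0
  f0 <- fit_cross_trait(a0, h$b, ctx$scores, m_snps = 4000, n_blocks = 50)
  expect_true(is.na(f0$rg))
  expect_match(f0$flag, "non-positive")
})

test_that("fit_partitioned recovers planted category enrichment", {
  cfg <- sim_config(m_snps = 3000, ld_block_size = 30,
                    n1_cases = 25000, n1_controls = 25000,
                    h2_1 = 0.4, h2_2 = 0, rg = 0, n_ref = 400, seed = 35)
  panel <- make_ld_panel(cfg)
  m <- cfg$m_snps
  # planted: 10% of SNPs (whole LD blocks, as real annotations cluster)
  # carry 5x the per-SNP heritability
  set.seed(36)
  sp_blocks <- sort(sample.int(nrow(panel$blocks), nrow(panel$blocks) / 10))
  special <- unlist(lapply(sp_blocks, function(b)
    panel$blocks$start[b]:panel$blocks$end[b]))
  per_snp <- rep(cfg$h2_1 / (0.1 * 5 * m + 0.9 * m), m)
  per_snp[special] <- per_snp[special] * 5
  cats <- list(special = panel$variants$SNP[special],
               rest = panel$variants$SNP[-special])
  scores <- compute_ld_scores(panel, categories = cats)
  n1 <- cfg$n1_cases + cfg$n1_controls
  enr <- replicate(8, {
    beta <- rnorm(m, sd = sqrt(per_snp))
    zero <- numeric(m)
    chl <- lapply(seq_len(nrow(panel$blocks)), function(b) {
      k <- panel$blocks$end[b] - panel$blocks$start[b] + 1L
      chol(crosstraitr:::ar1_cor(k, panel$block_decay[b]))
    })
    zz <- crosstraitr:::sim_z_blocks(panel$blocks, chl, beta, zero, n1, n1, 0)
    ss <- data.frame(SNP = panel$variants$SNP, Z = zz$z1,
                     N_CAS = cfg$n1_cases, N_CON = cfg$n1_controls)
    fit <- fit_partitioned(ss, scores, m_snps = m, categories = cats,
                           n_blocks = 50)
    fit$enrichment[fit$category == "special"]
  })
  expect_lt(abs(mean(enr) - 5), 2 * sd(enr) / sqrt(length(enr)) + 0.5)

  # single all-SNPs category -> enrichment exactly 1
  ss1 <- data.frame(SNP = panel$variants$SNP, Z = rnorm(m),
                    N_CAS = 100L, N_CON = 100L)
  sall <- compute_ld_scores(panel, categories = list(all = panel$variants$SNP))
  f1 <- fit_partitioned(ss1, sall, m_snps = m,
                        categories = list(all = panel$variants$SNP),
                        n_blocks = 50)
  expect_equal(f1$enrichment, 1, tolerance = 1e-12)
  # zero-SNP category rejected
  expect_error(fit_partitioned(ss1, sall, m_snps = m,
                               categories = list(none = character()),
                               n_blocks = 50), "zero SNPs")
})
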