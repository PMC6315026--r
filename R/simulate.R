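# Synthetic-data generators: LD-structured reference panels, bivariate GWAS
# summary statistics with known h2 / genetic correlation, cis-eQTL loci,
# chromatin-peak fixtures, and the packaged risk-locus table.
#
# Z-scores are simulated directly at the summary level, block by block, from
# the moment structure cross-trait LD-score regression assumes:
#   z_k | beta ~ MVN( sqrt(N_k) R beta_k , R )   within each LD block,
# with cross-trait noise correlation n_overlap / sqrt(N1 N2) modelling shared
# samples. This is exact for the estimand and orders of magnitude faster than
# individual-level simulation.

#' Simulation configuration
#'
#' Defaults mirror the motivating study design: two case-control B-cell
#' malignancy GWAS (trait 1 "MM": 7717 cases / 21,587 controls; trait 2
#' "CLL": 4017 cases / 7881 controls), observed-scale SNP heritabilities
#' 0.092 and 0.22, genetic correlation 0.44, no sample overlap.
#'
#' @param m_snps number of SNPs.
#' @param n1_cases,n1_controls,n2_cases,n2_controls per-trait sample sizes.
#' @param h2_1,h2_2 observed-scale heritabilities in `[0, 1]`.
#' @param rg genetic correlation in `[-1, 1]`.
#' @param n_overlap number of shared individuals (>= 0).
#' @param ld_block_size SNPs per independent LD block.
#' @param ld_decay within-block AR(1) correlation parameter in `[0, 1)`.
#'   A length-2 vector gives a range from which each block draws its own
#'   decay (the default): heterogeneous LD across blocks is what real
#'   genomes look like and what gives LD-score regression its spread in
#'   the regressor. A scalar gives every block the same decay.
#' @param n_ref reference-panel individuals.
#' @param bp_spacing base pairs between adjacent SNPs.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 10000,
                       n1_cases = 7717, n1_controls = 21587,
                       n2_cases = 4017, n2_controls = 7881,
                       h2_1 = 0.092, h2_2 = 0.22, rg = 0.44,
                       n_overlap = 0,
                       ld_block_size = 50, ld_decay = c(0.3, 0.95),
                       n_ref = 1000, bp_spacing = 10000L, seed = 1L) {
  stopifnot(h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1,
            rg >= -1, rg <= 1, ld_block_size >= 1,
            all(ld_decay >= 0), all(ld_decay < 1),
            length(ld_decay) %in% 1:2,
            n_overlap >= 0, m_snps >= 1)
  cfg <- list(m_snps = as.integer(m_snps),
              n1_cases = n1_cases, n1_controls = n1_controls,
              n2_cases = n2_cases, n2_controls = n2_controls,
              h2_1 = h2_1, h2_2 = h2_2, rg = rg, n_overlap = n_overlap,
              ld_block_size = as.integer(ld_block_size), ld_decay = ld_decay,
              n_ref = as.integer(n_ref), bp_spacing = as.integer(bp_spacing),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

block_bounds <- function(m, bs) {
  starts <- seq(1L, m, by = bs)
  data.frame(start = starts, end = pmin(starts + bs - 1L, m))
}

ar1_cor <- function(k, rho) {
  if (k == 1) return(matrix(1, 1, 1))
  rho ^ abs(outer(seq_len(k), seq_len(k), "-"))
}

#' Generate an LD-structured reference panel
#'
#' SNPs are laid out in independent blocks; within a block the target
#' correlation between SNPs `i` and `j` is `ld_decay^|i-j|` (AR(1)).
#' Dosages are Gaussian-scaled with mean `2*MAF` and variance
#' `2*MAF*(1-MAF)`; they are deliberately not clipped to `[0, 2]`, so the
#' realized LD matches the target without attenuation (see the methods
#' vignette). MAFs are uniform on `[0.05, 0.5]`. Non-ambiguous allele pairs
#' are assigned per SNP, with a small fraction of strand-ambiguous (A/T, C/G)
#' pairs so harmonization filters have work to do.
#'
#' @param config a [sim_config()].
#' @return list of class `ld_panel` with `variants` (data.frame: SNP, CHR,
#'   BP, A1, A2, MAF), `genotypes` (n_ref x m matrix), `blocks`
#'   (data.frame of index intervals) and `config`.
#' @export
make_ld_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m_snps; bs <- config$ld_block_size; n <- config$n_ref
  if (m %% bs != 0)
    warning("m_snps not a multiple of ld_block_size; last block truncated")
  blocks <- block_bounds(m, bs)
  block_decay <- if (length(config$ld_decay) == 2)
    runif(nrow(blocks), config$ld_decay[1], config$ld_decay[2])
  else rep(config$ld_decay, nrow(blocks))
  maf <- runif(m, 0.05, 0.5)

  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"),
                 c("A", "T"), c("C", "G"))          # last two ambiguous
  pick <- sample.int(10, m, replace = TRUE,
                     prob = c(rep(0.115, 8), 0.04, 0.04))
  variants <- data.frame(SNP = paste0("rs", seq_len(m)),
                         CHR = "1",
                         BP = as.integer(seq_len(m)) * config$bp_spacing,
                         A1 = pairs[pick, 1], A2 = pairs[pick, 2],
                         MAF = maf, stringsAsFactors = FALSE)

  geno <- matrix(NA_real_, n, m)
  for (b in seq_len(nrow(blocks))) {
    idx <- blocks$start[b]:blocks$end[b]
    L <- chol(ar1_cor(length(idx), block_decay[b]))
    z <- matrix(rnorm(n * length(idx)), n) %*% L
    geno[, idx] <- sweep(sweep(z, 2, sqrt(2 * maf[idx] * (1 - maf[idx])), "*"),
                         2, 2 * maf[idx], "+")
  }
  colnames(geno) <- variants$SNP
  out <- list(variants = variants, genotypes = geno, blocks = blocks,
              block_decay = block_decay, config = config)
  class(out) <- "ld_panel"
  out
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("LD panel:", nrow(x$variants), "SNPs,", nrow(x$genotypes),
      "individuals,", nrow(x$blocks), "blocks\n")
  invisible(x)
}

# draw per-block z-scores for two traits given causal effects
sim_z_blocks <- function(blocks, R_chol_list, beta1, beta2, n1, n2, r_overlap) {
  m <- length(beta1)
  z1 <- numeric(m); z2 <- numeric(m)
  for (b in seq_len(nrow(blocks))) {
    idx <- blocks$start[b]:blocks$end[b]
    L <- R_chol_list[[b]]                       # upper-triangular chol
    mu1 <- sqrt(n1) * drop(crossprod(L, L %*% beta1[idx]))
    mu2 <- sqrt(n2) * drop(crossprod(L, L %*% beta2[idx]))
    u1 <- rnorm(length(idx)); u2 <- rnorm(length(idx))
    e1 <- drop(crossprod(L, u1))
    e2 <- drop(crossprod(L, r_overlap * u1 + sqrt(1 - r_overlap^2) * u2))
    z1[idx] <- mu1 + e1
    z2[idx] <- mu2 + e2
  }
  list(z1 = z1, z2 = z2)
}

#' Simulate bivariate GWAS summary statistics with known truth
#'
#' Per-SNP causal effects are drawn from a bivariate normal with variances
#' `h2_k / M` and cross-covariance `rg * sqrt(h2_1 h2_2) / M`; marginal
#' Z-scores are drawn per LD block from
#' `MVN(sqrt(N_k) R beta_k, R)` where `R` is the block's generating LD
#' matrix; sample overlap adds cross-trait noise correlation
#' `n_overlap / sqrt(N1 N2)`. Output records carry the panel MAF and an
#' imputation INFO drawn uniform on `[0.85, 1]`, and ~20% of records have
#' their allele pair swapped (with sign flip) relative to the panel, so
#' harmonization is exercised.
#'
#' @param panel an [make_ld_panel()] panel.
#' @param config a [sim_config()]; `NULL` uses `panel$config`.
#' @param seed optional seed overriding `config$seed` (use when drawing
#'   replicates from one panel).
#' @return list with `ss1`, `ss2` (canonical summary-stat data.frames) and
#'   `truth` (h2s, rg, rho_g, expected intercepts, causal effects).
#' @export
simulate_bivariate_sumstats <- function(panel, config = NULL, seed = NULL) {
  stopifnot(inherits(panel, "ld_panel"))
  cfg <- if (is.null(config)) panel$config else config
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  m <- nrow(panel$variants)
  n1 <- cfg$n1_cases + cfg$n1_controls
  n2 <- cfg$n2_cases + cfg$n2_controls
  r_overlap <- cfg$n_overlap / sqrt(n1 * n2)
  stopifnot(r_overlap <= 1)

  # bivariate causal effects (standardized-genotype scale)
  cov_b <- cfg$rg * sqrt(cfg$h2_1 * cfg$h2_2) / m
  s1 <- sqrt(cfg$h2_1 / m); s2 <- sqrt(cfg$h2_2 / m)
  u <- rnorm(m); v <- rnorm(m)
  beta1 <- s1 * u
  rho_b <- if (s1 > 0 && s2 > 0) cov_b / (s1 * s2) else 0
  beta2 <- s2 * (rho_b * u + sqrt(max(0, 1 - rho_b^2)) * v)

  chl <- lapply(seq_len(nrow(panel$blocks)), function(b) {
    k <- panel$blocks$end[b] - panel$blocks$start[b] + 1L
    chol(ar1_cor(k, panel$block_decay[b]))
  })
  zz <- sim_z_blocks(panel$blocks, chl, beta1, beta2, n1, n2, r_overlap)

  mk_ss <- function(z, n_cas, n_con) {
    n <- n_cas + n_con
    v <- panel$variants
    swap <- runif(m) < 0.2
    a1 <- ifelse(swap, v$A2, v$A1); a2 <- ifelse(swap, v$A1, v$A2)
    zs <- ifelse(swap, -z, z)
    data.frame(SNP = v$SNP, CHR = v$CHR, BP = v$BP, A1 = a1, A2 = a2,
               BETA = zs / sqrt(n), SE = 1 / sqrt(n), Z = zs,
               P = 2 * pnorm(-abs(zs)),
               N_CAS = n_cas, N_CON = n_con, MAF = v$MAF,
               INFO = runif(m, 0.85, 1), is_indel = FALSE,
               inconsistent = FALSE, stringsAsFactors = FALSE)
  }
  truth <- list(h2_1 = cfg$h2_1, h2_2 = cfg$h2_2, rg = cfg$rg,
                rho_g = cfg$rg * sqrt(cfg$h2_1 * cfg$h2_2),
                expected_intercept_cross = r_overlap,
                beta1 = beta1, beta2 = beta2)
  list(ss1 = mk_ss(zz$z1, cfg$n1_cases, cfg$n1_controls),
       ss2 = mk_ss(zz$z2, cfg$n2_cases, cfg$n2_controls),
       truth = truth)
}

#' Simulate a cis-eQTL locus under pleiotropy, linkage or the null
#'
#' Uses the first block (or `block`) of the panel as the cis region. Under
#' `"pleiotropy"` a single causal SNP drives both expression and trait with
#' trait effect `b_xy * b_zx`; under `"linkage"` two distinct correlated
#' causal SNPs act, one on expression and one on the trait; under `"null"`
#' only the expression signal exists. Effect estimates are the truth plus
#' LD-correlated noise at the stated sample sizes.
#'
#' @param panel an `ld_panel`.
#' @param scenario one of `"pleiotropy"`, `"linkage"`, `"null"`.
#' @param b_zx causal-SNP effect on expression (standardized scale).
#' @param b_xy effect of expression on trait (pleiotropy scenario).
#' @param b_zy2 trait effect of the second causal SNP (linkage scenario).
#' @param n_eqtl,n_gwas sample sizes of the eQTL and GWAS studies.
#' @param block which LD block to use as the cis region.
#' @param causal_offset,linkage_gap indices (within block) of the causal
#'   SNP(s); the gap sets the LD between the two linkage-scenario causals.
#' @param decay AR(1) LD decay of the cis region (default 0.9, a dense
#'   cis-eQTL block; overrides the panel block's own decay so the scenario
#'   is reproducible whatever the panel looks like).
#' @param seed seed.
#' @return list with `eqtl` (probe, SNP, b_zx, se_zx, p_zx), `gwas`
#'   (canonical columns), `ld` (cis LD matrix), `truth`.
#' @export
simulate_eqtl_locus <- function(panel, scenario = c("pleiotropy", "linkage", "null"),
                                b_zx = 0.3, b_xy = 0.2, b_zy2 = 0.06,
                                n_eqtl = 5000, n_gwas = 50000,
                                block = 1L, causal_offset = 10L,
                                linkage_gap = 3L, decay = 0.9, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(panel, "ld_panel"), block <= nrow(panel$blocks))
  set.seed(seed)
  idx <- panel$blocks$start[block]:panel$blocks$end[block]
  k <- length(idx)
  v <- panel$variants[idx, ]
  if (any(v$MAF <= 0)) stop("monomorphic SNP in cis region")
  R <- ar1_cor(k, decay)
  L <- chol(R)
  c1 <- min(causal_offset, k)
  c2 <- min(c1 + linkage_gap, k)

  bzx_true <- R[, c1] * b_zx
  bzy_true <- switch(scenario,
    pleiotropy = R[, c1] * b_zx * b_xy,
    linkage    = R[, c2] * b_zy2,
    null       = numeric(k))

  noise <- function(n) drop(crossprod(L, rnorm(k))) / sqrt(n)
  bzx_hat <- bzx_true + noise(n_eqtl)
  bzy_hat <- bzy_true + noise(n_gwas)
  se_zx <- rep(1 / sqrt(n_eqtl), k)
  se_zy <- rep(1 / sqrt(n_gwas), k)

  eqtl <- data.frame(probe = "probe1", gene = "GENE1", SNP = v$SNP,
                     b_zx = bzx_hat, se_zx = se_zx,
                     p_zx = 2 * pnorm(-abs(bzx_hat / se_zx)),
                     stringsAsFactors = FALSE)
  gwas <- data.frame(SNP = v$SNP, CHR = v$CHR, BP = v$BP, A1 = v$A1, A2 = v$A2,
                     BETA = bzy_hat, SE = se_zy, Z = bzy_hat / se_zy,
                     P = 2 * pnorm(-abs(bzy_hat / se_zy)),
                     N_CAS = NA_integer_, N_CON = NA_integer_,
                     MAF = v$MAF, INFO = 1, stringsAsFactors = FALSE)
  rownames(R) <- colnames(R) <- v$SNP
  list(eqtl = eqtl, gwas = gwas, ld = R,
       truth = list(scenario = scenario, causal_snp = v$SNP[c1],
                    causal_snp2 = if (scenario == "linkage") v$SNP[c2] else NA,
                    b_xy = if (scenario == "pleiotropy") b_xy else 0,
                    r2_causals = if (scenario == "linkage") R[c1, c2]^2 else NA))
}

#' Build a chromatin-peak fixture around panel SNPs
#'
#' Emits 0-based half-open intervals covering every SNP in `enriched_set`
#' plus a random `coverage_background` fraction of the remaining SNP
#' positions. Each peak is `[pos - 1, pos)` in BED coordinates, i.e. exactly
#' the SNP base, unless `halfwidth > 0`.
#'
#' @param panel an `ld_panel`.
#' @param enriched_set character vector of SNP ids to cover (may be empty).
#' @param coverage_background fraction of non-enriched SNPs to cover.
#' @param seed seed.
#' @param halfwidth extra bases either side of the SNP.
#' @param path optional path; when given the BED is written there.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
make_peak_fixture <- function(panel, enriched_set = character(),
                              coverage_background = 0.1, seed = 1L,
                              halfwidth = 0L, path = NULL) {
  stopifnot(coverage_background >= 0, coverage_background < 1)
  set.seed(seed)
  v <- panel$variants
  enr <- v$SNP %in% enriched_set
  bg_pool <- which(!enr)
  n_bg <- round(coverage_background * length(bg_pool))
  bg <- if (n_bg > 0) sample(bg_pool, n_bg) else integer()
  sel <- sort(unique(c(which(enr), bg)))
  bed <- data.frame(chrom = v$CHR[sel],
                    start = v$BP[sel] - 1L - halfwidth,
                    end = v$BP[sel] + halfwidth,
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  bed
}

#' Packaged risk-locus table (pleiotropy-scan worked example)
#'
#' Returns the packaged transcription of the published risk-locus table for
#' the two B-cell malignancies: 10 loci, each with a sentinel variant and
#' (where reported) one correlated variant, per-trait p-values, risk alleles
#' and odds ratios. Cells printed as "-" (variant absent from a trait's
#' filtered dataset) come back as `NA`; the as-printed p-value strings are
#' kept alongside the parsed numbers.
#'
#' @return data.frame with one row per (locus, variant) and columns `locus`,
#'   `discovery`, `role`, `snp_id`, `pos_hg19`, `risk_allele_cll`,
#'   `risk_allele_mm`, `or_cll`, `or_mm`, `p_cll`, `p_mm`, `p_cll_str`,
#'   `p_mm_str`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_risk_loci.tsv", package = "crosstraitr",
                      mustWork = TRUE)
  tb <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  tb$pos_hg19 <- as.integer(tb$pos_hg19)
  for (col in c("risk_allele_cll", "risk_allele_mm"))
    tb[[col]][tb[[col]] == "-"] <- NA
  tb$p_cll_str <- tb$p_cll; tb$p_mm_str <- tb$p_mm
  for (col in c("or_cll", "or_mm", "p_cll", "p_mm")) {
    tb[[col]][tb[[col]] == "-"] <- NA
    tb[[col]] <- as.numeric(tb[[col]])
  }
  tb
}
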