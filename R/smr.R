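# Summary-data-based Mendelian randomization (SMR) and the HEIDI
# heterogeneity test distinguishing pleiotropy from linkage.
#
# With z the instrument SNP, x gene expression and y the trait:
#   b_xy = b_zy / b_zx
#   T_SMR = z_zx^2 z_zy^2 / (z_zx^2 + z_zy^2) ~ chi2(1) under b_xy = 0.
# Under pleiotropy (one shared causal variant) b_xy is identical for every
# SNP in LD with it; HEIDI tests heterogeneity of the per-SNP b_xy.

#' SMR test at a single instrument SNP
#'
#' @param b_zx,se_zx eQTL effect and SE of the SNP on expression.
#' @param b_zy,se_zy GWAS effect and SE of the same SNP on the trait
#'   (aligned to the same effect allele — alignment is the caller's job).
#' @return list of class `smr_result`: `b_xy`, `se_xy`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(b_zx, se_zx, b_zy, se_zy) {
  stopifnot(se_zx > 0, se_zy > 0)
  if (b_zx == 0) stop("b_zx = 0: undefined Wald ratio")
  z_zx <- b_zx / se_zx
  z_zy <- b_zy / se_zy
  t_smr <- (z_zx^2 * z_zy^2) / (z_zx^2 + z_zy^2)
  b_xy <- b_zy / b_zx
  out <- list(b_xy = b_xy,
              se_xy = if (t_smr > 0) abs(b_xy) / sqrt(t_smr) else NA_real_,
              t_smr = t_smr,
              p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE))
  class(out) <- "smr_result"
  out
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("SMR: b_xy = %.4f (SE %s), T = %.3f, P = %.3g\n",
              x$b_xy, ifelse(is.na(x$se_xy), "NA", sprintf("%.4f", x$se_xy)),
              x$t_smr, x$p_smr))
  invisible(x)
}

# delta-method covariance of d_i = b_xy(i) - b_xy(top), treating the eQTL and
# GWAS estimates as LD-correlated within study, independent between studies
heidi_cov <- function(bzx, sezx, bzy, sezy, R, top) {
  k <- length(bzx)
  others <- setdiff(seq_len(k), top)
  m <- length(others)
  # gradient of d wrt (b_zy_1..k, b_zx_1..k)
  G <- matrix(0, m, 2 * k)
  for (r in seq_len(m)) {
    i <- others[r]
    G[r, i] <- 1 / bzx[i]
    G[r, top] <- -1 / bzx[top]
    G[r, k + i] <- -bzy[i] / bzx[i]^2
    G[r, k + top] <- bzy[top] / bzx[top]^2
  }
  S <- matrix(0, 2 * k, 2 * k)
  S[1:k, 1:k] <- R * tcrossprod(sezy)
  S[(k + 1):(2 * k), (k + 1):(2 * k)] <- R * tcrossprod(sezx)
  G %*% S %*% t(G)
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Selects cis SNPs that are reasonable instruments (eQTL p below
#' `p_instrument`) and in moderate LD with the top SNP
#' (`r2` in `[r2_min, r2_max]`), caps them at the `max_snps` strongest, and
#' tests whether their Wald ratios `b_xy(i)` differ from the top SNP's. The
#' statistic is the sum of squared standardized differences; its null
#' distribution (correlated chi-squares) is evaluated by seeded Monte Carlo
#' from the delta-method multivariate normal of the differences.
#'
#' @param cis_eqtl data.frame with `SNP`, `b_zx`, `se_zx`, `p_zx`.
#' @param cis_gwas data.frame with `SNP`, `BETA`, `SE` on the same alleles.
#' @param ld correlation (not r2) matrix among the cis SNPs, dimnames = SNP ids.
#' @param top_snp id of the instrument SNP.
#' @param p_instrument relaxed instrument threshold (default 1.57e-3).
#' @param r2_min,r2_max LD window with the top SNP (defaults 0.05, 0.90).
#' @param max_snps cap on tested SNPs (default 20 strongest instruments).
#' @param n_draws Monte-Carlo draws (default 50,000).
#' @param seed seed for the draws.
#' @return list: `p_heidi` (NA with `reason` when < 3 eligible SNPs),
#'   `n_used`, `statistic`.
#' @export
heidi_test <- function(cis_eqtl, cis_gwas, ld, top_snp,
                       p_instrument = 1.57e-3, r2_min = 0.05, r2_max = 0.90,
                       max_snps = 20, n_draws = 50000, seed = 1L) {
  stopifnot(top_snp %in% cis_eqtl$SNP, top_snp %in% colnames(ld))
  gi <- match(cis_eqtl$SNP, cis_gwas$SNP)
  keep <- !is.na(gi)
  eq <- cis_eqtl[keep, ]; gw <- cis_gwas[gi[keep], ]
  li <- match(eq$SNP, colnames(ld))
  stopifnot(!anyNA(li))
  R <- ld[li, li, drop = FALSE]
  top <- match(top_snp, eq$SNP)

  r2_top <- R[, top]^2
  elig <- which(eq$p_zx < p_instrument & r2_top >= r2_min & r2_top <= r2_max &
                  seq_along(r2_top) != top)
  if (length(elig) < 3)
    return(list(p_heidi = NA_real_, n_used = length(elig),
                reason = "fewer than 3 eligible SNPs"))
  if (length(elig) > max_snps)
    elig <- elig[order(eq$p_zx[elig], eq$SNP[elig])][seq_len(max_snps)]
  # canonical (id-sorted) order so the result is invariant to input row order
  sel <- c(top, elig[order(eq$SNP[elig])])
  eq <- eq[sel, ]; gw <- gw[sel, ]; R <- R[sel, sel]
  top2 <- 1L

  b_xy <- gw$BETA / eq$b_zx
  d <- b_xy[-top2] - b_xy[top2]
  V <- heidi_cov(eq$b_zx, eq$se_zx, gw$BETA, gw$SE, R, top2)
  sdv <- sqrt(diag(V))
  stat <- sum((d / sdv)^2)

  # Monte-Carlo null: d* ~ MVN(0, V), same standardization
  set.seed(seed)
  ev <- eigen(V, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% (t(ev$vectors) * sqrt(lam))   # V^(1/2)
  Zm <- matrix(rnorm(n_draws * length(d)), n_draws)
  Dm <- Zm %*% t(A)
  stat0 <- rowSums(sweep(Dm, 2, sdv, "/")^2)
  p <- (1 + sum(stat0 >= stat)) / (1 + n_draws)
  list(p_heidi = p, n_used = length(d), statistic = stat)
}

#' SMR scan over an eQTL catalog
#'
#' Per probe, picks the top cis-eQTL (smallest `p_zx`, required to pass the
#' instrument threshold), runs the SMR test against the GWAS, and advances
#' probes with `p_smr < alpha / n_probes_tested` to HEIDI when LD is
#' available. Probes without an instrument-grade SNP are skipped and counted.
#'
#' @param eqtl_catalog data.frame with `probe`, `SNP`, `b_zx`, `se_zx`, `p_zx`.
#' @param gwas canonical summary-stats data.frame.
#' @param ld optional named list: per-probe LD correlation matrix for HEIDI.
#' @param n_probes_tested number of probes behind the Bonferroni correction.
#' @param alpha family-wise level (default 0.05).
#' @param p_instrument_top instrument threshold for the top SNP (default 5e-8).
#' @param heidi_alpha heterogeneity call level (default 0.05).
#' @param seed seed passed to HEIDI.
#' @param ... further arguments to [heidi_test()].
#' @return data.frame, one row per tested probe: `probe`, `top_snp`, `b_xy`,
#'   `se_xy`, `t_smr`, `p_smr`, `passes_smr`, `p_heidi`, `n_heidi_snps`,
#'   `heterogeneity`; attribute `n_skipped` counts instrument-less probes.
#' @export
run_smr_scan <- function(eqtl_catalog, gwas, ld = NULL, n_probes_tested,
                         alpha = 0.05, p_instrument_top = 5e-8,
                         heidi_alpha = 0.05, seed = 1L, ...) {
  stopifnot(n_probes_tested >= 1)
  thr <- alpha / n_probes_tested
  probes <- unique(eqtl_catalog$probe)
  skipped <- 0L
  rows <- list()
  for (pb in probes) {
    eq <- eqtl_catalog[eqtl_catalog$probe == pb, ]
    eq <- eq[eq$SNP %in% gwas$SNP, ]
    eq_ok <- eq[eq$p_zx < p_instrument_top, ]
    if (!nrow(eq_ok)) { skipped <- skipped + 1L; next }
    top <- eq_ok[which.min(eq_ok$p_zx), ]
    gw <- gwas[match(top$SNP, gwas$SNP), ]
    sm <- smr_test(top$b_zx, top$se_zx, gw$BETA, gw$SE)
    passes <- sm$p_smr < thr
    p_h <- NA_real_; n_h <- NA_integer_
    if (passes && !is.null(ld) && !is.null(ld[[pb]])) {
      h <- heidi_test(eq, gwas, ld[[pb]], top$SNP, seed = seed, ...)
      p_h <- h$p_heidi; n_h <- h$n_used
    }
    rows[[length(rows) + 1]] <- data.frame(
      probe = pb, top_snp = top$SNP, b_xy = sm$b_xy, se_xy = sm$se_xy,
      t_smr = sm$t_smr, p_smr = sm$p_smr, passes_smr = passes,
      p_heidi = p_h, n_heidi_snps = n_h,
      heterogeneity = !is.na(p_h) & p_h < heidi_alpha,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe = character(), top_snp = character(), b_xy = numeric(),
               se_xy = numeric(), t_smr = numeric(), p_smr = numeric(),
               passes_smr = logical(), p_heidi = numeric(),
               n_heidi_snps = integer(), heterogeneity = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}
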