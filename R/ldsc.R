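# LD-score computation and univariate / cross-trait / stratified LD-score
# regression with block-jackknife standard errors.
#
# Model (per SNP j, M SNPs, sample size N):
#   E[chi2_j]      = 1 + N h2 l_j / M                        (univariate)
#   E[z1_j z2_j]   = intercept + sqrt(N1 N2) rho_g l_j / M   (cross-trait)
# where l_j is the LD score. The cross-trait intercept absorbs sample
# overlap, so rg = rho_g / sqrt(h2_1 h2_2) is unbiased by shared controls.

#' Compute LD scores from a reference panel
#'
#' `l_j = sum_k r2(j, k)` over SNPs `k` whose position lies within `window`
#' base pairs of SNP `j` (self included). With `adjusted = TRUE` the
#' finite-sample-unbiased estimator `r2_adj = r2 - (1 - r2)/(n - 2)` is used
#' (the self term stays 1). Optional categories give per-category partial
#' scores restricting the sum to category members.
#'
#' @param panel an `ld_panel` (or any list with `variants` and `genotypes`).
#' @param window window in base pairs (default 1 Mb).
#' @param categories optional named list of SNP-id character vectors.
#' @param adjusted use the finite-sample adjustment (default TRUE).
#' @return data.frame with `SNP`, `CHR`, `BP`, `L2`, then one `L2_<name>`
#'   column per category.
#' @export
compute_ld_scores <- function(panel, window = 1e6, categories = NULL,
                              adjusted = TRUE) {
  v <- panel$variants
  g <- panel$genotypes
  m <- nrow(v); n <- nrow(g)
  if (window < v$BP[2] - v$BP[1] && m > 1) stop("window smaller than 1 SNP spacing")
  gs <- scale(g)                     # center+scale once; r = crossprod/ (n-1)
  cat_mat <- NULL
  if (!is.null(categories)) {
    for (nmc in names(categories))
      if (!length(categories[[nmc]])) stop("category with zero SNPs: ", nmc)
    cat_mat <- vapply(categories, function(ids) v$SNP %in% ids,
                      logical(m))  # m x C
  }
  ell <- numeric(m)
  ell_cat <- if (!is.null(cat_mat)) matrix(0, m, ncol(cat_mat)) else NULL

  chunk <- 512L
  pos <- v$BP
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    lo <- findInterval(pos[s] - window, pos) + 1L
    hi <- findInterval(pos[e] + window, pos)
    nb <- lo:hi
    r <- crossprod(gs[, s:e, drop = FALSE], gs[, nb, drop = FALSE]) / (n - 1)
    r2 <- r * r
    if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
    # zero out pairs outside the per-SNP bp window; restore exact self term
    dmat <- abs(outer(pos[s:e], pos[nb], "-")) > window
    r2[dmat] <- 0
    self <- cbind(seq_len(e - s + 1L), match(s:e, nb))
    r2[self] <- 1
    ell[s:e] <- rowSums(r2)
    if (!is.null(cat_mat))
      ell_cat[s:e, ] <- r2 %*% cat_mat[nb, , drop = FALSE]
  }
  out <- data.frame(SNP = v$SNP, CHR = v$CHR, BP = v$BP, L2 = ell,
                    stringsAsFactors = FALSE)
  if (!is.null(cat_mat)) {
    ec <- as.data.frame(ell_cat)
    names(ec) <- paste0("L2_", names(categories))
    out <- cbind(out, ec)
  }
  out
}

#' Write / read LD scores (round-trip tab-separated)
#' @param scores data.frame from [compute_ld_scores()].
#' @param path file path.
#' @export
write_ld_scores <- function(scores, path) {
  data.table::fwrite(scores, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_ld_scores
#' @export
read_ld_scores <- function(path) {
  data.table::fread(path, data.table = FALSE, colClasses = list(character = "CHR"))
}

#' Delete-one-block jackknife
#'
#' Splits the (genome-ordered) items `1..n` into `n_blocks` contiguous blocks
#' and recomputes `statistic` leaving each block out. The jackknife SE is
#' `sqrt((B-1)/B * sum((theta_b - mean)^2))`.
#'
#' @param statistic function taking an integer index vector (items kept) and
#'   returning a numeric scalar or vector.
#' @param n number of items.
#' @param n_blocks number of blocks (>= 2).
#' @return list with `estimate` (full sample), `se`, and the
#'   `leave_one_out` matrix (B x length(estimate)).
#' @export
block_jackknife <- function(statistic, n, n_blocks = 200) {
  stopifnot(n_blocks >= 2, n >= n_blocks)
  bounds <- floor(seq(0, n, length.out = n_blocks + 1))
  full <- statistic(seq_len(n))
  loo <- matrix(NA_real_, n_blocks, length(full))
  for (b in seq_len(n_blocks)) {
    keep <- c(seq_len(bounds[b]), seq.int(bounds[b + 1] + 1L, length.out = n - bounds[b + 1]))
    val <- statistic(keep)
    if (any(!is.finite(val)))
      stop("statistic non-finite when leaving out block ", b)
    loo[b, ] <- val
  }
  mns <- colMeans(loo)
  se <- sqrt((n_blocks - 1) / n_blocks *
               colSums(sweep(loo, 2, mns, "-")^2))
  list(estimate = full, se = se, leave_one_out = loo)
}

# weighted least squares of y on (1, x): returns c(intercept, slope)
wls <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x * x); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  c(intercept = (swy - slope * swx) / sw, slope = slope)
}

# standard LDSC regression weights: 1 / (heteroskedasticity * overcounting)
ldsc_weights <- function(ell, expected) {
  1 / (pmax(ell, 1) * pmax(expected, 0.1)^2)
}

prep_regression <- function(ss, scores, chi2_max) {
  i <- match(ss$SNP, scores$SNP)
  if (any(is.na(i))) stop("missing LD score for ", sum(is.na(i)), " SNP(s)")
  ell <- scores$L2[i]
  chi2 <- ss$Z^2
  ok <- is.finite(chi2) & chi2 <= chi2_max
  n_dropped <- sum(!ok)
  if (n_dropped) message(n_dropped, " SNP(s) dropped (non-finite or chi2 > ",
                         signif(chi2_max, 3), ")")
  list(ell = ell[ok], z = ss$Z[ok], chi2 = chi2[ok], keep = which(ok))
}

#' Univariate LD-score regression (SNP heritability)
#'
#' Two-pass weighted regression of per-SNP chi-square on LD score with free
#' intercept; `h2 = slope * M / N`. SEs by delete-one-block jackknife with
#' the weights held fixed at their full-sample values.
#'
#' @param ss harmonized summary statistics (needs `SNP`, `Z`, `N_CAS`,
#'   `N_CON`; per-SNP `N` column honored if present).
#' @param scores LD scores from [compute_ld_scores()].
#' @param m_snps total SNPs M assumed to contribute heritability.
#' @param n_blocks jackknife blocks.
#' @param chi2_max outlier cap; default `max(80, 0.001 * N)`.
#' @return object of class `ldsc_fit` with `h2_obs`, `se_h2`, `slope`,
#'   `intercept`, `se_intercept`, `n_snps`, `n_blocks`, `n_eff`.
#' @export
fit_univariate <- function(ss, scores, m_snps, n_blocks = 200, chi2_max = NULL) {
  n_eff <- if ("N" %in% names(ss)) mean(ss$N) else
    mean(ss$N_CAS + ss$N_CON)
  if (is.null(chi2_max)) chi2_max <- max(80, 0.001 * n_eff)
  pr <- prep_regression(ss, scores, chi2_max)
  if (length(pr$ell) < n_blocks) stop("fewer SNPs than jackknife blocks")
  stopifnot(m_snps >= length(pr$ell))

  co0 <- wls(pr$ell, pr$chi2, rep(1, length(pr$ell)))
  h2_prov <- min(max(co0[["slope"]] * m_snps / n_eff, 0), 1)
  w <- ldsc_weights(pr$ell, 1 + n_eff * h2_prov * pr$ell / m_snps)

  stat <- function(idx) {
    co <- wls(pr$ell[idx], pr$chi2[idx], w[idx])
    c(h2 = co[["slope"]] * m_snps / n_eff, intercept = co[["intercept"]],
      slope = co[["slope"]])
  }
  jk <- block_jackknife(stat, length(pr$ell), n_blocks)
  out <- list(h2_obs = jk$estimate[["h2"]], se_h2 = jk$se[1],
              intercept = jk$estimate[["intercept"]], se_intercept = jk$se[2],
              slope = jk$estimate[["slope"]],
              n_snps = length(pr$ell), n_blocks = n_blocks, n_eff = n_eff,
              m_snps = m_snps, weights = w, keep = pr$keep)
  class(out) <- "ldsc_fit"
  out
}

#' Cross-trait LD-score regression (genetic covariance and correlation)
#'
#' Regresses `z1_j * z2_j` on the LD score with free intercept;
#' `rho_g = slope * M / sqrt(N1 N2)` and `rg = rho_g / sqrt(h2_1 h2_2)`.
#' The SE of `rg` comes from a block jackknife of the full ratio: each
#' leave-one-block-out sample re-estimates both heritabilities and the
#' genetic covariance. The intercept absorbs sample overlap. Allele
#' concordance between the two tables is re-checked and `z2` flipped where
#' the effect alleles are swapped (defence in depth after harmonization).
#'
#' @param ss1,ss2 harmonized records over an identical SNP set.
#' @param scores LD scores.
#' @param m_snps total SNP count M.
#' @param n_blocks jackknife blocks.
#' @param chi2_max outlier cap applied to both traits' chi-square.
#' @return `ldsc_fit` with `rho_g`, `rg`, `se_rg`, `p_rg`, `intercept`
#'   (cross-trait), `se_intercept`, `h2_1`, `h2_2`, per-trait fits attached.
#' @export
fit_cross_trait <- function(ss1, ss2, scores, m_snps, n_blocks = 200,
                            chi2_max = NULL) {
  if (!identical(ss1$SNP, ss2$SNP)) {
    i <- match(ss1$SNP, ss2$SNP)
    if (any(is.na(i))) stop("SNP sets differ between traits")
    ss2 <- ss2[i, , drop = FALSE]
  }
  flip <- ss1$A1 == ss2$A2 & ss1$A2 == ss2$A1
  mism <- !flip & !(ss1$A1 == ss2$A1 & ss1$A2 == ss2$A2)
  if (any(mism)) stop(sum(mism), " SNP(s) with non-matching allele pairs")
  if (any(flip)) ss2$Z[flip] <- -ss2$Z[flip]

  n1 <- if ("N" %in% names(ss1)) mean(ss1$N) else mean(ss1$N_CAS + ss1$N_CON)
  n2 <- if ("N" %in% names(ss2)) mean(ss2$N) else mean(ss2$N_CAS + ss2$N_CON)
  if (is.null(chi2_max)) chi2_max <- max(80, 0.001 * max(n1, n2))

  i <- match(ss1$SNP, scores$SNP)
  if (any(is.na(i))) stop("missing LD score for ", sum(is.na(i)), " SNP(s)")
  ell <- scores$L2[i]
  ok <- is.finite(ss1$Z) & is.finite(ss2$Z) &
    ss1$Z^2 <= chi2_max & ss2$Z^2 <= chi2_max
  ell <- ell[ok]; z1 <- ss1$Z[ok]; z2 <- ss2$Z[ok]
  mm <- length(ell)
  if (mm < n_blocks) stop("fewer SNPs than jackknife blocks")

  # provisional (unweighted) passes for the weights
  co1 <- wls(ell, z1^2, rep(1, mm)); co2 <- wls(ell, z2^2, rep(1, mm))
  cox <- wls(ell, z1 * z2, rep(1, mm))
  h1p <- min(max(co1[["slope"]] * m_snps / n1, 0), 1)
  h2p <- min(max(co2[["slope"]] * m_snps / n2, 0), 1)
  e1 <- 1 + n1 * h1p * ell / m_snps
  e2 <- 1 + n2 * h2p * ell / m_snps
  ex <- cox[["intercept"]] + cox[["slope"]] * ell
  w1 <- ldsc_weights(ell, e1)
  w2 <- ldsc_weights(ell, e2)
  wx <- 1 / (pmax(ell, 1) * (e1 * e2 + ex^2))

  chi1 <- z1^2; chi2v <- z2^2; prod12 <- z1 * z2
  base_stat <- function(idx, floor1 = 0, floor2 = 0) {
    c1 <- wls(ell[idx], chi1[idx], w1[idx])
    c2 <- wls(ell[idx], chi2v[idx], w2[idx])
    cx <- wls(ell[idx], prod12[idx], wx[idx])
    h2_1 <- c1[["slope"]] * m_snps / n1
    h2_2 <- c2[["slope"]] * m_snps / n2
    rho <- cx[["slope"]] * m_snps / sqrt(n1 * n2)
    d1 <- max(h2_1, floor1); d2 <- max(h2_2, floor2)
    rg <- if (d1 > 0 && d2 > 0) rho / sqrt(d1 * d2) else NA_real_
    c(rg = rg, rho_g = rho, intercept = cx[["intercept"]],
      h2_1 = h2_1, h2_2 = h2_2)
  }
  full <- base_stat(seq_len(mm))
  # leave-out pseudovalues floor the denominator h2 at a quarter of the
  # full-sample estimate so a pathological block cannot send rg to +/-Inf
  stat <- function(idx) base_stat(idx,
                                  floor1 = max(full[["h2_1"]] * 0.25, 1e-6),
                                  floor2 = max(full[["h2_2"]] * 0.25, 1e-6))
  if (!is.finite(full[["rg"]])) {
    out <- list(rg = NA_real_, rho_g = full[["rho_g"]],
                intercept = full[["intercept"]],
                h2_1 = full[["h2_1"]], h2_2 = full[["h2_2"]],
                flag = "rg undefined: non-positive heritability estimate",
                n_snps = mm, n_blocks = n_blocks)
    class(out) <- "ldsc_fit"
    return(out)
  }
  jk <- block_jackknife(stat, mm, n_blocks)
  rg <- jk$estimate[["rg"]]; se_rg <- jk$se[1]
  out <- list(rg = rg, se_rg = se_rg,
              p_rg = 2 * pnorm(-abs(rg / se_rg)),
              rho_g = jk$estimate[["rho_g"]], se_rho_g = jk$se[2],
              intercept = jk$estimate[["intercept"]], se_intercept = jk$se[3],
              h2_1 = jk$estimate[["h2_1"]], se_h2_1 = jk$se[4],
              h2_2 = jk$estimate[["h2_2"]], se_h2_2 = jk$se[5],
              slope = jk$estimate[["rho_g"]] * sqrt(n1 * n2) / m_snps,
              n_snps = mm, n_blocks = n_blocks, n1 = n1, n2 = n2,
              m_snps = m_snps, leave_one_out = jk$leave_one_out)
  class(out) <- "ldsc_fit"
  out
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("LD-score regression fit\n")
  if (!is.null(x$h2_obs))
    cat(sprintf("  h2 (observed) = %.4f (SE %.4f), intercept = %.4f (SE %.4f)\n",
                x$h2_obs, x$se_h2, x$intercept, x$se_intercept))
  if (!is.null(x$rg)) {
    if (is.na(x$rg)) cat("  rg undefined:", x$flag, "\n")
    else cat(sprintf("  rg = %.4f (SE %.4f), P = %.3g; rho_g = %.5f; intercept = %.4f\n",
                     x$rg, x$se_rg, x$p_rg, x$rho_g, x$intercept))
  }
  cat("  SNPs:", x$n_snps, " jackknife blocks:", x$n_blocks, "\n")
  invisible(x)
}

#' Flat key-value report for a fit
#' @param fit an `ldsc_fit`.
#' @return data.frame with `key`, `value`.
#' @export
ldsc_report <- function(fit) {
  keep <- vapply(fit, function(v) is.numeric(v) && length(v) == 1, logical(1))
  data.frame(key = names(fit)[keep],
             value = unlist(fit[keep], use.names = FALSE))
}

#' Stratified (partitioned-heritability) LD-score regression
#'
#' Joint weighted regression of chi-square on all per-category LD scores.
#' Per-category heritability share is the category's summed contribution to
#' the fitted per-SNP heritability; enrichment is (share of h2)/(share of
#' SNPs). Categories may overlap; each must be nonempty and the union must
#' cover all regression SNPs. Categories whose name ends in `".flank"` are
#' fitted but excluded from the enrichment report.
#'
#' @param ss harmonized records.
#' @param scores LD scores with per-category columns.
#' @param m_snps total SNP count.
#' @param categories named list of SNP-id vectors matching the score columns.
#' @param n_blocks jackknife blocks.
#' @param ridge ridge penalty used only on collinearity fallback.
#' @return data.frame: category, n_snps, prop_snps, prop_h2, enrichment,
#'   se_enrichment.
#' @export
fit_partitioned <- function(ss, scores, m_snps, categories, n_blocks = 200,
                            ridge = 1e-6) {
  for (nmc in names(categories))
    if (!length(categories[[nmc]])) stop("category with zero SNPs: ", nmc)
  cols <- paste0("L2_", names(categories))
  if (!all(cols %in% names(scores)))
    stop("scores lack per-category columns: ",
         paste(setdiff(cols, names(scores)), collapse = ", "))
  i <- match(ss$SNP, scores$SNP)
  if (any(is.na(i))) stop("missing LD score for some SNPs")
  X <- as.matrix(scores[i, cols, drop = FALSE])
  memb <- vapply(categories, function(ids) ss$SNP %in% ids,
                 logical(nrow(ss)))
  if (any(rowSums(memb) == 0)) stop("categories do not cover all regression SNPs")
  n_eff <- if ("N" %in% names(ss)) mean(ss$N) else mean(ss$N_CAS + ss$N_CON)
  chi2 <- ss$Z^2
  ell_tot <- rowSums(X[, !grepl("\\.flank$", names(categories)), drop = FALSE])
  co0 <- wls(rowSums(X), chi2, rep(1, length(chi2)))
  h2p <- min(max(co0[["slope"]] * m_snps / n_eff, 0), 1)
  w <- ldsc_weights(rowSums(X), 1 + n_eff * h2p * rowSums(X) / m_snps)

  fit_tau <- function(idx) {
    Xi <- cbind(1, X[idx, , drop = FALSE])
    wi <- w[idx]
    XtWX <- crossprod(Xi * wi, Xi)
    XtWy <- crossprod(Xi * wi, chi2[idx])
    co <- tryCatch(solve(XtWX, XtWy), error = function(e) {
      warning("collinear category scores; ridge fallback")
      solve(XtWX + diag(ridge * diag(XtWX)), XtWy)
    })
    drop(co)[-1]                     # per-category coefficients tau_c
  }
  stat <- function(idx) {
    tau <- fit_tau(idx)
    per_snp <- drop(memb %*% tau)    # per-SNP expected h2 contribution (x N/M)
    h2_c <- vapply(seq_along(tau), function(c)
      sum(per_snp[memb[, c]]), numeric(1))
    tot <- sum(per_snp)
    prop_h2 <- h2_c / tot
    prop_snp <- colSums(memb) / nrow(memb)
    prop_h2 / prop_snp
  }
  jk <- block_jackknife(stat, nrow(ss), n_blocks)
  res <- data.frame(category = names(categories),
                    n_snps = colSums(memb),
                    prop_snps = colSums(memb) / nrow(memb),
                    enrichment = jk$estimate,
                    se_enrichment = jk$se,
                    stringsAsFactors = FALSE)
  res$prop_h2 <- res$enrichment * res$prop_snps
  res <- res[!grepl("\\.flank$", res$category),
             c("category", "n_snps", "prop_snps", "prop_h2",
               "enrichment", "se_enrichment")]
  rownames(res) <- NULL
  res
}
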