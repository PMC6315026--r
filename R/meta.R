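# Fixed-effects inverse-variance meta-analysis with heterogeneity
# diagnostics (Cochran's Q, I^2).

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-study effect estimates on the log-odds scale with weights
#' `w_i = 1/se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`,
#' `Q = sum(w (b - beta)^2)` on `k - 1` df, and
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param beta per-study effects (log odds ratios), or a 2-column
#'   matrix/data.frame of `(beta, se)` when `se` is missing.
#' @param se per-study standard errors (> 0).
#' @param study optional study labels for error messages.
#' @return list of class `meta_result`: `beta_meta`, `se_meta`, `z_meta`,
#'   `p_meta`, `q_stat`, `q_df`, `q_p`, `i2`, `k`.
#' @export
ivw_meta <- function(beta, se = NULL, study = NULL) {
  if (is.null(se)) {
    stopifnot(ncol(beta) >= 2)
    se <- beta[[2]]; beta <- beta[[1]]
  }
  k <- length(beta)
  stopifnot(k >= 1, length(se) == k)
  if (is.null(study)) study <- paste0("study", seq_len(k))
  if (any(se <= 0 | !is.finite(se)))
    stop("non-positive SE in: ", paste(study[se <= 0 | !is.finite(se)], collapse = ", "))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - b)^2)
  df <- k - 1L
  i2 <- if (q > 1e-12) max(0, (q - df) / q) * 100 else 0   # snap numeric noise
  out <- list(beta_meta = b, se_meta = s, z_meta = b / s,
              p_meta = 2 * pnorm(-abs(b / s)),
              q_stat = q, q_df = df,
              q_p = if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_,
              i2 = i2, k = k)
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("IVW meta-analysis of %d studies: beta = %.4f (SE %.4f), P = %.3g\n",
              x$k, x$beta_meta, x$se_meta, x$p_meta))
  cat(sprintf("  heterogeneity: Q = %.3f on %d df (P = %.3g), I2 = %.1f%%\n",
              x$q_stat, x$q_df, ifelse(is.na(x$q_p), NaN, x$q_p), x$i2))
  invisible(x)
}

#' Per-SNP meta-analysis of stacked study tables
#'
#' Accepts a long-format table with one row per (study, SNP) and combines
#' each SNP across studies by [ivw_meta()]. Odds ratios are accepted via
#' `or_col` and converted to the log scale on input.
#'
#' @param stacked data.frame with columns `SNP`, `BETA`, `SE` (and
#'   optionally a study column).
#' @param or_col optional column name holding odds ratios instead of `BETA`.
#' @return data.frame with one row per SNP: `SNP`, `BETA`, `SE`, `Z`, `P`,
#'   `Q`, `Q_P`, `I2`, `K`.
#' @export
meta_by_snp <- function(stacked, or_col = NULL) {
  if (!is.null(or_col)) stacked$BETA <- log(stacked[[or_col]])
  stopifnot(all(c("SNP", "BETA", "SE") %in% names(stacked)))
  sp <- split(stacked, stacked$SNP)
  rows <- lapply(sp, function(d) {
    m <- ivw_meta(d$BETA, d$SE)
    data.frame(SNP = d$SNP[1], BETA = m$beta_meta, SE = m$se_meta,
               Z = m$z_meta, P = m$p_meta, Q = m$q_stat, Q_P = m$q_p,
               I2 = m$i2, K = m$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
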