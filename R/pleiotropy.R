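# Correlated-variant sets (AVS) around known risk loci, and the region-wide
# Bonferroni cross-trait scan over them.

#' Pairwise LD between two genotype/dosage vectors
#'
#' `r2` is composite LD: the squared Pearson correlation of dosages.
#' `dprime` is computed from EM-estimated haplotype frequencies, which
#' requires discrete genotypes; continuous dosages are rounded to 0/1/2
#' (clamped) first.
#'
#' @param g1,g2 dosage vectors.
#' @param max_iter,tol EM controls.
#' @return list with `r2`, `dprime`, `d` (raw D), haplotype frequency `p11`.
#' @export
ld_pair <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  r <- suppressWarnings(cor(g1, g2, use = "complete.obs"))
  if (is.na(r)) r <- 0
  x <- pmin(pmax(round(g1), 0), 2)
  y <- pmin(pmax(round(g2), 0), 2)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pA <- mean(x) / 2; pB <- mean(y) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1 || n == 0)
    return(list(r2 = r^2, dprime = 0, d = 0, p11 = pA * pB))
  # EM over the double-heterozygote phase ambiguity
  n_dh <- sum(x == 1 & y == 1)
  # known "11" haplotype counts from unambiguous genotype combinations
  known11 <- 2 * sum(x == 2 & y == 2) + sum(x == 2 & y == 1) +
    sum(x == 1 & y == 2)
  p11 <- pA * pB
  for (it in seq_len(max_iter)) {
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    num <- p11 * p00
    den <- p11 * p00 + p10 * p01
    frac <- if (den > 0) num / den else 0.5
    p11_new <- (known11 + frac * n_dh) / (2 * n)
    if (abs(p11_new - p11) < tol) { p11 <- p11_new; break }
    p11 <- p11_new
  }
  d <- p11 - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(r2 = r^2, dprime = if (dmax > 0) abs(d) / dmax else 0, d = d, p11 = p11)
}

#' Build an associated variant set (AVS) around a sentinel SNP
#'
#' Members are panel SNPs within `window` base pairs of the sentinel whose
#' `r2` with the sentinel exceeds `r2_threshold` (and whose D' exceeds
#' `dprime_threshold` when given). The sentinel always belongs to its set.
#'
#' @param sentinel SNP id present in the panel.
#' @param panel an `ld_panel`.
#' @param r2_threshold r-squared cutoff (default 0.8).
#' @param dprime_threshold optional D' cutoff (e.g. 0.8); `NULL` skips D'.
#' @param window half-window in base pairs around the sentinel (default 500 kb).
#' @param locus optional locus label.
#' @return list of class `avs`: `locus`, `sentinel`, `members` (data.frame
#'   with `SNP`, `BP`, `r2`, `dprime`).
#' @export
build_avs <- function(sentinel, panel, r2_threshold = 0.8,
                      dprime_threshold = NULL, window = 5e5, locus = sentinel) {
  j <- match(sentinel, panel$variants$SNP)
  if (is.na(j)) stop("sentinel absent from panel: ", sentinel)
  v <- panel$variants
  cand <- which(v$CHR == v$CHR[j] & abs(v$BP - v$BP[j]) <= window)
  g0 <- panel$genotypes[, j]
  keep <- list()
  for (k in cand) {
    if (k == j) { keep[[length(keep) + 1]] <- data.frame(
      SNP = v$SNP[k], BP = v$BP[k], r2 = 1, dprime = 1); next }
    ld <- ld_pair(g0, panel$genotypes[, k])
    if (ld$r2 > r2_threshold &&
        (is.null(dprime_threshold) || ld$dprime > dprime_threshold))
      keep[[length(keep) + 1]] <- data.frame(SNP = v$SNP[k], BP = v$BP[k],
                                             r2 = ld$r2, dprime = ld$dprime)
  }
  members <- do.call(rbind, keep)
  rownames(members) <- NULL
  out <- list(locus = locus, sentinel = sentinel, members = members)
  class(out) <- "avs"
  out
}

#' @export
print.avs <- function(x, ...) {
  cat(sprintf("AVS %s: sentinel %s, %d member SNP(s)\n",
              x$locus, x$sentinel, nrow(x$members)))
  invisible(x)
}

#' Build AVS-shaped locus sets from the packaged risk-locus table
#'
#' Each locus becomes a set containing its sentinel and, where present, its
#' correlated variant; per-trait p-value lookups are extracted from the
#' printed values.
#'
#' @param fixture data.frame from [table1_fixture()].
#' @return list with `loci` (data.frame: locus, discovery, sentinel),
#'   `members` (data.frame: locus, snp_id), `p_cll`, `p_mm` (named vectors).
#' @export
avs_from_table1 <- function(fixture = table1_fixture()) {
  sent <- fixture[fixture$role == "sentinel", ]
  loci <- data.frame(locus = sent$locus, discovery = sent$discovery,
                     sentinel = sent$snp_id, stringsAsFactors = FALSE)
  members <- fixture[, c("locus", "snp_id")]
  names(members)[2] <- "snp_id"
  p_cll <- setNames(fixture$p_cll, fixture$snp_id)
  p_mm <- setNames(fixture$p_mm, fixture$snp_id)
  list(loci = loci, members = members,
       p_cll = p_cll[!is.na(p_cll)], p_mm = p_mm[!is.na(p_mm)])
}

#' Region-wide Bonferroni scan of risk loci in the other trait
#'
#' For each locus of the discovery trait, takes the minimum other-trait
#' p-value over the sentinel and its correlated variants and compares it with
#' `alpha / n_discovery_loci`. Members absent from the lookup are skipped
#' (counted); loci with no resolvable member are flagged untestable.
#'
#' @param loci data.frame with `locus`, `discovery`, `sentinel` columns (as
#'   from [avs_from_table1()]), or a list of `avs` objects plus a
#'   `discovery` vector.
#' @param members data.frame with `locus`, `snp_id`.
#' @param p_other named numeric vector: other-trait p-value per SNP id.
#' @param n_discovery_loci total discovery-trait loci behind the Bonferroni
#'   correction (e.g. 45 or 23) — not merely the loci scanned here.
#' @param alpha family-wise level (default 0.05).
#' @param p_own optional named vector of own-trait p-values, used to set the
#'   `genome_wide_both` flag (member p < `gw_threshold` in both traits).
#' @param gw_threshold genome-wide significance level (default 5e-8).
#' @return data.frame, one row per locus: `locus`, `discovery`,
#'   `best_snp`, `best_p_other`, `threshold`, `passes`, `untestable`,
#'   `n_members`, `n_unresolved`, `genome_wide_both`.
#' @export
region_wide_scan <- function(loci, members, p_other, n_discovery_loci,
                             alpha = 0.05, p_own = NULL, gw_threshold = 5e-8) {
  stopifnot(n_discovery_loci >= 1, alpha > 0)
  threshold <- alpha / n_discovery_loci
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    lc <- loci$locus[i]
    mem <- members$snp_id[members$locus == lc]
    po <- p_other[mem]
    resolved <- !is.na(po)
    untestable <- !any(resolved)
    best_i <- if (untestable) NA_integer_ else which.min(po)
    gw_both <- FALSE
    if (!is.null(p_own)) {
      pw <- p_own[mem]
      gw_both <- any(!is.na(po) & !is.na(pw) &
                       po < gw_threshold & pw < gw_threshold)
    }
    data.frame(locus = lc, discovery = loci$discovery[i],
               best_snp = if (untestable) NA_character_ else mem[best_i],
               best_p_other = if (untestable) NA_real_ else unname(po[best_i]),
               threshold = threshold,
               passes = !untestable && po[best_i] < threshold,
               untestable = untestable,
               n_members = length(mem),
               n_unresolved = sum(!resolved),
               genome_wide_both = gw_both,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine directional scans into the pleiotropic-locus summary
#'
#' The pleiotropic set is the union of loci passing either directional scan
#' and loci whose correlated-variant set reaches genome-wide significance
#' (`p < gw_threshold`) in both traits, deduplicated by locus name.
#'
#' @param results_ab,results_ba scan results from [region_wide_scan()] for
#'   the two directions.
#' @param members data.frame `locus`, `snp_id` covering all loci.
#' @param p_a,p_b named per-SNP p-value vectors for the two traits.
#' @param gw_threshold genome-wide level (default 5e-8).
#' @return list of class `pleiotropy_summary`: `loci` (data.frame with
#'   `locus`, `how`), `n_pass_ab`, `n_pass_ba`, `n_gw_both`, `n_total`.
#' @export
classify_pleiotropic <- function(results_ab, results_ba, members, p_a, p_b,
                                 gw_threshold = 5e-8) {
  both <- rbind(results_ab, results_ba)
  dup <- both[duplicated(both$locus), ]
  for (lc in unique(dup$locus)) {
    labs <- unique(both$discovery[both$locus == lc])
    if (length(labs) > 1)
      stop("duplicate locus with conflicting discovery labels: ", lc)
  }
  pass_ab <- results_ab$locus[results_ab$passes]
  pass_ba <- results_ba$locus[results_ba$passes]
  all_loci <- unique(members$locus)
  gw_both <- vapply(all_loci, function(lc) {
    mem <- members$snp_id[members$locus == lc]
    pa <- p_a[mem]; pb <- p_b[mem]
    any(!is.na(pa) & !is.na(pb) & pa < gw_threshold & pb < gw_threshold)
  }, logical(1))
  gw_loci <- all_loci[gw_both]
  union_loci <- unique(c(pass_ab, pass_ba, gw_loci))
  how <- vapply(union_loci, function(lc) {
    paste(c(if (lc %in% pass_ab) "scan_ab",
            if (lc %in% pass_ba) "scan_ba",
            if (lc %in% gw_loci) "genome_wide_both"), collapse = "+")
  }, character(1))
  out <- list(loci = data.frame(locus = union_loci, how = how,
                                stringsAsFactors = FALSE),
              n_pass_ab = length(pass_ab), n_pass_ba = length(pass_ba),
              n_gw_both = length(gw_loci),
              n_total = length(union_loci))
  class(out) <- "pleiotropy_summary"
  out
}

#' @export
print.pleiotropy_summary <- function(x, ...) {
  cat(sprintf("Pleiotropic loci: %d (direction A->B: %d, B->A: %d, genome-wide both: %d)\n",
              x$n_total, x$n_pass_ab, x$n_pass_ba, x$n_gw_both))
  print(x$loci)
  invisible(x)
}

#' Run the packaged worked example: both directional scans on the risk-locus
#' table and the combined pleiotropy classification
#'
#' CLL-discovery loci are tested in MM at `0.05/n_cll_loci` and MM-discovery
#' loci in CLL at `0.05/n_mm_loci`; loci labelled as discovered in both
#' traits are captured by the genome-wide-both rule only.
#'
#' @param fixture data.frame from [table1_fixture()].
#' @param n_cll_loci,n_mm_loci known risk-locus counts (45, 23).
#' @param alpha family-wise level.
#' @return list with `scan_cll_to_mm`, `scan_mm_to_cll`, `summary`.
#' @export
scan_table1 <- function(fixture = table1_fixture(), n_cll_loci = 45,
                        n_mm_loci = 23, alpha = 0.05) {
  av <- avs_from_table1(fixture)
  cll <- av$loci[av$loci$discovery == "CLL", ]
  mm <- av$loci[av$loci$discovery == "MM", ]
  res_cll <- region_wide_scan(cll, av$members, av$p_mm, n_cll_loci, alpha,
                              p_own = av$p_cll)
  res_mm <- region_wide_scan(mm, av$members, av$p_cll, n_mm_loci, alpha,
                             p_own = av$p_mm)
  summ <- classify_pleiotropic(res_cll, res_mm, av$members,
                               p_a = av$p_cll, p_b = av$p_mm)
  list(scan_cll_to_mm = res_cll, scan_mm_to_cll = res_mm, summary = summ)
}
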