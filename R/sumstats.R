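# Summary-statistics I/O, harmonization and QC.
#
# Canonical column set (tab-separated, header required):
#   SNP CHR BP A1 A2 BETA SE Z P N_CAS N_CON MAF INFO
# A1 is the effect allele. Foreign headers are handled through a `dialect`
# mapping canonical name -> file column name.

CANONICAL_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z", "P",
                    "N_CAS", "N_CON", "MAF", "INFO")

# default HLA exclusion interval (1-based inclusive, build-agnostic extended MHC)
HLA_REGION <- list(chrom = "6", start = 25e6, end = 34e6)

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-separated association table, maps foreign column
#' names through `dialect`, validates mandatory fields and derives missing
#' statistics: `Z` from `BETA/SE`, `P` from `Z` under the two-sided normal.
#' Rows whose mandatory fields fail to parse are returned in the
#' `"bad_rows"` attribute rather than silently dropped. Variants with a
#' non-ACGT or multi-base allele are flagged in the logical `is_indel` column
#' for downstream filtering; they are not an error.
#'
#' If both `Z` and `BETA/SE` are present they must agree to 1e-6; if both a
#' supplied `P` and the `Z`-derived p-value exist and disagree by more than
#' 1e-4 on the -log10 scale the row is flagged `inconsistent` (removed later
#' by [harmonize_pair()] with reason `"inconsistent_stats"`).
#'
#' @param path path to the table (uncompressed text).
#' @param dialect optional named character vector, canonical name ->
#'   column name in the file, e.g. `c(SNP = "rsid", P = "pval")`.
#' @return data.frame with canonical columns (missing optional ones filled
#'   with `NA`), plus `is_indel` and `inconsistent` flags; attribute
#'   `bad_rows` holds unparseable input rows.
#' @export
read_sumstats <- function(path, dialect = NULL) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = list(character = 1))
  nm <- names(raw)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), CANONICAL_COLS)
    if (length(bad))
      stop("dialect maps unknown canonical column(s): ", paste(bad, collapse = ", "))
    missing_src <- dialect[!dialect %in% nm]
    if (length(missing_src))
      stop("configuration error: column(s) named in dialect not in file: ",
           paste(sprintf("%s -> %s", names(missing_src), missing_src), collapse = ", "))
    for (canon in names(dialect)) nm[nm == dialect[[canon]]] <- canon
    names(raw) <- nm
  }
  mandatory <- c("SNP", "CHR", "BP", "A1", "A2")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("configuration error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!("Z" %in% names(raw)) && !all(c("BETA", "SE") %in% names(raw)))
    stop("configuration error: need either column Z or columns BETA and SE")

  ss <- data.frame(SNP = as.character(raw$SNP),
                   CHR = as.character(raw$CHR),
                   BP = suppressWarnings(as.integer(raw$BP)),
                   A1 = toupper(as.character(raw$A1)),
                   A2 = toupper(as.character(raw$A2)),
                   stringsAsFactors = FALSE)
  for (col in c("BETA", "SE", "Z", "P", "MAF", "INFO")) {
    ss[[col]] <- if (col %in% names(raw))
      suppressWarnings(as.numeric(raw[[col]])) else NA_real_
  }
  for (col in c("N_CAS", "N_CON")) {
    ss[[col]] <- if (col %in% names(raw))
      suppressWarnings(as.integer(raw[[col]])) else NA_integer_
  }

  bad <- is.na(ss$SNP) | ss$SNP == "" | is.na(ss$BP) | ss$BP < 1 |
    is.na(ss$CHR) | ss$CHR == "" |
    (is.na(ss$Z) & (is.na(ss$BETA) | is.na(ss$SE))) |
    (!is.na(ss$SE) & ss$SE <= 0)
  bad_rows <- ss[bad, , drop = FALSE]
  ss <- ss[!bad, , drop = FALSE]

  # derive Z then P; keep |Z| authoritative
  derivable <- is.na(ss$Z) & !is.na(ss$BETA) & !is.na(ss$SE)
  ss$Z[derivable] <- ss$BETA[derivable] / ss$SE[derivable]
  both <- !is.na(ss$BETA) & !is.na(ss$SE) & !derivable
  if (any(both)) {
    if (any(abs(ss$Z[both] - ss$BETA[both] / ss$SE[both]) > 1e-6 *
            pmax(1, abs(ss$Z[both]))))
      warning("Z and BETA/SE disagree beyond 1e-6 for some SNPs; keeping Z")
  }
  p_from_z <- 2 * pnorm(-abs(ss$Z))
  ss$inconsistent <- !is.na(ss$P) & ss$P > 0 & p_from_z > 0 &
    abs(log10(ss$P) - log10(p_from_z)) > 1e-4
  ss$P[is.na(ss$P)] <- p_from_z[is.na(ss$P)]

  valid_base <- ss$A1 %in% names(DNA_COMP) & ss$A2 %in% names(DNA_COMP)
  ss$is_indel <- !valid_base
  rownames(ss) <- NULL
  attr(ss, "bad_rows") <- bad_rows
  if (nrow(bad_rows))
    message(nrow(bad_rows), " row(s) with unparseable mandatory fields (see attr 'bad_rows')")
  ss
}

#' Write a summary-statistics table in the canonical dialect
#' @param ss data.frame from [read_sumstats()] or a simulator.
#' @param path output path.
#' @export
write_sumstats <- function(ss, path) {
  cols <- intersect(CANONICAL_COLS, names(ss))
  data.table::fwrite(ss[cols], path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

new_qc_report <- function(n_input, removed_reason, retained) {
  r <- list(n_input = n_input,
            n_removed_by_reason = table(factor(removed_reason)),
            retained = retained)
  class(r) <- "qc_report"
  r
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "input SNPs,", length(x$retained), "retained\n")
  tb <- x$n_removed_by_reason
  for (r in names(tb)) cat(sprintf("  removed %-20s %d\n", r, tb[[r]]))
  invisible(x)
}

#' Serialize a QC report as a machine-readable key-value table
#' @param report a `qc_report`.
#' @return data.frame with columns `key`, `value`.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  tb <- report$n_removed_by_reason
  data.frame(key = c("n_input", "n_retained", paste0("removed_", names(tb))),
             value = c(report$n_input, length(report$retained),
                       as.integer(tb)),
             stringsAsFactors = FALSE)
}

strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# match study alleles against a reference pair up to swap and strand flip.
# returns "ok", "swap" or "mismatch" per SNP (ambiguous pairs excluded earlier)
match_alleles <- function(a1, a2, r1, r2) {
  c1 <- unname(DNA_COMP[a1]); c2 <- unname(DNA_COMP[a2])
  out <- rep("mismatch", length(a1))
  out[(a1 == r1 & a2 == r2) | (c1 == r1 & c2 == r2)] <- "ok"
  out[(a1 == r2 & a2 == r1) | (c1 == r2 & c2 == r1)] <- "swap"
  out
}

#' Harmonize two traits' summary statistics to a common reference
#'
#' Applies the cross-trait LD-score-regression input filters and aligns both
#' tables to the reference effect allele. Retained SNPs satisfy, in both
#' traits: imputation INFO > 0.9, study MAF > 0.01, presence in the reference
#' with reference MAF > 0.05, single-base non-ambiguous alleles (A/T and C/G
#' dropped), alleles matching the reference pair up to swap and strand flip,
#' and position outside the HLA exclusion interval. Allele-swapped records
#' have `BETA` and `Z` sign-flipped onto the reference effect allele; `|Z|`
#' and `P` are never changed.
#'
#' Removal reasons follow a fixed precedence (first triggered wins):
#' parse, inconsistent_stats, indel, info, maf, not_in_reference,
#' reference_maf, strand_ambiguous, allele_mismatch, hla, not_in_both.
#' The report covers the union of SNP ids seen in either trait.
#'
#' @param ss_a,ss_b data.frames from [read_sumstats()].
#' @param reference data.frame with columns `SNP`, `A1`, `A2`, `MAF`
#'   (reference-panel allele pair and allele frequency).
#' @param hla_region list with `chrom`, `start`, `end` (1-based inclusive);
#'   default chr6:25,000,000-34,000,000. `NULL` disables the exclusion.
#' @param info_min,maf_min,ref_maf_min filter thresholds.
#' @return list with elements `a`, `b` (filtered, allele-aligned data.frames
#'   with identical SNP sets in identical order) and `report` (a `qc_report`).
#' @export
harmonize_pair <- function(ss_a, ss_b, reference, hla_region = HLA_REGION,
                           info_min = 0.9, maf_min = 0.01, ref_maf_min = 0.05) {
  stopifnot(all(c("SNP", "A1", "A2", "MAF") %in% names(reference)))
  ref <- reference[!duplicated(reference$SNP), ]

  reason_one <- function(ss) {
    # per-SNP first-triggered removal reason, NA = pass all single-trait filters
    idx <- match(ss$SNP, ref$SNP)
    in_ref <- !is.na(idx)
    amb <- strand_ambiguous(ss$A1, ss$A2)
    match_st <- rep("mismatch", nrow(ss))
    chk <- in_ref & !ss$is_indel & !amb
    if (any(chk))
      match_st[chk] <- match_alleles(ss$A1[chk], ss$A2[chk],
                                     ref$A1[idx[chk]], ref$A2[idx[chk]])
    in_hla <- if (is.null(hla_region)) rep(FALSE, nrow(ss)) else
      ss$CHR == as.character(hla_region$chrom) &
      ss$BP >= hla_region$start & ss$BP <= hla_region$end
    reason <- rep(NA_character_, nrow(ss))
    hit <- function(cond, lab) reason <<- ifelse(is.na(reason) & cond, lab, reason)
    hit(isTRUE_vec(ss$inconsistent), "inconsistent_stats")
    hit(ss$is_indel, "indel")
    hit(!is.na(ss$INFO) & ss$INFO <= info_min, "info")
    hit(!is.na(ss$MAF) & ss$MAF <= maf_min, "maf")
    hit(!in_ref, "not_in_reference")
    hit(in_ref & ref$MAF[idx] <= ref_maf_min, "reference_maf")
    hit(amb, "strand_ambiguous")
    hit(match_st == "mismatch", "allele_mismatch")
    hit(in_hla, "hla")
    list(reason = reason, match = match_st, ref_idx = idx)
  }
  ra <- reason_one(ss_a); rb <- reason_one(ss_b)

  all_ids <- union(ss_a$SNP, ss_b$SNP)
  r_a <- ra$reason[match(all_ids, ss_a$SNP)]
  r_b <- rb$reason[match(all_ids, ss_b$SNP)]
  in_a <- all_ids %in% ss_a$SNP; in_b <- all_ids %in% ss_b$SNP
  # combined precedence: a reason from either trait, in precedence order
  prec <- c("inconsistent_stats", "indel", "info", "maf", "not_in_reference",
            "reference_maf", "strand_ambiguous", "allele_mismatch", "hla")
  combined <- rep(NA_character_, length(all_ids))
  for (p in prec) {
    trig <- is.na(combined) & ((!is.na(r_a) & r_a == p) | (!is.na(r_b) & r_b == p))
    combined[trig] <- p
  }
  combined[is.na(combined) & !(in_a & in_b)] <- "not_in_both"
  keep_ids <- all_ids[is.na(combined)]
  if (!length(keep_ids)) stop("no harmonized SNPs after filtering")

  align <- function(ss, rr) {
    i <- match(keep_ids, ss$SNP)
    out <- ss[i, , drop = FALSE]
    sw <- rr$match[i] == "swap"
    out$BETA[sw] <- -out$BETA[sw]
    out$Z[sw] <- -out$Z[sw]
    ri <- rr$ref_idx[i]
    out$A1 <- ref$A1[ri]; out$A2 <- ref$A2[ri]
    rownames(out) <- NULL
    out
  }
  report <- new_qc_report(length(all_ids), combined[!is.na(combined)], keep_ids)
  list(a = align(ss_a, ra), b = align(ss_b, rb), report = report)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: sums, over all heterozygote counts compatible with
#' the observed allele counts (same parity), the probabilities of tables no
#' more probable than the observed one. Monomorphic markers return 1 by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  n_a <- 2 * n_aa + n_Aa          # minor-ish allele count (either works)
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_het | allele counts) up to a constant: standard exact HWE kernel
  logp <- hets * log(2) + lgamma(n + 1) -
    (lgamma((rare - hets) / 2 + 1) + lgamma(hets + 1) +
       lgamma((2 * n - rare - hets) / 2 + 1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  if (is.na(obs)) stop("observed heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Genotype-matrix quality control
#'
#' Individuals with call rate < `ind_call_rate` are removed first; SNP filters
#' (call rate, MAF, exact HWE in controls) are then applied to the remaining
#' individuals. Each failing SNP is assigned its first-triggered reason in
#' the order call_rate, maf, hwe.
#'
#' @param geno individuals x SNPs matrix coded 0/1/2 with `NA` for missing;
#'   column names are SNP ids.
#' @param is_control logical per individual; HWE is computed in controls only.
#'   Default: all individuals.
#' @param snp_call_rate,ind_call_rate,maf_min,hwe_p_min thresholds.
#' @return a `qc_report`; attribute `removed_individuals` lists dropped rows.
#' @export
qc_genotypes <- function(geno, is_control = rep(TRUE, nrow(geno)),
                         snp_call_rate = 0.95, ind_call_rate = 0.95,
                         maf_min = 0.01, hwe_p_min = 1e-5) {
  stopifnot(is.matrix(geno), nrow(geno) > 0, ncol(geno) > 0)
  if (is.null(colnames(geno))) colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  ind_cr <- rowMeans(!is.na(geno))
  keep_ind <- ind_cr >= ind_call_rate
  if (!any(keep_ind)) stop("degenerate input: all individuals removed by call-rate filter")
  g <- geno[keep_ind, , drop = FALSE]
  ctrl <- is_control[keep_ind]

  cr <- colMeans(!is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  gc <- g[ctrl, , drop = FALSE]
  hwe <- vapply(seq_len(ncol(gc)), function(j) {
    x <- gc[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))

  reason <- rep(NA_character_, ncol(g))
  reason[cr < snp_call_rate] <- "call_rate"
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & hwe < hwe_p_min] <- "hwe"
  rep_out <- new_qc_report(ncol(g), reason[!is.na(reason)],
                           colnames(g)[is.na(reason)])
  attr(rep_out, "removed_individuals") <- which(!keep_ind)
  rep_out
}

#' Genomic inflation factor and its 1000-case/1000-control rescaling
#'
#' `lambda_gc` is the median chi-square among the `quantile_fraction`
#' least-significant SNPs divided by the null median `qchisq(0.5, 1)`.
#' `lambda_1000` rescales to an equivalent study of 1000 cases and 1000
#' controls: `1 + (lambda - 1) * (1/n_cases + 1/n_controls) / (2/1000)`.
#'
#' @param chi2 per-SNP chi-square statistics (1 df).
#' @param n_cases,n_controls study sample sizes.
#' @param quantile_fraction fraction of least-significant SNPs used (default 0.90).
#' @return list with `lambda_gc`, `lambda_1000`, `n_snps_used`, and a
#'   `warning` field when fewer than 100 SNPs were supplied.
#' @export
genomic_inflation <- function(chi2, n_cases, n_controls, quantile_fraction = 0.90) {
  chi2 <- chi2[is.finite(chi2)]
  stopifnot(length(chi2) > 0, quantile_fraction > 0, quantile_fraction <= 1)
  srt <- sort(chi2)
  k <- max(1L, floor(quantile_fraction * length(srt)))
  used <- srt[seq_len(k)]
  lambda <- median(used) / qchisq(0.5, df = 1)
  lambda_1000 <- 1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) / (2 / 1000)
  out <- list(lambda_gc = lambda, lambda_1000 = lambda_1000, n_snps_used = k)
  if (length(chi2) < 100) out$warning <- "fewer than 100 SNPs; inflation estimate unstable"
  out
}
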