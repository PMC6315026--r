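# Small tabular I/O helpers for the remaining interchange formats:
# reference panels, locus-definition files, scan reports, eQTL catalogs.

#' Serialize / restore an LD panel as tab-separated text
#'
#' Writes `<stem>.variants.tsv` (variant metadata plus per-block decay and
#' block index) and `<stem>.dosages.tsv` (individuals x SNPs dosage matrix).
#' `read_ld_panel()` restores a panel usable by [compute_ld_scores()],
#' [build_avs()] and [build_snp_universe()].
#'
#' @param panel an `ld_panel`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_ld_panel <- function(panel, stem) {
  v <- panel$variants
  blk <- rep.int(seq_len(nrow(panel$blocks)),
                 panel$blocks$end - panel$blocks$start + 1L)
  v$BLOCK <- blk
  v$BLOCK_DECAY <- panel$block_decay[blk]
  data.table::fwrite(v, paste0(stem, ".variants.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(panel$genotypes),
                     paste0(stem, ".dosages.tsv"), sep = "\t")
  invisible(stem)
}

#' @rdname write_ld_panel
#' @export
read_ld_panel <- function(stem) {
  v <- data.table::fread(paste0(stem, ".variants.tsv"), data.table = FALSE,
                         colClasses = list(character = "CHR"))
  g <- as.matrix(data.table::fread(paste0(stem, ".dosages.tsv"),
                                   data.table = FALSE))
  colnames(g) <- v$SNP
  blocks <- do.call(rbind, lapply(split(seq_len(nrow(v)), v$BLOCK),
                                  function(i) data.frame(start = min(i),
                                                         end = max(i))))
  blocks <- blocks[order(blocks$start), ]
  rownames(blocks) <- NULL
  out <- list(variants = v[, c("SNP", "CHR", "BP", "A1", "A2", "MAF")],
              genotypes = g, blocks = blocks,
              block_decay = v$BLOCK_DECAY[blocks$start],
              config = NULL)
  class(out) <- "ld_panel"
  out
}

#' Read a locus-definition table
#'
#' Tab-separated with header `LOCUS`, `DISCOVERY`, `SENTINEL_SNP` — the
#' format accepted by the pleiotropy scan for user-supplied risk loci.
#'
#' @param path file path.
#' @return data.frame with `locus`, `discovery`, `sentinel`.
#' @export
read_locus_file <- function(path) {
  tb <- data.table::fread(path, data.table = FALSE)
  need <- c("LOCUS", "DISCOVERY", "SENTINEL_SNP")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("locus file lacks column(s): ",
                         paste(miss, collapse = ", "))
  data.frame(locus = as.character(tb$LOCUS),
             discovery = as.character(tb$DISCOVERY),
             sentinel = as.character(tb$SENTINEL_SNP),
             stringsAsFactors = FALSE)
}

#' Write a scan result as a risk-locus-table-shaped TSV
#'
#' One row per locus with the best cross-trait variant, its p-value, the
#' Bonferroni threshold used and the pass flags.
#'
#' @param scan data.frame from [region_wide_scan()].
#' @param path output path.
#' @export
write_scan_report <- function(scan, path) {
  data.table::fwrite(scan, path, sep = "\t", quote = FALSE, na = "-")
  invisible(path)
}

#' Read an eQTL summary-statistics catalog
#'
#' Tab-separated with header `PROBE GENE SNP B SE P` (gene optional); the
#' per-probe cis-eQTL format consumed by [run_smr_scan()].
#'
#' @param path file path.
#' @return data.frame with `probe`, `gene`, `SNP`, `b_zx`, `se_zx`, `p_zx`.
#' @export
read_eqtl <- function(path) {
  tb <- data.table::fread(path, data.table = FALSE)
  need <- c("PROBE", "SNP", "B", "SE")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("eQTL file lacks column(s): ",
                         paste(miss, collapse = ", "))
  se <- as.numeric(tb$SE)
  if (any(!is.finite(se) | se <= 0)) stop("eQTL SE must be positive")
  b <- as.numeric(tb$B)
  p <- if ("P" %in% names(tb)) as.numeric(tb$P) else 2 * pnorm(-abs(b / se))
  data.frame(probe = as.character(tb$PROBE),
             gene = if ("GENE" %in% names(tb)) as.character(tb$GENE) else NA,
             SNP = as.character(tb$SNP),
             b_zx = b, se_zx = se, p_zx = p, stringsAsFactors = FALSE)
}
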