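# Variant-set enrichment (VSE): does a set of risk loci overlap chromatin
# peaks more often than matched random variant sets? Plus a cell-type
# specificity score across tissues.

norm_chrom <- function(x) sub("^chr", "", as.character(x))

peaks_granges <- function(peaks) {
  if (inherits(peaks, "GRanges")) return(peaks)
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) == 0)
    return(GenomicRanges::GRanges())
  stopifnot(all(peaks$start < peaks$end))
  # BED is 0-based half-open; GRanges is 1-based inclusive
  gr <- GenomicRanges::GRanges(norm_chrom(peaks$chrom),
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  if ("fold" %in% names(peaks)) S4Vectors::mcols(gr)$fold <- peaks$fold
  gr
}

#' Read a BED peak file (3-6 columns, optional fold-enrichment column)
#'
#' Columns beyond the first three are scanned for a numeric column named
#' `fold` (or supplied via `fold_col`) carrying per-peak fold-enrichment.
#'
#' @param path BED path (0-based half-open intervals).
#' @param fold_col optional index of the fold-enrichment column.
#' @return data.frame `chrom`, `start`, `end` and optionally `fold`.
#' @export
read_bed <- function(path, fold_col = NULL) {
  bed <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(bed) < 3) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
  if (!is.null(fold_col)) out$fold <- as.numeric(bed[[fold_col]])
  out
}

snp_granges <- function(snps) {
  # snps: data.frame with CHR (or chrom) and BP (1-based position)
  chrom <- if ("CHR" %in% names(snps)) snps$CHR else snps$chrom
  pos <- if ("BP" %in% names(snps)) snps$BP else snps$pos
  GenomicRanges::GRanges(norm_chrom(chrom), IRanges::IRanges(pos, pos))
}

# positions of each AVS's members, as a list of GRanges-index vectors
avs_positions <- function(avs_list, panel_variants) {
  lapply(avs_list, function(a) {
    ids <- if (inherits(a, "avs")) a$members$SNP else a$snp_id
    i <- match(ids, panel_variants$SNP)
    panel_variants[i[!is.na(i)], c("CHR", "BP"), drop = FALSE]
  })
}

#' Locus-level mapping tally of AVSs against a peak set
#'
#' Counts the loci with at least one member SNP falling inside at least one
#' peak. SNP positions are 1-based; peaks are 0-based half-open, so a SNP at
#' position `p` is inside `[p-1, p)` but not `[p, p+1)`. `chr`-prefixed and
#' bare chromosome names are normalized to a common convention (warning once
#' per call when mixed).
#'
#' @param avs_list list of `avs` objects or of data.frames with `CHR`, `BP`.
#' @param peaks data.frame (`chrom`, `start`, `end`) or `GRanges`.
#' @param panel_variants variant table used to resolve member positions when
#'   `avs_list` holds `avs` objects.
#' @return integer tally.
#' @export
mapping_tally <- function(avs_list, peaks, panel_variants = NULL) {
  gr <- peaks_granges(peaks)
  if (!is.null(panel_variants))
    avs_list <- avs_positions(avs_list, panel_variants)
  if (is.data.frame(peaks) && nrow(peaks) > 0 &&
      any(grepl("^chr", peaks$chrom)) != all(grepl("^chr", peaks$chrom)))
    warning("mixed chromosome naming in peaks; normalized by stripping 'chr'")
  sum(vapply(avs_list, function(d) {
    if (nrow(d) == 0) return(FALSE)
    any(IRanges::overlapsAny(snp_granges(d), gr))
  }, logical(1)))
}

#' Build a matched-null SNP universe from an LD panel
#'
#' Precomputes, for every panel SNP, its correlated-variant set (within-block
#' `r2 > r2_threshold` on the generating AR(1) LD) and MAF, the two matching
#' characteristics used when sampling null variant sets.
#'
#' @param panel an `ld_panel`.
#' @param r2_threshold LD cutoff defining correlated sets.
#' @return data.frame of class `snp_universe`: `SNP`, `CHR`, `BP`, `MAF`,
#'   `set_size`, with a list-column `members` of data.frames (`SNP`, `CHR`,
#'   `BP`) carrying each correlated set with its positions.
#' @export
build_snp_universe <- function(panel, r2_threshold = 0.8) {
  v <- panel$variants
  m <- nrow(v)
  members <- vector("list", m)
  for (b in seq_len(nrow(panel$blocks))) {
    idx <- panel$blocks$start[b]:panel$blocks$end[b]
    R2 <- ar1_cor(length(idx), panel$block_decay[b])^2
    for (jj in seq_along(idx)) {
      mi <- idx[R2[jj, ] > r2_threshold]
      members[[idx[jj]]] <- data.frame(SNP = v$SNP[mi], CHR = v$CHR[mi],
                                       BP = v$BP[mi], stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(SNP = v$SNP, CHR = v$CHR, BP = v$BP, MAF = v$MAF,
                    set_size = vapply(members, nrow, integer(1)),
                    stringsAsFactors = FALSE)
  out$members <- members   # each member set carries its own positions,
  class(out) <- c("snp_universe", class(out))   # so subsetting rows is safe
  out
}

# per-universe-SNP flag: does the SNP's correlated set hit any peak?
universe_hits <- function(universe, peaks) {
  gr <- peaks_granges(peaks)
  all_mem <- do.call(rbind, universe$members)
  grp <- rep.int(seq_len(nrow(universe)),
                 vapply(universe$members, nrow, integer(1)))
  hit <- IRanges::overlapsAny(snp_granges(all_mem), gr)
  out <- logical(nrow(universe))
  agg <- tapply(hit, grp, any)
  out[as.integer(names(agg))] <- agg
  out
}

match_candidates <- function(universe, maf, size, maf_bins, size_tol = 0.25) {
  bin <- findInterval(maf, maf_bins, all.inside = TRUE)
  target_bin <- findInterval(universe$MAF, maf_bins, all.inside = TRUE)
  lo <- max(1, floor(size * (1 - size_tol))); hi <- ceiling(size * (1 + size_tol))
  which(target_bin == bin & universe$set_size >= lo & universe$set_size <= hi)
}

#' Sample the matched-null tally distribution
#'
#' Each permutation replaces every AVS by a random universe SNP matched on
#' MAF (20 quantile bins over the universe) and correlated-set size (within
#' +/- 25%), together with that SNP's own correlated set, and recomputes the
#' locus-level mapping tally. If a locus has no match the bins are widened
#' once (40% size tolerance, +/- 1 MAF bin); failing that an error is raised.
#'
#' @param avs_list list of `avs` objects.
#' @param universe a [build_snp_universe()] result.
#' @param peaks peak set (data.frame or GRanges).
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed.
#' @return integer vector of `n_perm` null tallies.
#' @export
sample_matched_null <- function(avs_list, universe, peaks, n_perm = 10000,
                                seed = 1L) {
  set.seed(seed)
  hits <- universe_hits(universe, peaks)
  maf_bins <- unique(stats::quantile(universe$MAF, probs = seq(0, 1, length.out = 21)))
  cand <- lapply(avs_list, function(a) {
    ids <- a$members$SNP
    j <- match(a$sentinel, universe$SNP)
    maf <- if (!is.na(j)) universe$MAF[j] else stats::median(universe$MAF)
    k <- match_candidates(universe, maf, length(ids), maf_bins)
    if (!length(k)) {  # widen once
      k <- match_candidates(universe, maf, length(ids), maf_bins, size_tol = 0.4)
      if (!length(k))
        stop("no matched null SNPs available for locus ", a$locus)
    }
    k
  })
  vapply(seq_len(n_perm), function(p) {
    sum(vapply(cand, function(k) hits[k[sample.int(length(k), 1L)]], logical(1)))
  }, integer(1))
}

#' Variant-set enrichment test
#'
#' Observed locus-level mapping tally versus the matched-null distribution.
#' Empirical p uses the add-one rule `p = (1 + #(null >= obs)) / (1 + B)`;
#' the enrichment score is `(obs - median(null)) / sd(null)` (number of null
#' SDs from the null median).
#'
#' @inheritParams sample_matched_null
#' @param panel_variants variant table resolving AVS member positions.
#' @return list of class `enrichment_result`: `observed`, `null_tallies`,
#'   `score` (NA with `score_undefined = TRUE` when the null SD is 0),
#'   `p_empirical`, `n_perm`.
#' @export
vse_test <- function(avs_list, peaks, universe, panel_variants,
                     n_perm = 10000, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100: empirical p is very coarse")
  obs <- mapping_tally(avs_list, peaks, panel_variants)
  nulls <- sample_matched_null(avs_list, universe, peaks, n_perm, seed)
  s <- sd(nulls)
  score <- if (s > 0) (obs - median(nulls)) / s else NA_real_
  out <- list(observed = obs, null_tallies = nulls,
              score = score, score_undefined = !(s > 0),
              p_empirical = (1 + sum(nulls >= obs)) / (1 + n_perm),
              n_perm = n_perm)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("VSE: observed tally %d, null median %.1f; score = %s, p = %.4g (%d perms)\n",
              x$observed, median(x$null_tallies),
              if (x$score_undefined) "undefined (zero null SD)" else sprintf("%.2f", x$score),
              x$p_empirical, x$n_perm))
  invisible(x)
}

triangular_kernel <- function(dist, bandwidth) pmax(0, 1 - dist / bandwidth)

#' Cell-type specificity of GWAS SNPs across chromatin-mark peak sets
#'
#' Per SNP and cell type the score is the maximum over peaks of
#' fold-enrichment times a triangular proximity kernel (1 inside the peak,
#' decaying linearly to 0 at `bandwidth` bp away). The cell-type statistic
#' sums over SNPs; significance is assessed tissue by tissue by permuting
#' SNP positions uniformly over the universe positions.
#'
#' @param gwas_snps data.frame with `CHR`, `BP` (1-based) for the scored SNPs.
#' @param marks named list of peak sets (data.frames with `chrom`, `start`,
#'   `end`, `fold`), one per cell type.
#' @param universe_pos data.frame with `CHR`, `BP`: positions null SNPs are
#'   drawn from.
#' @param n_perm permutations per cell type.
#' @param bandwidth kernel bandwidth in bp (default 2500).
#' @param seed integer seed.
#' @return data.frame: `cell_type`, `score`, `p`.
#' @export
cell_type_specificity <- function(gwas_snps, marks, universe_pos,
                                  n_perm = 1000, bandwidth = 2500, seed = 1L) {
  set.seed(seed)
  score_snps <- function(pos_df, gr, fold) {
    if (length(gr) == 0) return(numeric(nrow(pos_df)))
    sg <- snp_granges(pos_df)
    out <- numeric(nrow(pos_df))
    # nearest peak is not necessarily the best-scoring one when folds vary;
    # check all peaks within bandwidth of each SNP
    ov <- GenomicRanges::findOverlaps(sg, gr + bandwidth)
    if (length(ov)) {
      dd <- GenomicRanges::distance(sg[S4Vectors::queryHits(ov)],
                                    gr[S4Vectors::subjectHits(ov)])
      val <- fold[S4Vectors::subjectHits(ov)] * triangular_kernel(dd, bandwidth)
      agg <- tapply(val, S4Vectors::queryHits(ov), max)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  rows <- lapply(names(marks), function(ct) {
    pk <- marks[[ct]]
    if (is.null(pk) || (is.data.frame(pk) && nrow(pk) == 0)) {
      warning("cell type with zero peaks: ", ct)
      return(data.frame(cell_type = ct, score = 0, p = 1))
    }
    fold <- if ("fold" %in% names(pk)) pk$fold else rep(1, nrow(pk))
    gr <- peaks_granges(pk)
    obs <- sum(score_snps(gwas_snps, gr, fold))
    null_stats <- vapply(seq_len(n_perm), function(b) {
      i <- sample.int(nrow(universe_pos), nrow(gwas_snps), replace = TRUE)
      sum(score_snps(universe_pos[i, , drop = FALSE], gr, fold))
    }, numeric(1))
    data.frame(cell_type = ct, score = obs,
               p = (1 + sum(null_stats >= obs)) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
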