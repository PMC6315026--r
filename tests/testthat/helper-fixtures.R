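# Shared fixtures, built in code at test time.

# small default panel reused across tests (cheap: ~1s)
tiny_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- make_ld_panel(sim_config(m_snps = 400,
                                                   ld_block_size = 20,
                                                   n_ref = 400, seed = 11))
    p
  }
})

# write a canonical summary-stats table to a temp file
write_ss_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_sumstats <- function() {
  data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
             BP = c(100L, 200L, 300L),
             A1 = c("A", "C", "G"), A2 = c("G", "T", "A"),
             BETA = c(0.1, -0.05, 0.02), SE = c(0.05, 0.025, 0.01),
             N_CAS = 1000L, N_CON = 1000L,
             MAF = c(0.2, 0.3, 0.4), INFO = c(0.99, 0.95, 0.97),
             stringsAsFactors = FALSE)
}

# independent full-enumeration oracle for the exact HWE test: enumerate all
# genotype tables with the observed allele counts and sum multinomial-style
# probabilities of tables no more probable than the observed one
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * naa + nAa
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    n_hom_rare <- (rare - h) / 2
    n_hom_com <- n - h - n_hom_rare
    exp(lgamma(n + 1) - lgamma(n_hom_rare + 1) - lgamma(h + 1) -
          lgamma(n_hom_com + 1) + h * log(2) +
          lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  prob <- prob / sum(prob)   # normalization (constant factors cancel)
  obs <- prob[match(nAa, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# brute-force all-pairs LD-score oracle
ld_score_oracle <- function(geno, adjusted = TRUE) {
  n <- nrow(geno)
  r2 <- cor(geno)^2
  if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
  diag(r2) <- 1
  unname(rowSums(r2))
}

# first-principles SMR oracle via the harmonic-mean identity
smr_oracle <- function(b_zx, se_zx, b_zy, se_zy) {
  z1sq <- (b_zx / se_zx)^2
  z2sq <- (b_zy / se_zy)^2
  t <- 1 / (1 / z1sq + 1 / z2sq)
  list(b_xy = b_zy / b_zx, t_smr = t,
       p_smr = pchisq(t, 1, lower.tail = FALSE))
}
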