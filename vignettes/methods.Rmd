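---
title: "Methods: cross-trait genetic correlation and pleiotropy from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait genetic correlation and pleiotropy from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstraitr)
```

# The question and the model

Do two complex diseases share common genetic aetiology? `crosstraitr`
answers this at three scales using nothing but GWAS summary statistics, an
LD reference panel, chromatin-peak intervals and eQTL summary data:

1. **Genome-wide**: cross-trait LD-score regression estimates the genetic
   correlation $R_g$ between the traits.
2. **Locus-level**: a region-wide Bonferroni scan asks which known risk loci
   of one disease also associate with the other.
3. **Mechanism-level**: variant-set enrichment places shared loci in
   regulatory chromatin, and SMR/HEIDI asks whether a shared signal is
   mediated by gene expression.

## LD-score regression

For SNP $j$ with LD score $\ell_j = \sum_k r^2_{jk}$ (sum of squared
correlations with all SNPs in a window, self included), the polygenic model
implies

$$E[\chi^2_j] = 1 + \frac{N h^2 \ell_j}{M}, \qquad
  E[z_{1j} z_{2j}] = \rho_{\text{overlap}} + \frac{\sqrt{N_1 N_2}\,\rho_g\,\ell_j}{M},$$

so regressing per-SNP $\chi^2$ (or the cross-trait product of Z-scores) on
$\ell_j$ with a free intercept yields $h^2$ (or the genetic covariance
$\rho_g$), and $R_g = \rho_g / \sqrt{h^2_1 h^2_2}$. The free intercept is
the point of the method: confounding from population structure and, in the
cross-trait case, from shared samples moves the intercept, not the slope,
so $R_g$ is not biased by sample overlap. Heritabilities are reported on
the observed scale; genetic correlation needs no scale conversion for
case-control traits.

Implementation choices (all configurable):

* **Weights**: two-pass weighted least squares. A provisional unweighted
  fit sets the per-SNP expected statistic; the second pass weights by
  $1/(\max(\ell_j, 1)\cdot \hat{E}[\cdot]^2)$, the standard
  heteroskedasticity-and-overcounting correction. Weights affect
  efficiency, not consistency, so tests assert recovery of the estimand,
  not a particular weighting.
* **Uncertainty**: delete-one-block jackknife over 200 contiguous
  equal-count SNP blocks. For $R_g$ the *full ratio* is re-estimated in
  every leave-one-out sample (both heritabilities and the covariance). In a
  leave-out sample the denominator heritabilities are floored at a quarter
  of their full-sample estimates: a single pathological block can otherwise
  send a ratio pseudovalue to infinity. The floor only engages in samples
  whose leave-out heritability collapses below that bound, where the
  jackknife variance is dominated by the flooring anyway. $P(R_g \ne 0)$
  uses the normal approximation $R_g/\mathrm{SE}$.

  A desk-scale caveat worth knowing: with $M = 10{,}000$ SNPs in 200 LD
  blocks there are only ~200 independent units, and across simulation
  replicates the *realized* regression estimand (given one draw of causal
  effects) varies nearly as much as the estimates themselves. The jackknife
  is calibrated for a replicate's own sampling noise, but it is conditioned
  on the reference panel: validation experiments that re-use one panel for
  every replicate share that panel's LD-score noise and block-decay draw
  across replicates and make the jackknife look anticonservative. Interval
  coverage should therefore be assessed with a fresh panel per replicate,
  which is how the package's acceptance experiments are run (measured
  coverage ≈95% at nominal 95%).
* **Outlier guard**: SNPs with $\chi^2 > \max(80, 0.001\,N)$ are excluded
  (and counted). At consortium scale this is the conventional guard; at toy
  scale ($M$ of a few thousand) per-SNP expected $\chi^2$ is large and the
  guard can truncate real signal, so simulation worlds here keep
  $E[\chi^2]$ well below the cap.
* **LD scores**: empirical within a 1 Mb window, with the finite-sample
  adjustment $r^2_{\text{adj}} = r^2 - (1-r^2)/(n-2)$ so that null pairs
  contribute zero on average.
* **Stratified fit**: the partitioned regression uses all per-category LD
  scores jointly; per-category enrichment is (share of $h^2$)/(share of
  SNPs). The conventional enrichment definition is used even though the
  published descriptions sometimes phrase it loosely as heritability proportion over
  total heritability; flanking-window helper categories (names ending
  `.flank`) are fitted but excluded from the report.

## The region-wide pleiotropy scan

Known risk loci of the discovery trait are expanded to their correlated
variant sets ($r^2 > 0.8$, optionally $D' > 0.8$). A locus counts as
pleiotropic when the **minimum p-value over its set** in the *other* trait
beats $\alpha/n_{\text{discovery loci}}$ (0.05/45 and 0.05/23 in the
packaged worked example, i.e. thresholds 0.0011 and 0.0022). Min-p over the
set rather than the sentinel alone is validated by the packaged table: at
10q23.31 the sentinel misses the threshold (p = 1.8e-3) but its correlated
variant passes (8.2e-4), and the locus is counted. Loci discovered in both
traits are excluded from the directional scans and captured instead by the
genome-wide-both rule (some member variant with $p < 5\times10^{-8}$ in
both traits); with the packaged table this reproduces 4 + 5 + 1 = 10
pleiotropic loci. Whether the published analysis corrected per locus or per
variant is not fully specified; the per-locus reading matches the printed
thresholds and is implemented.

## Variant-set enrichment (VSE)

The locus-level mapping tally counts loci with at least one member SNP
inside at least one peak. The null distribution replaces each locus by a
random "sentinel" SNP matched on MAF (20 quantile bins over the supplied
SNP universe) and correlated-set size (within ±25%, widened once before
erroring), together with that SNP's own correlated set; 10,000 permutations
by default. The empirical p-value uses the add-one rule
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$ — it can never be zero —
and the enrichment score is the number of null SDs between the observed
tally and the null median. "Same characteristics" is not quantified in the
published method description; MAF plus set size is this package's
operationalization, and both the binning and the tally level (locus vs
SNP) are configurable.

Coordinates: BED intervals are 0-based half-open, SNP positions 1-based, so
a SNP at position $p$ lies inside $[p-1, p)$ and outside $[p, p+1)$;
conversion happens at the `GRanges` boundary and is tested explicitly.

The cell-type specificity score is max-over-peaks of per-peak
fold-enrichment times a triangular proximity kernel (bandwidth 2.5 kb,
zero beyond); the cited external method does not publish its kernel
parameters, so these are package choices, configurable.

## SMR and HEIDI

With $z$ a cis-eQTL instrument, $x$ expression and $y$ the trait,
$b_{xy} = b_{zy}/b_{zx}$ and

$$T_{\text{SMR}} = \frac{z_{zx}^2 z_{zy}^2}{z_{zx}^2 + z_{zy}^2} \sim \chi^2_1
  \quad\text{under } b_{xy} = 0.$$

HEIDI distinguishes pleiotropy (one causal variant driving both $x$ and
$y$: every SNP in LD with it estimates the *same* $b_{xy}$) from linkage
(two distinct causal variants: $b_{xy}$ varies). SNPs with eQTL
$p < 1.57\times10^{-3}$ and $r^2$ with the top SNP in $[0.05, 0.90]$ (at
most the 20 strongest) contribute differences
$d_i = b_{xy}(i) - b_{xy}(\text{top})$; their covariance follows from the
LD matrix by the delta method, and the null distribution of
$\sum_i (d_i/\mathrm{sd}_i)^2$ (a sum of correlated $\chi^2$) is evaluated
by seeded Monte Carlo with 50,000 draws rather than a saddlepoint
approximation — simpler, testable, and accurate at the 0.05 decision
boundary. Selected SNPs are put in a canonical id-sorted order first so the
result is invariant to input row order. The SMR significance threshold is
$\alpha/n_{\text{probes}}$ with $n_{\text{probes}}$ an explicit argument
(never inferred): 0.05/2000 reproduces the conventional
$2.5\times10^{-5}$.

# The synthetic world

Real consortium GWAS inputs are not redistributable, so the package ships a
generator whose defaults mirror the originating study design: two B-cell
malignancy case-control GWAS of 7717/21,587 and 4017/7881 cases/controls,
observed-scale heritabilities 0.092 and 0.22, genetic correlation 0.44.

* **Panel**: SNPs in independent LD blocks; within a block the target
  correlation is AR(1), $r_{ij} = \phi^{|i-j|}$. Each block draws its decay
  $\phi$ uniformly from $[0.3, 0.95]$ by default: heterogeneous LD across
  blocks is what real genomes look like, and the spread in LD scores it
  produces is precisely what identifies the regression (a homogeneous-decay
  panel leaves all interior SNPs with nearly equal $\ell_j$ and the
  slope/intercept barely identified). A scalar decay is accepted for
  controlled tests of the generator itself.
* **Dosages** are Gaussian-scaled with mean $2\cdot\text{MAF}$ and variance
  $2\,\text{MAF}(1-\text{MAF})$, deliberately *not* clipped to $[0,2]$:
  clipping would attenuate the realized LD below the AR(1) target that the
  generator's own tests assert. Consequence: the panel behaves like an
  imputed-dosage panel, and the EM-based $D'$ in `build_avs()` rounds
  dosages to 0/1/2 first.
* **Summary statistics** are drawn directly at the Z-score level per block:
  $z \mid \beta \sim \mathcal{N}(\sqrt{N} R \beta, R)$ with bivariate
  normal causal effects (variances $h^2_k/M$, cross-covariance
  $r_g\sqrt{h^2_1 h^2_2}/M$) and cross-trait noise correlation
  $n_{\text{overlap}}/\sqrt{N_1 N_2}$. This matches exactly the moment
  structure the estimator assumes and is orders of magnitude faster than
  individual-level simulation; the optional individual-level path is
  omitted. INFO is drawn uniform on $[0.85, 1]$ and ~8% of allele pairs
  are strand-ambiguous, so harmonization genuinely filters (~55% of SNPs
  survive the paired INFO > 0.9 filter plus ambiguity removal in both
  traits).
* **What a green test does not establish**: the generator makes no attempt
  to mimic real allele-frequency spectra, real LD beyond block-AR(1), real
  HapMap3 SNP lists, per-SNP sample-size variation, or real peak widths.
  Parameter recovery here validates the estimator's algebra and its
  uncertainty calibration under the assumed moment structure, not
  robustness to model misspecification.

## eQTL scenarios

`simulate_eqtl_locus()` plants, in a dense cis block (AR(1) decay 0.9 by
default, independent of the panel's own decay so scenarios are
reproducible): **pleiotropy** — one causal SNP drives expression and trait
with constant $b_{xy}$; **linkage** — two causal SNPs three positions
apart ($r^2 \approx 0.53$), one per outcome; **null** — expression signal
only. Instrument strength defaults ($b_{zx} = 0.3$, $n_{\text{eQTL}} =
5000$) put the analysis in the strong-instrument regime where the HEIDI
delta-method approximation is accurate; HEIDI is expected (and observed)
to be slightly conservative at nominal 0.05.

# Numerical and degenerate-input policy

* Exact HWE p-values by enumeration over heterozygote counts;
  monomorphic markers return 1 by convention. HWE is computed in controls
  only (standard practice where the convention is unstated).
* $\lambda_{1000} = 1 + (\lambda-1)(1/n_{\text{cases}} +
  1/n_{\text{controls}})/(2/1000)$, the equal-1000/1000 convention; reports
  of $\lambda_{1000}$ rarely print the rescaling formula, so the convention
  is made explicit here.
* Removal reasons in harmonization follow a fixed precedence (parse,
  inconsistent stats, indel, INFO, MAF, reference membership, reference
  MAF, strand ambiguity, allele mismatch, HLA, not-in-both) so every SNP
  has exactly one reason and reports are deterministic. The HLA exclusion
  defaults to chr6:25-34 Mb (1-based inclusive), configurable, since the
  published analyses typically say only that the region was excluded.
* $I^2$ is floored at 0 and snapped to 0 when $Q < 10^{-12}$ (numeric
  noise from exactly-concordant studies must not report 100%
  heterogeneity).
* Zero-SD VSE nulls report the score as undefined rather than dividing by
  zero; empirical p-values use add-one rules throughout and cannot be 0.
* Cross-trait fits re-check allele concordance and re-flip Z where needed
  even after harmonization (defence in depth); non-positive heritability
  makes $R_g$ a flagged result, never a silent NaN.

# Known limitations

* No liability-scale heritability conversion (out of scope by design).
* No shipped 53-category annotation model; stratified fits take
  user-supplied categories.
* The matched-null characteristics for VSE (MAF bin + set size) are a
  reasonable but not unique reading of "same characteristics"; LD-proxy
  count matching is not implemented.
* Jackknife normality is relied on for $P(R_g)$; at very small SNP counts
  per block this approximation degrades.
* The simulated world's harmonization filters act independently per trait;
  real INFO values are correlated between studies sharing an imputation
  panel.
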