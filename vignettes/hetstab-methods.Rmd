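---
title: "Models and methods behind hetstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hetstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetstab)
```

hetstab analyses the data types produced by suppressor screens of
heterochromatin instability phenotypes: pooled-bulk variant frequencies,
binned read depth, replicated feature counts, bisulfite cytosine reports,
and flow-cytometry ploidy histograms. This vignette describes each model,
its assumptions and tunable parameters, what the synthetic-data generators
emulate (and do not), and the numerical and design choices that were
genuinely open.

## Coordinate and data conventions

All interval arithmetic is 0-based half-open internally. Formats keep their
native conventions on disk: VCF-minimal and cytosine reports are 1-based,
BED-like tracks 0-based half-open, GFF3 1-based inclusive. Converting a
1-based inclusive column to the internal frame uses `start = pos - 1`.
Every reader/writer pair round-trips valid files bit-identically, and every
stage runner is a pure function of `(config, seed)`, so reruns are
byte-identical — the property the determinism tests assert.

## Bulked-segregant mapping model

The bulk is modelled as an F2-type pool selected for a recessive phenotype
at a single causal lesion: each of the `2n` chromosomes of the pool is an
independent gamete carrying the causal allele, so a variant at map distance
`d` Morgans is co-inherited with probability `1 - c(d)` under the Haldane
map function `c(d) = (1 - exp(-2d))/2`; variants on other chromosomes
segregate at expected frequency 0.5. Whether real screen bulks are M2 or
backcross-F2 pools is rarely knowable from the data; the F2 model is the
standard bulked-segregant assumption and is the generator's
(config-switchable) default. Recombination is uniform at `r = 0.04`
Morgan/Mb, a typical plant genome-wide average.

Per-site enrichment testing uses the minimal model consistent with pooled
mismatch data: a one-sided binomial tail `P[X >= alt | depth, eps]` against
the sequencing error rate `eps` (default 0.005/read), BH-corrected across
sites at `alpha = 0.05`. An EMS-signature filter (G>A / C>T, the
transitions EMS chemistry produces) is on by default and can be disabled
for non-EMS screens. The frequency profile averages the mismatch fraction
of enriched sites in sliding windows (100 kb window, window/5 step at the
miniature-genome scale; 500 kb at real-genome scale).

The candidate interval is the longest run of windows with smoothed
mismatch fraction at or above `tau = 0.9`, ties broken by higher mean and
then leftmost position. One design point was genuinely open: what a
variant-free (masked) window does to a run. We skip masked windows rather
than breaking runs on them, because an empty window carries no evidence
against linkage — at realistic planted-site densities (~1.2 enriched sites
per 100 kb window) roughly 30% of windows are empty, and breaking runs on
them fragments the causal chromosome into arbitrary pieces. Runs are still
broken by *observed* windows below `tau` and by chromosome boundaries. A
profile with no window above `tau` yields a zero-row "no interval" result,
not an error.

Effect classification is deliberately minimal: SNVs only, one isoform per
gene (the longest CDS when a GFF3 has several), strand-aware codon lookup
from the spliced CDS, `splice_site` for intronic positions within 2 bp of a
junction. Positions with no coding or intronic consequence — UTR exons,
non-coding TE bodies, true intergenic space — are all reported as
`intergenic`, keeping the class set closed.

## Copy-number ratio tracks and pericentromeric enrichment

The ratio track is `log2((m_i/M + kappa)/(c_i/C + kappa))` with library
totals `M`, `C` and a pseudo-rate `kappa` defaulting to one read in the
smaller library, which stabilises empty bins. Bins whose control count
falls below `floor = 10` are masked, mirroring the low-coverage gaps left
blank in chromosomal views. Bin size is 10 kb on the miniature genome
(100 kb is the analogous real-genome choice); no smoothing is applied.

The enrichment score `S` is the difference of mean log2 ratios between
pericentromeric and arm bins (bins classified by midpoint). Significance
is a one-sided permutation test — the phenotype is specifically a *gain* —
shuffling bin class labels with `p = (b + 1)/(n_perm + 1)`. `S` is exactly
invariant under joint library rescaling at fixed `kappa`; with the default
data-dependent `kappa` the invariance is to within the one-read pseudo-rate.
Note the permutation p is exact, so on truly flat genomes `P(p <= 0.05)` is
5% by construction; the package's null tests therefore budget for exactly
that failure rate at its binomial sampling noise rather than asserting a
pointwise bound.

## Up-regulation calling

The test is specified entirely by formulas rather than by delegating to an
external DE package. Counts are normalized with median-of-ratios size
factors. Per feature, a moment estimate of the negative-binomial dispersion
comes from the pooled within-group variance of normalized counts with the
shot-noise term removed:
`phi_hat = (var_w - mu_bar * mean(1/s_j)) / mu_bar^2`. Three standard
refinements make this usable at 2+2 replicates, where a raw moment estimate
has only 2 degrees of freedom:

1. the genome-wide centre is the median of `phi_hat` corrected for the
   chi-square median bias (`/ (qchisq(0.5, df)/df)`), since the median of a
   2-df estimate underestimates the centre by ~30%;
2. per-feature estimates are shrunk toward that centre with a prior df
   estimated by trigamma matching — the spread of `log(phi_hat)` in excess
   of the chi-square sampling variance determines how much true
   feature-to-feature dispersion variation exists (none in excess means
   shrink hard; the prior df is capped at 50, floored at 4);
3. the result is floored at `phi_min = 0.01`.

The test statistic is a one-sided Wald z on the log fold change of
normalized group means (pseudo-count 1), with the delta-method variance
evaluated at the pooled null mean:
`Var(log mu_g) = [sum_j (mu0/s_j + phi mu0^2)/n_g^2] / (mu0 + 1)^2`.
Working on the log scale matters: at these replicate numbers a linear-scale
difference test with a null-pooled variance loses roughly 0.5 sigma of
standardized effect for a 4-fold change. Before BH correction the features
are screened by independent filtering on the base mean (the cutoff, over a
coarse quantile grid, that maximizes rejections) — the filter statistic is
independent of the test statistic under the null, so FDR control is
preserved. A feature is called up-regulated when `q <= 0.05`, its LFC is at
least `log2(2)`, and its mean mutant RPKM is at least 1. Calls are
one-sided by construction: the biology of interest is derepression.

## DMR discovery

Per context (CG/CHG/CHH analysed independently throughout), the genome is
cut into fixed non-overlapping 100 bp windows. Within a window, reads of
cytosines with at least `cov_min = 4` reads are pooled per sample and the
two samples compared with a Fisher exact test; windows need `n_min = 4`
covered cytosines in both samples. The Fisher p is two-sided
(minimum-likelihood rule, the `fisher.test` convention): a two-sided test
is what makes DMR calls symmetric — swapping the input samples flips
hyper/hypo labels but preserves intervals and p-values exactly. BH runs per
context at `alpha = 0.01`; passing windows additionally need
`|delta| >= 0.4 / 0.2 / 0.1` for CG/CHG/CHH, and adjacent passing windows
within `gap_max = 200` bp merge. Merged regions report pooled levels, a
Fisher p recomputed on the merged counts, and the smallest
constituent-window q.

Two numerical points: methylation levels are always coverage-weighted
(`sum meth / sum total`), never means of per-site ratios, so a 1/1 site
cannot outvote a 0/99 site; and the window scan computes exact Fisher
p-values only for windows whose one-sided hypergeometric tail bound could
possibly reach significance — the bound is a guaranteed lower bound on the
two-sided p, and p-values above the BH level cannot change the rejection
set, so the screen is exact, not approximate.

## Ploidy-peak mixture

Nuclei intensities are modelled as a K-component Gaussian mixture with
means tied exactly to doubling peaks `mu * 2^k` (2C, 4C, 8C, 16C for
K = 4): a single free `mu`, free weights, free per-peak standard
deviations. Strict mean-tying is what keeps the fit identifiable when a
peak is strongly broadened — with free means a broad 16C component can
drift and absorb 8C mass. The per-peak coefficient of variation
`CV_k = sigma_k / (mu * 2^k)` is the extra-DNA readout; comparing `CV_3`
between two samples (difference and ratio) quantifies 16C broadening.

Fitting is EM on the binned data (bin midpoints weighted by counts) with a
conditional M-step — `mu` given current sigmas, then sigmas given the new
`mu` — which keeps the log-likelihood non-decreasing (asserted on every fit
in the tests). Initialization: `mu0` is the modal bin midpoint within the
lowest-intensity quartile (the 2C peak dominates there), `sigma_k` starts
at 5% of each peak mean, weights uniform. Convergence is a relative
log-likelihood change below `1e-8`, at most 500 iterations; non-convergence
raises a classed error that carries the best-so-far fit. Standard
deviations are floored at a quarter bin width to prevent component
collapse. The fit is scale-equivariant: rescaling intensities rescales `mu`
and `sigma_k` and leaves every CV unchanged. FCS parsing is out of scope —
flow data enter as exported histograms. For ungated histograms an optional
uniform background component over the intensity range
(`background = TRUE`, off by default) absorbs debris/sub-2C events without
disturbing the peak CVs.

## The synthetic-data generators, and what passing tests mean

The generators plant machine-readable ground truth for every modality over
a miniature genome of five 1 Mb chromosomes with central 200 kb
pericentromeric intervals — the five-chromosome organisation of the
Arabidopsis genome at one-hundredth scale, sized so whole-pipeline studies
run in seconds to minutes. Study-condition defaults: 60 EMS sites with a
bulk of n = 50 plants at 30x depth and error 0.005; 3,000 features of which
100 are up-regulated at fold change 4, negative-binomial dispersion 0.1,
two replicates per group; Poisson bin depth lambda = 200 with
pericentromeric gain g = 2; ten 300 bp CG DMRs at delta = -0.5 from a CG
base level of 0.8 (CHG 0.3, CHH 0.1); flow peaks at mu = 50 a.u. with CV
5%, 20,000 nuclei, and 16C broadening beta = 1.6.

Where a condition was not externally fixed we chose once, for realism, and
froze it: baseline expression means are log-normal (meanlog `log(100)`,
sdlog 1.2), a typical RNA-seq dynamic range; cytosine spacings are 15/20/15
bp for CG/CHG/CHH, matching motif densities at ~36% GC with both strands
reported (real CHH is denser; it is thinned to keep desk-scale runs fast,
which only makes CHH calls harder, not easier); bisulfite coverage is
Poisson with mean 15; monitoring (non-variant) sites number 200.

The generators emulate the statistical structure of the assays, not their
artefacts. Real data add mappability and GC biases, repeat-driven
multi-mapping (most acute exactly in pericentromeric heterochromatin),
bisulfite conversion failure, PCR duplicates, S-phase and debris events in
flow histograms, ecotype-level genetic background differences, and
parental SNPs that survive background subtraction. Passing the planted-truth
tests therefore demonstrates that the estimators recover what they claim
under their own assumptions at realistic signal-to-noise — it does not
certify performance on any particular real dataset. Quantities that depend
on deposited reads and unstated upstream thresholds (absolute counts of
derepressed TEs or DMRs in specific mutants, for instance) are explicitly
not reproduction targets.

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` run: 20 mapping screens plus 100
no-selection nulls; oracle sweeps over all binomial instances with depth
<= 60, random BH vectors of length 500, and Fisher tables with totals
<= 60; 20 expression runs plus 8 nulls; 20 methylome runs plus 5 nulls; 20
copy-number runs at g = 2, 100 flat-genome nulls, and a gain ladder
g in {1, 1.5, 2, 3}; 20 flow pairs plus a broadening ladder
beta in {1, 1.3, 1.6, 2}; and two full byte-identity pipeline reruns on a
reduced genome. These sizes are the package's own choice of a desk-scale
study; recovery rates are stable at them (Monte-Carlo error on seed
averages is small relative to the margins asserted).

## Known limitations

- The mapping model assumes a single recessive causal locus and uniform
  recombination; dominant suppressors, multi-locus interactions, and
  recombination cold spots (pericentromeres, notably) are not modelled.
- Subtraction of variants present in an unselected sibling pool
  (`subtract_background()`) is available but off by default, since screens
  do not always sequence the unselected bulk; without it, background EMS
  load on the causal chromosome can widen intervals slightly.
- The DE caller tests a two-group, replicated design only — no batch
  covariates, no isoform resolution.
- DMR calling uses fixed windows, not cytosine-level segmentation, and no
  ecotype correction: comparisons across genetic backgrounds will report
  background DMRs as real (they are real, just not treatment effects).
- The ploidy mixture has no explicit S-phase model; the optional uniform
  background absorbs debris but not the inter-peak bridge that heavy
  S-phase populations create.
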