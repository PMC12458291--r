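---
title: "Methods: windowed divergence, PBS and CNV scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence, PBS and CNV scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, estimator conventions and
design choices behind `divergescan`, in the spirit of a methods appendix:
what is computed, under which assumptions, and where the genuinely open
decisions were resolved.

## The measurement problem

In very recently diverged populations ("ecotypes", incipient species),
genome-wide differentiation is weak — mean F\_ST of a few percent — and
biologically interesting signal is confined to narrow windows. Three
estimator pathologies dominate at this scale:

1. **Denominator bias in π and d\_XY.** Computing per-site diversity only
   over variant records inflates π wherever variant density varies.
   We therefore require *all-sites* input (variant plus invariant
   records) and compute π and d\_XY as ratios of sums: per-site
   pairwise-difference counts over per-site pairwise-comparison counts.
   A site with n0 REF and n1 ALT called copies (k = n0 + n1) contributes
   n0·n1 differing pairs out of k(k−1)/2 within a population, and
   n\_A0·n\_B1 + n\_A1·n\_B0 out of k\_A·k\_B between populations.
   Missing genotypes simply shrink the counts; an all-missing site
   contributes (0, 0). Window values are Σdiff/Σcomp, never means of
   per-site ratios.

2. **Negative-variance noise in F\_ST.** We use the Weir & Cockerham
   (1984) variance components a (among populations), b (among
   individuals within populations) and c (within individuals), computed
   per site from sample sizes, allele frequencies and observed
   heterozygosities, and aggregate per window as Σa / Σ(a+b+c) over
   variant sites. Window values below 0 are set to 0 (the raw value is
   retained in `fst_raw` for auditability); values are likewise capped
   at 1. Sites where either population has no called individuals are
   excluded from the F\_ST sums but still feed the other population's π.

3. **Ploidy on the Y.** Y analyses use male samples only; diploid calls
   are haploidized (heterozygotes → missing, homozygotes collapsed).
   Running the diploid F\_ST estimator on pseudo-diploid Y calls would
   count phantom within-individual components, so haploid data use the
   haploid reduction of the estimator: a one-level ANOVA of allele
   frequencies with the finite-sample correction n\_c, where b carries
   the within-population mean square and c ≡ 0. The windowed ratio
   Σa/Σ(a+b+c) is unchanged in form.

## Windows, summaries, partitions

Windows tile each chromosome from coordinate 0 in 50 kb steps (0-based
half-open; a 1-based site p maps to window ⌊(p−1)/50000⌋). The terminal
window per chromosome is flagged partial and retained. Genome-wide means
weight windows equally; a statistic whose window denominator is zero is
*missing*, never zero.

Confidence intervals are percentile bootstrap over windows: the window is
the resampling unit because the genome-wide quantity is a mean over
windows, and spatial correlation within windows is then preserved inside
the resampling unit. 10,000 replicates, 2.5/97.5 percentiles, half-width
(hi−lo)/2 for "mean ±" presentation. We chose the percentile method over
BCa because the reported quantity is a symmetric "±" band.

The X-chromosome pseudoautosomal region (PAR) is summarized separately
from the rest of the X: a window is PAR if its midpoint falls inside the
PAR interval. The Y:autosome diversity ratio π(Y)/π(A) is reported both
raw and truncated (floored) to two decimals for display; truncation is
the package's display convention for this ratio, and the raw value is
always carried alongside. Under neutrality with equal sex ratios the
expectation is 1/4.

## The PBS scan

Pairwise windowed F\_ST among the focal population and two references is
transformed to branch lengths T = −ln(1 − F\_ST) — natural log, the
convention of the PBS literature — and the focal branch is
PBS = ((T\_AB + T\_AC) − T\_BC)/2. Clamping order matters and is fixed:
F\_ST is clamped to [0, 1] *before* the log transform; PBS is clamped at
0 *after*. F\_ST = 1 is capped at 1 − 10⁻⁶ (flagged) so arithmetic stays
finite. Outliers are windows strictly above the empirical 0.99 quantile
(R's type-7 linear interpolation), computed genome-wide per analysis;
autosomes, X and Y are filtered and scanned separately, so each gets its
own threshold. A per-chromosome threshold is a caller option.

The pairwise F\_ST tracks feeding PBS reuse the ratio-of-sums windowed
estimator above. Field pipelines sometimes produce per-window F\_ST as a
mean of per-site ratios instead; that convention weights low-information
sites more heavily and is noisier, so ratio-of-sums is the default here.

## CNV differentiation

Each CNV is a biallelic locus whose ALT allele is "carrier"; per-locus
F\_ST is the same Weir–Cockerham ratio on dosage-coded genotypes (the
code path is shared with the SNP estimator, which the tests exploit as an
exact equivalence check). Copy-number differentiation uses
V\_ST = (V\_T − V\_S)/V\_T with V\_T the pooled variance and V\_S the
size-weighted mean within-population variance. V\_ST is undefined when
V\_T = 0 or any population has fewer than two called samples; negative
values are reported as-is — clamping is a convention for F\_ST and PBS,
and V\_ST's negative excursions are informative about within-population
noise.

Cross-validation retains a primary call iff a secondary call of the same
svtype overlaps it with intersection strictly greater than 50% of the
*primary* call's length. The overlap fraction is referenced to the
primary callset because the validation question is asymmetric — "is this
primary call supported?" — and retention is then naturally reported as a
fraction of the primary set; a `reciprocal = TRUE` mode applies the
fraction both ways for users who want the stricter symmetric rule.
DEL and DUP are analyzed jointly in F\_ST/V\_ST but never cross-matched
in validation (a type mismatch is a discordant call, not support).
Inversions are parsed but excluded from downstream statistics by default.

## PCA and demographic model comparison

Genotype PCA follows the standard recipe: ALT dosage per site (0/1/2
diploid, 0/1 haploid), missing dosages imputed with the site mean,
columns centered and scaled by √(p(1−p)), eigendecomposition of the
sample covariance. Mean imputation is deliberate: it reproduces the
well-known behavior of high-missingness samples collapsing toward the
origin, which practitioners must recognize rather than have hidden.
Components are sign-fixed so the largest-magnitude coordinate is
positive; percent variance is the eigenvalue share of the positive
spectrum.

Model comparison consumes a table of demographic fits (log-likelihood,
free-parameter count k, diffusion-unit parameters); AIC = 2k − 2LL,
ranked ascending with ties broken toward fewer parameters. For the three
bundled two-population fits, k is 7 (isolation-with-migration: s, ν1, ν2,
m12, m21, T, misid), 4 (strict isolation) and 6 (ancient symmetric
migration), the counts consistent with each model's populated parameters.
Scaling to natural units uses the diffusion conventions θ = 4 N\_anc μ L,
sizes ν\_i N\_anc, time unit 2 N\_anc generations, migration
m/(2 N\_anc) per generation; μ, generation time and callable length L
are required inputs with no defaults, since no single choice is
defensible across systems. The bundled analysis resolves μ·L per model
from θ and the fitted N\_anc, which makes the scaled parameters
internally consistent by construction. Likelihood optimization itself is
out of scope: fits are inputs.

## The simulator: what it emulates, and what it does not

`simulate_split_populations()` draws, per polymorphic site, an ancestral
frequency p ~ Uniform(0.05, 0.95) and per-population frequencies from the
Balding–Nichols Beta with mean p and variance F·p(1−p); diploid genotypes
are binomial; invariant sites are emitted as all-reference records;
missingness is i.i.d. per genotype. F = 0 is handled as a point mass at p
(the Beta parameterization degenerates). The uniform ancestral
distribution is a deliberate simplification — it keeps allele-frequency
filters non-degenerate and makes E[F\_ST] ≈ F so estimator recovery is
checkable, but it is *not* a realistic site-frequency spectrum. The
sex-chromosome generator implements the PAR's elevated diversity by
scaling the polymorphic-site fraction inside the PAR (expected π is
linear in that fraction; scaling per-site heterozygosity alone cannot
exceed 2×, and the empirically interesting contrast is ~3.5×). The CNV
generator emits both callsets from the same latent loci with uniform
endpoint jitter and spurious calls whose lengths are resampled from true
calls (preserving the length distribution that overlap validation is
sensitive to); copy numbers are 2 ± carrier dosage, which couples the
F\_ST and V\_ST axes the way a real shared signal would.

Not emulated: linkage disequilibrium and recombination maps (windows are
i.i.d. across sites given frequencies), coalescent genealogies, selection
at simulated loci, realistic SFS shape, and non-random missingness.
Passing recovery tests on this generator therefore validates the
*estimators and plumbing*, not robustness to LD-induced window
correlation or to structured missingness in real resequencing data.

All randomness flows from an explicit per-call seed (`withr::with_seed`),
so identical parameters and seed are bit-identical; no function touches
the global RNG state.

## Problem sizes and numerical conventions

The bundled analyses and tests use desk-scale problem sizes chosen so
the full suite runs in well under a minute of simulation per stage:
20 diploids per population and 10,000–25,000 sites for estimator
recovery (the scale at which the windowed F\_ST estimate stabilizes to
±0.02 of the simulated F), 500 windows of 50 kb for the PBS scan, and
~120 CNV loci for the callset analyses. Exact-agreement tests (π/d\_XY
against O(n²) pair enumeration, V\_ST against brute-force variance
decomposition, W–C components against a textbook transcription) run on
small instances where the oracle is affordable and assert identity to
1e-10–1e-12; behavioral tests on stochastic quantities assert the bands
stated above. Degenerate inputs are contractually defined: empty windows
are missing (never 0), constant vectors yield empty outlier sets, a
degenerate bootstrap collapses to a point CI, and V\_ST without total
variance is undefined.

## Known limitations

- Window-level bootstrap CIs ignore correlation *between* adjacent
  windows; with real LD they will be slightly anticonservative.
- The haploid F\_ST reduction is the defensible equivalent of, not
  identical to, running diploid tooling on haploidized calls; both are
  estimator conventions and differ in finite samples.
- Equal window weighting in genome-wide means is one of two defensible
  conventions; site-count weighting changes means when window coverage
  is very uneven (a caller-side choice on the returned tables).
- The simulator's independence across sites makes quantile thresholds
  sharper than on real, autocorrelated genomes; outlier recall numbers
  on synthetic data are upper bounds.
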