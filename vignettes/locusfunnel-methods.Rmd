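---
title: "locusfunnel: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{locusfunnel: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusfunnel)
```

`locusfunnel` chains the statistical steps that take a GWAS risk locus to
a candidate functional variant and target-gene mechanism. This vignette
is the package's own account of each model, the parameters that matter,
the numerical choices behind the implementations, and what the synthetic
data do and do not establish.

## Meta-analysis of study-level odds ratios

Study summaries arrive as odds ratios with 95% confidence intervals. On
the log scale the interval is symmetric, so the standard error is
recovered as $se = (\ln \mathrm{CI_{hi}} - \ln \mathrm{CI_{lo}})/(2 z)$
with $z = \Phi^{-1}(0.975) \approx 1.959964$; `se_from_ci()` and
`ci_from_beta()` are exact inverses, which the tests assert to $10^{-12}$.
`ivw_fixed_meta()` is the classical fixed-effect inverse-variance scheme
on log-odds (the "standard-error" weighting of the common GWAS
meta-analysis tools). Cochran's $Q$ is computed but only reported:
with two or three large studies a heterogeneity test is too weak to act
on, and the funnel's downstream steps assume a single shared effect.
`allelic_or_from_maf()` rebuilds the 2×2 allele table from printed
minor-allele frequencies; counts are rounded half-up to integers because
published MAFs carry two decimals and the rounding error (< 0.5 allele)
is far below the interval width. A zero cell triggers the
Haldane–Anscombe 0.5 correction and a flag rather than an error.

Crude allelic ORs reconstructed this way differ slightly from published
covariate-adjusted logistic estimates (1.465 vs 1.45 for the replication
cohort bundled in `extdata`); the ~1% gap is the price of not having
individual-level covariates and is well inside the published interval.

## Fine-mapping

**Likelihood ratios.** For a 1-df Wald/score statistic the relative
likelihood of variant $i$'s association model against the tag's is
$\mathrm{LLR}_i = \exp((\chi^2_{tag} - \chi^2_i)/2)$, with
$\chi^2 = [\Phi^{-1}(1 - p/2)]^2$ recovered from the reported p-value.
The quantile is evaluated on the log scale (`qnorm(log(p) - log(2),
log.p = TRUE)`), which keeps the relative error below $10^{-6}$ down to
$p = 10^{-300}$; inverting the complementary chi-squared CDF directly in
double precision loses the tail long before the $10^{-14}$ p-values that
occur in practice. The "1:100" rule is interpreted as
$\mathrm{LLR} \le 100$ together with LD $r^2 > 0.8$ (strict) to the tag,
which matches the convention that published candidate lists with LLR
values between 1 and ~12 all pass.

**Credible sets.** `susie_fit()` implements the additive
sum-of-single-effects model with iterative Bayesian stepwise selection.
Each of $L = 10$ effects is a single-effect regression on the
residualized phenotype; per-variant Bayes factors are Wakefield-style,
$BF_j = \sqrt{s_j^2/(s_j^2+\sigma_0^2)}\,
\exp\!\big(\tfrac{z_j^2}{2}\,\sigma_0^2/(s_j^2+\sigma_0^2)\big)$, and the
per-effect prior variance $\sigma_0^2$ is chosen per iteration by
maximizing the single-effect marginal likelihood over the grid
$\{0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5, 1\} \times \mathrm{var}(y)$
(the source method leaves the prior unstated; a grid maximization is the
conventional default). The residual variance is re-estimated from the
fit each sweep. Convergence is declared when no inclusion probability
moves by more than `tol = 1e-3`; non-convergence at `max_iter` is
reported, not hidden. A case-control 0/1 phenotype is treated as
Gaussian — the standard working-model choice for this family, adequate
for balanced designs at GWAS effect sizes.

A level-0.9 credible set is the smallest prefix of an effect's sorted
inclusion vector reaching 0.9 mass, reported only when its purity
(minimum pairwise absolute dosage correlation) is at least 0.5, the
reference default for this model class; duplicate sets across effects
are collapsed. Under a null phenotype the inclusion vectors stay diffuse
and fail purity, so no sets are reported — the tests check this across
seeds, and the acceptance suite measures empirical coverage of the
planted causal variant across 200 simulated blocks against the
advertised 0.9.

## Allele-differential motif scoring

`pfm_to_pwm()` turns count matrices into log-odds scores with a
Dirichlet-style pseudocount of 1 spread according to the background.
Scores are *quantized at construction* to a per-matrix resolution
$\delta$ = (largest per-position score range)/10000. Everything
downstream — window scoring and the score-distribution dynamic program —
operates on the same quantized matrix, so the DP tail probability is
exact for the matrix as stored (the tests verify equality with
exhaustive enumeration over all $4^L$ sequences at $L \le 8$ to
$10^{-9}$), and the only approximation is the initial quantization,
bounded by $L\delta/2 \approx L/20000$ of a score unit and reported as a
p-value bracket in the `error_bound` attribute. This design replaces an
undocumented internal discretization in the reference motif tool with
one whose error is explicit.

`snp_best_hit()` scans every window of the motif length that overlaps
the SNP on both strands (minus-strand hits via the reverse-complement
matrix, reported in plus-strand coordinates; 1-based closed windows) and
returns the hit minimizing the background p-value. Allele comparison is
the fold change $\max(p_1,p_2)/\min(p_1,p_2)$ with the stronger allele
carried separately; published allele-preference tables list the weaker
allele first, consistent with this definition. One published fold change
(FOSB) is ~10× the ratio of its own printed p-values — presumably a
typographical slip — and is excluded from tests.

## Colocalization

`coloc_posteriors()` is the standard enumeration over single-causal
configurations: per-variant Wakefield log approximate Bayes factors for
each trait, summed with log-sum-exp into the five hypothesis likelihoods,
with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and effect-prior
standard deviations 0.2 (case-control) and 0.15 (quantitative), the
defaults of the tool family the analysis emulates. Harmonization is an
inner join on variant id; when both tables carry alleles, swapped
records have their effect sign flipped and strand flips are resolved,
but palindromic (A/T, C/G) mismatches are dropped with a warning — their
orientation cannot be determined from summary data. One caveat
discovered in testing: the posteriors are *not* invariant to adding a
constant to one trait's log Bayes factors (that rescales H1/H3/H4
against H0/H2); what is invariant is the H4:H3 odds, and that is the
property the tests pin down against a direct enumeration oracle.

## IP-MS substrate triage

The enrichment statistic follows the spectral-count recipe literally: a
pseudo-count of 1 on every PSM count, per-condition medians, fold change
as the ratio of medians, and an unpaired two-tailed equal-variance
t-test on the +1 counts without log transform. The t-test on counts is a
deliberate approximation (the source protocol's own), and the
synthetic-data module keeps it honest by generating truly Poisson
counts. Degenerate rows (all counts identical) return $p = 1$; two
constant but different groups return $p = 0$ rather than an error. The
filter is strict at both thresholds, so a protein at exactly 1.5-fold is
excluded. Dose-dependence is operationalized as a least-squares slope of
per-dose mean abundance on $\log_{10}(\mathrm{dose})$ with one-sided
$p < 0.05$; an endpoint lowest-vs-highest-dose t-test is reported
alongside but does not gate the verdict, mirroring how dose-response
evidence is usually summarized. Pseudo-count dilution means the fold
change is not exactly scale-free at low counts (the ratio
$(10m+1)/(m+1)$ drifts); at medians ≥ 10 the ×10-scaling drift is
provably under 10%, which is what the tests assert.

## In-silico knockdown

Genes with zero counts in more than 20% of samples are dropped (strict
inequality, so a gene at exactly 20% survives). TMM normalization is
delegated to edgeR's implementation of the trimmed-mean-of-M-values
estimator (30%/5% trims) behind `tmm_factors()`, with factors rescaled
to zero log-mean. Quartile splitting takes the `floor(N/4)` samples at
each extreme of normalized driver-gene expression with stable
tie-breaking, so 328 samples give the published 82 per arm.

The exact test is re-implemented from its published description rather
than called from edgeR, so that the scheme itself is inspectable:
counts are mapped to a common (geometric-mean) library size by a mid-p
quantile-to-quantile negative-binomial transformation; the common
dispersion maximizes the conditional log-likelihood of the adjusted
counts (golden-section search over $\log \phi \in [\log 10^{-4},
\log 10]$, with one re-adjustment round); and each gene receives a
two-sided conditional exact test on its group sums, the p-value being
the total probability of outcomes no more likely than the observed
split. The quantile mapping returns integer pseudo-counts (the NB
quantile function is integer-valued), a simplification relative to the
reference's interpolated pseudo-counts; the acceptance suite therefore
checks what matters statistically — type-I error within [0.03, 0.07] at
nominal 0.05 over 2000 null genes — and a test cross-checks p-value
ordering and dispersion against the reference implementation on a small
fixture. Fold changes use group-mean pseudo-counts with a 0.125 prior
count, oriented "low over high" so positive log2FC means higher
expression when the driver is low.

Preranked GSEA uses the classic weighted Kolmogorov–Smirnov running sum
(weight exponent 1 on |log2FC|), a gene-label permutation null
(equivalently random sets of the same size) under a mandatory seed,
$NES = ES/\mathrm{mean}(|ES_{null}|\ \text{same sign})$, add-one-smoothed
same-sign permutation p-values, and the positive/negative pooled-null
FDR convention. Set-size bounds are [5, 500] after intersection with
the ranked universe; undersized sets are skipped and listed. The
enrichment-score kernel is cross-checked against the reference fast
implementation to $10^{-9}$.

## Assay quantification

Standard curves regress Ct on $\log_{10}$ quantity; the efficiency is
$E = 10^{-1/\mathrm{slope}} - 1$, so a slope of $-3.3219$ is perfect
doubling. A non-negative slope marks the curve invalid, and quantitation
refuses invalid curves. Percent input passes both IP and input Cts
through the curve and corrects the input for its dilution factor — no
ΔΔCt shortcut anywhere, since curve-based quantitation is what the
underlying protocol specifies. Allelic enrichment uses means of
per-replicate A/G ratios (not the ratio of means) because significance
is tested on the per-replicate ratios; swapping allele labels inverts
ratios as expected. Luciferase folds are per-well firefly/Renilla
normalized to the mean empty-vector ratio; growth curves normalize to
the first (0 h) timepoint.

## The synthetic-data module

All generators are pure functions of a configuration and one integer
seed; per-stage streams are derived from the seed by fixed offsets
(genotypes +0, phenotype +1000, eQTL +2000, PSM +3000, RNA-seq +4000,
qPCR +5000, GSEA +6000, assay +7000), so a fixed seed reproduces every
byte of output, which the tests and the pipeline's report check.

*Genotypes.* Haplotypes are a first-order Markov chain of allele
indicators whose transition probabilities are linear in the previous
allele, giving adjacent-pair correlation exactly `ld_decay` and hence
geometric decay $\rho^k$ at distance $k$ — a closed form the LD code can
be tested against. Allele frequencies drift along the block as a bounded
random walk (step SD 0.02 within `maf_range`), with steps constrained to
keep the transition probabilities feasible; unconstrained frequency
jumps would force probability clipping and silently attenuate the decay.
This is a copula convenience, not coalescent realism: no recombination
hotspots, no rare variants, no population structure.

*Phenotypes and summaries.* Case-control status follows a logistic model
on the standardized causal dosage; per-variant statistics are
single-variant score tests (exact first-order inference, no iterative
fitting, hence no separation failures — quasi-separated variants are
flagged). Quantitative (eQTL-style) traits use per-variant least squares.
Null configurations give uniform p-values, which the tests verify by
Kolmogorov–Smirnov.

*Spectral counts.* PSM counts are Poisson (matching the low-count
character of spectral data, and deliberately *not* matching the t-test's
normality assumption). Background rates are Gamma-distributed with mean
2; planted substrates get a baseline floored at twice that mean and a
4-fold bait enrichment. The floor encodes that reported substrates are
reliably detected proteins; without it a sizeable fraction of planted
substrates would sit at 0–1 counts and be statistically invisible to the
n = 3 vs 4 t-test, so recovery properties would measure the generator's
tail rather than the triage procedure. Dose–response tables halve
substrate abundance per decade of inducer with 10% log-normal noise.

*RNA-seq.* Negative-binomial counts with log-normal mean abundances,
common dispersion 0.1, and a latent per-sample driver activity
$a \sim N(0,1)$; the driver gene scales as $2^a$ (about a two-fold
contrast between extreme quartiles, typical of a modest-variance
regulator in bulk tissue) and planted-set genes as
$2^{\mathrm{effect} \cdot a/2.54}$, where 2.54 is the expected
standardized gap between extreme-quartile means of a standard normal —
so the realized bottom-vs-top contrast equals the stated `log2_effect`.
Bulk-tissue confounders (cell-type composition, batch) are not
simulated, so passing tests demonstrate correctness of the procedure,
not robustness to tissue heterogeneity.

*qPCR.* Ct values follow the standard-curve model with configurable
efficiency (valid range (0.7, 1.1]) and Gaussian noise, so curve fitting
can be checked against the exact generating parameters.

## Pipeline and problem sizes

`run_pipeline()` executes the stages in dependency order; a failing
stage is recorded and its dependents are skipped, partial stage lists
run partial pipelines, and unknown configuration keys are rejected by
name. Thresholds default to the documented funnel values (LLR 100,
r² 0.8, coverage 0.9, L 10, enrichment fold 1.5 and p 0.05, FDR 0.05,
|log2FC| 0.5). The default demo locus is 2000 individuals × 50 variants
with a 2000-gene × 328-sample expression matrix; the test suite runs the
same stages at 500–800 individuals, 20–50 variants, and a few hundred
genes, and the calibration studies use 100–200 replicate blocks, 2000
null genes, and 25–50 proteomics seeds — sizes chosen so every property
is measured with useful precision while the whole suite remains quick on
a laptop.

## Known limitations

- Fine-mapping operates on individual-level synthetic genotypes; fitting
  from summary statistics with an external LD reference panel is out of
  scope, as are multi-ancestry analysis and annotation priors.
- Colocalization assumes at most one causal variant per trait in the
  region; multi-causal extensions are not implemented.
- The NB exact test uses integer pseudo-counts and a common dispersion;
  tagwise shrinkage and GLM-based designs are out of scope.
- The motif model is mononucleotide with a fixed background; dinucleotide
  backgrounds and thermodynamic affinity models are not attempted.
- Percent-input and allelic-ratio quantification assume the reported
  technical design (curve per primer set, replicate ratios); melt-curve
  QC and image-based readouts are not modeled.
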