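---
title: "Methods: proteome-wide MR for drug-target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR for drug-target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmr)
```

## The causal model

Two-sample Mendelian randomization treats a genetic variant as an
instrumental variable for an exposure. If variant $g$ is associated with
circulating protein level $X$ (effect $\beta_{gx}$, from a pQTL study) and
with disease $Y$ (effect $\beta_{gy}$, from an independent case-control
GWAS), and $g$ affects $Y$ only through $X$, then the causal effect of one
SD of protein on disease log-odds is identified by the Wald ratio

$$\hat\theta = \beta_{gy} / \beta_{gx}, \qquad
  \mathrm{se}(\hat\theta) = \mathrm{se}(\beta_{gy}) / |\beta_{gx}|,$$

the first-order delta-method standard error. With $k \ge 2$ independent
instruments the fixed-effect inverse-variance-weighted (IVW) estimate pools
the per-variant ratios $\hat\theta_j$ with weights $w_j = 1/\mathrm{se}_j^2$:
$\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$,
$\mathrm{se} = (\sum_j w_j)^{-1/2}$. Cis-acting instruments carry 1–2
variants per protein after clumping, so the fixed-effect model is the
operative one; a multiplicative random-effects standard error is available
(`mr_ivw(random_effects = TRUE)`) but off by default, as heterogeneity
cannot be estimated meaningfully from so few ratios. Two-sided p-values use
the standard normal; whether a t reference would be more faithful is
unknowable from summary data and immaterial at these sample sizes. The 95%
CI multiplier is fixed at 1.959964 so that printed ORs round identically
across platforms.

Restricting to cis instruments (within `cis_radius` of the gene anchor,
default 1 Mb, closed interval, 1-based coordinates) is the key pleiotropy
defense: a variant in the protein's own gene region most plausibly affects
the disease through that protein. Trans instruments are deliberately
unsupported. The anchor and window are configurable because conventions
differ (TSS vs gene body; 500 kb–1 Mb).

## Instrument selection

Candidates must pass, in order: cis restriction, genome-wide significance
(p < 5×10⁻⁸, strict), greedy LD clumping, and the weak-instrument filter.
Clumping takes the smallest-p unclaimed variant as an index and discards
unclaimed neighbours on the same chromosome within `window_kb` (default
10,000 kb) with r² > `r2_max` (default 0.001), repeating until no candidate
remains. P-value ties break lexicographically by variant id, so row order
can never change the output. The instrument F-statistic is computed as
(β/se)², equivalent to the usual r²-based approximation but independent of
allele frequencies, which are often missing from summary files; F < 10 is
excluded, F = 10 retained (the exclusion rule is strict).

## Allele harmonization

Exposure and outcome records are aligned on the exposure's effect allele:
identical codings pass through, swapped codings negate the outcome beta and
complement its frequency. Palindromic variants (A/T, C/G) are
strand-ambiguous; they are retained only when both studies' effect-allele
frequencies fall on the same side of 0.5 and outside the ambiguity band
`[0.42, 0.58]` (configurable via `palindromic_eaf_limit`; missing
frequencies drop the pair). Any other allele combination is incompatible.
All of these are statuses on the harmonized pair, not exceptions — dropped
pairs carry no estimates downstream but remain visible. Harmonization is
idempotent, and flipping an entire outcome file's allele coding leaves every
MR estimate unchanged (both are tested properties).

## Reverse-causation defenses

**Steiger filtering.** A valid protein instrument should explain more
variance in the protein than in the disease. Variance explained is computed
from the association z-score as $r^2 = z^2/(z^2+n-2)$ — the exact
identity between the squared t statistic and the squared correlation in
simple regression — summed over instruments per trait, with the
case-control side on the effective sample size
$4/(1/n_\mathrm{case}+1/n_\mathrm{control})$. The asymmetry is tested with
the independent-samples Fisher-z comparison of the implied correlations
(the two cohorts do not overlap in a two-sample design). A correct
direction with p < 0.05 passes.

**Bidirectional MR.** The disease is instrumented genome-wide under the
same selection criteria (no cis restriction) and its effect on the protein
estimated; p > 0.05 is read as no reverse causation. One subtlety matters:
a protein's own cis variant can reach genome-wide significance for the
disease *through* the protein, and if kept as a disease instrument it
mechanically converts the forward effect into an apparent reverse one. The
candidate disease instruments are therefore themselves Steiger-filtered —
a variant explaining more variance in the protein than in the disease is
removed before the reverse estimate. Without this step, every truly
forward-causal protein in our simulations was falsely vetoed; with it, the
reverse test retains its nominal 5% false-veto rate, which is inherent to
using a p > 0.05 rule and cannot be reduced without changing the rule.

## Colocalization

A significant MR hit can still be driven by LD between distinct causal
variants. For each shared variant the Wakefield approximate Bayes factor
against the null is computed in log space,

$$\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac{z^2 r}{2},
  \qquad r = \frac{W}{V+W},$$

with $V$ the squared standard error and $W$ the squared prior effect scale
(0.15 for quantitative traits on the per-SD scale, 0.2 for case-control
log-ORs — the conventional defaults, both configurable). The five
hypotheses are enumerated with per-configuration priors p1 = p2 = 10⁻⁴,
p12 = 10⁻⁵: H1/H2 sum single-trait Bayes factors, H4 sums the products at
the same variant, H3 sums products over distinct variant pairs (computed as
the difference of the product-of-sums and the H4 sum), and H0 is the unit
term. All sums use log-sum-exp; no raw Bayes factor is ever exponentiated,
so z-scores in the hundreds cannot overflow (tested). With a single shared
variant H3 is exactly zero. The posterior PPH4 > 0.7 (strict) calls a
shared causal variant. The published analysis this mirrors contains one
internal inconsistency — a target printed with PPH4 = 0.789 annotated as
failing the 0.7 rule — so the threshold is configurable and the replay
utilities can score either from the printed annotation or from the printed
posterior.

## Screens and the evidence verdict

The pleiotropy scan consults a local association catalog (a desk-local
stand-in for a phenotype-scanner service): instruments with catalogued
associations at p < 5×10⁻⁸ to the target disease or a configured list of
risk factors are dropped, and a protein whose instruments associate with
≥ 2 distinct catalogued proteins is flagged as a pleiotropy hub and
excluded as a target even though its estimate is still reported.

Replication re-estimates each discovery hit in an independent pQTL cohort
under two strategies — the discovery variants themselves (same-variant) or
instruments re-selected in the replication cohort (significant-variant) —
at the per-outcome threshold α divided by that outcome's discovery hit
count. A pass additionally requires direction concordance with discovery;
the published table implies but never states this, and without it a
significant reversal would count as support. Missing variants and
harmonization failures surface as `lack_of_data` / `incompatible_alleles`
statuses.

The phenome-wide screen estimates the protein's effect on every outcome in
a manifest at α/N and classifies significant effects by direction
consistency with the index disease: concordant means a drug against the
protein would also benefit the screened disease, discordant flags a
potential adverse effect.

The final verdict is a strict conjunction: `YES` only when discovery
significance, Steiger, bidirectional MR, the pleiotropy scan,
colocalization and both replication strategies all pass affirmatively.
Unknown flags (lack of data anywhere) veto, matching the published
handling of targets that could not be replicated.

## The synthetic-data generator

`simulate_panel` draws 0/1 haplotypes from a first-order Markov copying
process: site $j{+}1$ copies site $j$ with probability `ld_decay` and
otherwise draws a fresh allele at its own innovation frequency
(uniform on [0.1, 0.9]). Adjacent-site r² is therefore ≈ `ld_decay`² and
decays geometrically with distance, giving realistic clumping shadows;
frequencies stay bounded away from fixation, avoiding separation in the
logistic fits.

`simulate_two_trait_gwas` generates individual-level data for two
non-overlapping cohorts — genotypes drawn by pairing panel haplotypes, a
quantitative exposure with a cis causal variant explaining `h2_exposure`
of unit variance, and a case-control outcome from a logistic model at ~50%
prevalence with either a direct variant effect, an effect mediated through
the exposure (`mr_effect`, log-OR per SD), or reverse mediation through
disease status — and then reduces each cohort to per-variant marginal
summary statistics by **exact** regression: closed-form OLS for the
exposure and maximum-likelihood logistic fits for the outcome (the
likelihood collapses onto each variant's 3×2 genotype-by-status table, so
the fits are exact and fast). Computing marginals from the cohort rather
than from true effects plus noise is deliberate: LD-induced shadow
associations arise naturally, which is what makes the clumping and
colocalization tests honest.

What the generator does *not* emulate: human demographic history and
recombination hotspots, imputation error, population stratification,
sample overlap between cohorts, and genome-scale polygenicity. Passing
tests therefore demonstrate the statistical machinery's correctness and
calibration under clean two-sample assumptions, not robustness to those
real-data complications.

## Problem sizes and study conditions

The calibration defaults are fixed once: exposure cohort n = 7,213 (the
size of the primary pQTL cohort the design mirrors), case-control outcome
20,000/20,000, cis causal variant with h² = 0.05 and true log-OR 0.25 per
SD under forward causation, `ld_decay` 0.9, panels of 5,000 haplotypes;
colocalization scenarios use 200-variant regions and MR-calibration
scenarios 60-variant regions. Validation runs 200 replicates per
colocalization hypothesis, 500 forward-causal replicates (shared by the
effect-recovery and Steiger checks) and 1,000 null replicates for type-I
calibration. Full consortium scale (hundreds of thousands of cases) is not
simulated per replicate; the per-variant z² grows linearly in n (a tested
sanity regression), so calibration at this scale transfers.

The five-protein integration study (`simulate_study`) places each protein
on its own chromosome, adds one disease-susceptibility region so the
disease GWAS has instruments of its own for bidirectional MR, and gives
the causal protein a deliberately strong signal (h² = 0.1, log-OR 0.35)
— an integration demonstration, not a power analysis. Unlinked regions are
simulated on independent cohort draws; effects from other regions are
absorbed into residual noise, which leaves per-variant marginals
unchanged.

## Numerical choices and degenerate inputs

* Clumping and selection tie-breaks are lexicographic by variant id;
  output order is p-ascending — determinism is tested by shuffling input
  rows.
* `variance_explained` requires n > 2, the Fisher-z test n > 3; the
  summed r² per trait is capped below 1 before `atanh`.
* Monomorphic variants get r² = 0 off-diagonal (1 on the diagonal) in the
  LD panel and beta 0 / infinite se in the marginal scans, and are dropped
  when summary statistics are assembled.
* An empty instrument list, a chromosome absent from the stats, a region
  with no shared variants and a disease GWAS without genome-wide hits all
  surface as statuses or empty results, never crashes; the one hard input
  error is a colocalization call on an empty variant intersection.
* Every stochastic entry point takes an explicit seed, and pipeline reruns
  with the same config are byte-identical (tested).

## Known limitations

* With 1–2 instruments per protein there is no within-protein
  heterogeneity information: MR-Egger, weighted-median and modal
  estimators are out of scope by design.
* The Steiger comparison assumes non-overlapping cohorts; overlap-corrected
  variants are not implemented.
* Colocalization assumes at most one causal variant per trait per region
  (the classic enumeration); multi-signal fine-mapping approaches are not
  provided.
* The pleiotropy scan is only as good as the supplied catalog; it cannot
  discover associations the catalog lacks.
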