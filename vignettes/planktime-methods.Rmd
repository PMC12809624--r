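---
title: "Quantifying temporal community assembly with planktime: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal community assembly with planktime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktime)
```

# The question and the framework

A fixed-station microbial time series confounds two kinds of change:
deterministic selection, in which a shifting (or stable) environment
filters taxa by their traits, and stochastic processes — drift in
birth–death rates, and contingency on past states. `planktime`
separates them with a two-step null-model framework applied to every
pair of samples in a dataset (one site × size-fraction combination).

**Step 1, phylogenetic turnover.** The abundance-weighted beta mean
nearest taxon distance between samples $j$ and $k$ is

$$\beta\mathrm{MNTD}(j,k) = \frac{1}{2}\Big[\sum_{i \in j} f_{ij}\,
\min_{i' \in k} d(i,i') + \sum_{i' \in k} f_{i'k}\, \min_{i \in j}
d(i,i')\Big],$$

with $f$ within-sample relative abundances and $d$ patristic distances
on a rooted tree; a taxon present in both samples contributes zero. Its
null distribution comes from shuffling taxon labels across the entire
distance matrix — one permutation per randomisation shared by all
pairs, i.e. a regional-pool null — and the z-score
$\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{obs} - \mu_{null})/\sigma_{null}$
flags selection: $\beta$NTI > 2 means taxa turn over into *less*
related sets than chance (heterogeneous selection, the signature of a
changing filter), $\beta$NTI < −2 into *more* related sets
(homogeneous selection under a stable filter). This inference
presupposes phylogenetic conservatism of the selected trait: close
relatives must have similar niches for phylogenetic turnover to carry
information about selection. The synthetic generator builds exactly
that structure (below) so the presupposition holds where we test it.

**Step 2, taxonomic turnover.** Pairs not assigned to selection are
split by the Raup–Crick metric on Bray–Curtis dissimilarities. Each
randomisation reassembles every sample preserving its observed richness
and total count: taxa are drawn without replacement with probability
proportional to their occurrence frequency across the dataset, then the
remaining individuals are distributed multinomially with probability
proportional to dataset-wide mean relative abundance restricted to the
drawn taxa. With $n$ null values per pair,

$$RC_{bray} = 2\,\frac{\#\{BC_{null} < BC_{obs}\} +
\tfrac{1}{2}\#\{BC_{null} = BC_{obs}\}}{n} - 1 \in [-1, 1].$$

$RC_{bray} > 0.95$ is historical contingency (turnover beyond the
stochastic expectation: priority effects, disturbances),
$RC_{bray} < -0.95$ non-selective low turnover (unexpected
persistence), and $|RC_{bray}| \le 0.95$ ecological drift. The 0.95
cut is a two-tailed test at $\alpha = 0.05$ on the rescaled rank
statistic. Because the analysis is temporal (one station), the usual
spatial dispersal interpretations are deliberately renamed: nothing
here measures movement through space.

Tie handling uses the half-count rule, which makes the bounds exact:
a pair whose observed dissimilarity exceeds every null value scores
exactly +1, an identical pair with all-positive nulls exactly −1
(these two analytic facts are what `scripts/acceptance.R` recomputes).

## Degenerate nulls

When the null standard deviation is zero — a star-like phylogeny where
every shuffle is a no-op, or identical communities where observed and
all null $\beta$MNTD are zero — the z-score is undefined. `planktime`
records $\beta$NTI = 0 with a `degenerate` flag, so classification
falls through to the Raup–Crick branch. That is the semantically right
branch: a phylogeny carrying no signal cannot testify about selection.
Numerically, degeneracy is detected with a *relative* threshold
($\sigma_{null} \le 10^{-7}\mu_{null}$), because the running-sum
variance accumulates ~$10^{-8}$ cancellation noise on shuffle-invariant
inputs; an absolute cutoff would misread that noise as signal. The
relative form also preserves the framework's invariance to a uniform
rescaling of branch lengths.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_null` ($\beta$NTI, RC) | 999 (199 in demo fidelity) | randomisations | 999 is the standard protocol; 199 keeps desk-scale runs fast with a coarser p-grid |
| $\beta$NTI threshold | 2 | z-score | two-sided ~95% band of the null |
| RC threshold | 0.95 | rescaled rank | two-tailed $\alpha = 0.05$ |
| occupancy filter | 0.10 | fraction of samples | ASVs rarer than this cannot support a periodogram |
| PN threshold | 0.2 | fraction of variance | peak must explain ≥ 20% of series variance |
| seasonal p | 0.01 | permutation p | strict; requires `n_perm` ≥ 199 to be attainable |
| period window | [10, 14] | months | operationalises "about one year" |
| common occurrence | 0.5 (strict >) | fraction of site samples | majority presence at both sites |
| IndVal thresholds | 0.7 / 0.01 | stat / p | strong, significant site association |
| co-occurrence score | 0.5 | joint detection fraction | edges co-observed in under half the samples are unreliable |
| CLR pseudocount | 1 | counts | smallest mass preserving zeros' ordering |

# Seasonality on uneven time axes

Sampling is monthly but imperfect, so series live on a continuous axis:
days since the first sample divided by the mean Julian month
(30.436875 days). The classical Lomb–Scargle periodogram handles the
resulting unevenness without imputation. Power is normalised by the
series' total sum of squares, so a noiseless sinusoid scores ~1 and the
peak power PN reads as the fraction of variance explained — the
"standard" normalisation under which the PN > 0.2 threshold is
meaningful. The periodogram is therefore invariant to adding a constant
and to positive rescaling, which the test-suite asserts. The period
grid is uniform in frequency from 2 months to half the span with
4-fold oversampling: Nyquist-to-span coverage for ~41 monthly points.
Significance permutes observed values over fixed times, preserving the
sampling pattern while destroying temporal order. Peak month averages
relative abundance within calendar months across years; ties break to
the earliest month, deterministically.

# The synthetic two-observatory scenario

The generator's defaults are the study conditions used throughout the
recovery tests: 150 taxa, 41 monthly samples per site, 2000 individuals
per sample, immigration $m = 0.05$ from a uniform regional pool,
selection width $\sigma_{sel} = 0.5$ trait units, environmental
amplitude 3 (temperate) vs 0 (tropical) with period 12 months and noise
SD 0.25, and Brownian trait diffusion $\sigma_{BM} = 1$ on a Yule tree.
Monthly dynamics follow

$$w_i(t) \propto \Big(\frac{x_i(t-1)}{N}(1-m) + m\,\pi_i\Big)\,
\exp\!\Big(-\frac{(E(t)-\mu_i)^2}{2\sigma_{sel}^2}\Big), \qquad
x(t) \sim \mathrm{Multinomial}(N, w/\textstyle\sum w).$$

Choices worth recording:

- **The tropical site runs neutrally** (`selection_width = Inf`), not
  merely with amplitude 0. A constant environment under a finite
  selection width is *homogeneous selection*, not drift; since the
  scenario's truth label for that site is neutral drift, selection must
  actually be inert there. With selection inert the trait map provably
  cannot influence the output, which the suite checks by permuting
  traits under a shared seed.
- **Immigration 0.05** keeps the neutral site from collapsing to
  monodominance over 41 months while staying small enough that drift
  dominates month-to-month turnover; it is a scientist's-choice value,
  fixed once.
- **Uniform regional pool** by default (log-series optional): the
  simplest pool that keeps the null analytics transparent.
- **Two size-fractions**, when enabled, are independent multinomial
  draws from the same latent monthly weights — enough to exercise
  per-fraction pipelines without modelling cross-fraction coupling.

What the generator emulates: monthly cadence, uneven effort (optional
±20% depth variation), a seasonally forced vs a quasi-constant
environment, phylogenetically conserved niches, neutral drift with
immigration. What it does not: taxonomy, multi-year trends, episodic
blooms, interaction-driven dynamics (planted networks are structural
fixtures only), or within-month dynamics. Passing recovery tests
therefore shows the estimators detect the processes *when the
generating model matches their assumptions*; it cannot certify
behaviour on real data where, e.g., traits may be phylogenetically
labile or forcing non-sinusoidal.

# Diversity and PERMANOVA

Shannon uses natural logs (the vegan convention); Pielou is undefined
at richness 1 and reported missing; Faith PD includes the path to the
root, a convention that must simply be fixed — rooted input trees make
it well defined. Rarefaction is a single seeded draw per sample, with
the hypergeometric expectation $E[S] = \sum_i [1 - \binom{T-n_i}{d}/\binom{T}{d}]$
serving as the oracle in tests.

PERMANOVA is implemented directly as the McArdle–Anderson trace
partition (Gower-centred $-d^2/2$, sequential projection hats,
pseudo-F against free label permutations with
$p = (\#\{F^* \ge F\}+1)/(n+1)$, or the exact fraction under exhaustive
enumeration). The direct implementation exists for one numerical
reason: on perfectly separated fixtures the residual sum of squares is
floating-point noise, and tied "infinite" F statistics must compare
equal for the exhaustive p-value to be exact; residual SS below
$10^{-10}$ of the total therefore maps F to $+\infty$ explicitly, and
finite comparisons use a relative tolerance. On non-degenerate data the
implementation reproduces `vegan::adonis2` (same permutation matrix ⇒
identical R², F and p), which the suite asserts. Single-variable runs
are order-free; multi-term runs partition sequentially in the
user-given order, which is logged.

# Categories and networks

Occupancy ("occurrence") is the fraction of a site's samples — per
size-fraction, since fractions are analysed separately — with count
> 0 on the rarefied table; the strict > 0.5 boundary means exactly-half
occupancy is not "common". The headline category priority
(common > indicator > exclusive > background) is an artifact decision
for a single label; all flags are preserved, so an exclusive ASV
passing the indicator test is reported as an indicator with an
exclusive flag rather than losing either fact.

The co-occurrence score of an edge is operationalised as joint
detection frequency over all samples used in network construction — a
documented approximation, since the upstream inference tool's score is
not defined in terms available here. Monthly subnetworks follow the
detection rule exactly: a node is present in a month when its own
(fraction-specific) sample has abundance above zero, and an edge
survives when both endpoints do. Average path length ignores weights
and signs and averages over connected pairs only; mean positive
strength averages positive association scores over edges, not nodes.
Undefined metrics (assortativity with one category, path length on an
edgeless month) are reported missing with a machine-readable reason,
never silently dropped. Metric–environment screening uses Spearman
correlations on pairwise-complete months with Holm's step-down
correction across the whole tested family.

# Problem sizes and determinism

The test-suite runs the recovery analyses at the generator defaults
(150 taxa × 41 months × 2 sites, 199 randomisations/permutations) and
the calibration analyses at 12 samples × 50 taxa with pooled seeded
replicates — sizes chosen so the full suite completes in a few minutes
on one CPU while keeping the permutation p-value floors below the
strict thresholds they must clear. Every stochastic operation takes an
explicit seed and restores the caller's RNG state; pipeline stages
derive per-stage sub-seeds from one user seed, and rerunning the demo
with the same seed reproduces numeric outputs byte for byte.

# Known limitations

- ASVs absent from the input tree are dropped (with a logged count)
  from phylogenetic analyses only, and kept everywhere else; whether to
  discard them globally is a judgement the package leaves to the user.
- The Raup–Crick occurrence/abundance pools default to the analysis
  group (site × size-fraction); pooling across groups changes the null
  and is exposed as a choice, not silently made.
- $\beta$NTI's regional-pool null shares one permutation per
  randomisation across pairs; per-pair independent nulls are available
  behind a flag for sensitivity analysis but are quadratically slower.
- The Lomb–Scargle criteria assume one annual peak; multi-modal
  phenologies (e.g. spring + autumn blooms) can fail the period window
  despite being genuinely recurrent.
- Network inference and indirect-edge filtering are out of scope;
  static networks are inputs, and the bundled correlation-threshold
  builder is labelled plumbing for synthetic end-to-end runs only.
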