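---
title: "Methods: SSR fingerprinting of clonally propagated cultivars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR fingerprinting of clonally propagated cultivars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmSSR)
```

# The problem

Date palm and similar perennial crops are propagated vegetatively: a
cultivar is, ideally, a clonal lineage descended from a single seedling
kept because of its fruit quality. Collections therefore have an unusual
population-genetic structure — within a cultivar every tree should carry
the founder's exact diploid genotype, and because founders were selected
for heterosis, cultivars are typically heterozygous at most loci. Reality
adds noise: somatic one-step SSR mutations (variant clones), offshoots
planted under the wrong name (mislabels), cultivars that farmers
traditionally propagate by seed, and male pollinator trees whose varietal
origin is unknown because males are always raised from seed.

palmSSR treats a codominant SSR genotype table (two integer fragment
lengths in bp per locus per tree, plus cultivar/locality/sex labels) as its
single input currency and provides four analysis layers: diversity
description, genotypic distance geometry, identification keys, and
likelihood assignment of unknowns. A seeded simulator generates data with
exactly the structure above so that each layer can be verified against
ground truth.

# Diversity statistics

For a locus with allele frequencies $p_i$ estimated from the $2n$ allele
copies of $n$ trees with non-missing calls:

* $H_{obs}$ — fraction of heterozygous trees among the $n$ typed;
* $H_{exp} = 1 - \sum_i p_i^2$ — Hardy–Weinberg expected heterozygosity;
* $UH_{exp} = \frac{2n}{2n-1} H_{exp}$ — its small-sample unbiased form;
* $N_e = 1/\sum_i p_i^2 = 1/(1 - H_{exp})$ — effective allele number;
* $F = (H_{exp} - H_{obs})/H_{exp}$ — fixation index, undefined (reported
  `NA`) for monomorphic loci.

$F = -1$ is the clonal-heterosis signature (every tree heterozygous at a
two-allele locus); $F \approx 0$ indicates random mating, as in a
seed-propagated cultivar.

Two summary choices are deliberate and worth stating:

* **Group-level $F$ is the ratio of means**,
  $(\bar H_{exp} - \bar H_{obs})/\bar H_{exp}$ over loci (monomorphic loci
  included with $H = 0$), not the mean of per-locus $F$. The published
  per-cultivar diversity tables this package anchors to satisfy exactly
  this relation (e.g. the Halima row: $\bar H_{obs} = 0.750$,
  $\bar H_{exp} = 0.375 \Rightarrow F = -1.000$), so the ratio-of-means
  form is what `group_summary()` reports as `F`; the mean of per-locus $F$
  over polymorphic loci is reported alongside as `F_locus_mean`.
* **Monomorphic loci stay in the means** (contributing 0 to
  heterozygosities, 1 to $N_a$/$N_e$), and the polymorphic-locus
  percentage uses the full locus panel as denominator, so a group untyped
  at a locus is not silently dropped from `P_pct`.

A **fixed allele** is defined at cultivar level: an allele for which some
cultivar's non-missing calls are all homozygous. This is the only reading
under which a per-locus "fixed alleles" column with a cultivar list is
well defined, and it is how `fixed_alleles()` reports.

# Genotypic distances, PCoA, PhiPT, LD

Each diploid genotype at a locus is scored as an additive dosage vector
over the locus allele set ($A_iA_i \to 2$ at $i$; $A_iA_j \to 1$ at $i$
and $j$). The squared genotypic distance between two trees at one locus is
**one-half the squared Euclidean distance** between their dosage vectors,
giving values $\{0, 1, 2, 3, 4\}$ for the five possible configurations
(identical; het/het sharing one allele, hom/het sharing; het/het disjoint;
hom/het disjoint; hom/hom disjoint), and multilocus distance is the sum
over loci. The field's standard description of this statistic says
"one-half the Euclidean distance", but its own notation ($d^2$) and the
stated 0–4 range are only consistent with the squared form, which is what
the package implements.

Missing calls drop a locus for the affected pairs; an optional
`rescale = TRUE` multiplies by $L/L_{used}$ to keep distances comparable,
off by default because curated SSR panels are typically complete.

The cultivar-level matrix averages individual distances across all
cross-cultivar pairs, and its diagonal holds the mean pairwise
dissimilarity internal to each cultivar — exactly 0 for a pure clone line,
large for a seed-propagated cultivar. `ssr_pcoa()` embeds the off-diagonal
part only (the within-cultivar diagonal is descriptive, not a
self-distance in the embedding sense): Gower double-centering of $-D/2$
($D$ already being squared distances), eigendecomposition, coordinates
scaled by $\sqrt{\lambda}$. Percent variation is computed over positive
eigenvalues; negative eigenvalues (non-Euclidean input) are retained for
inspection, never silently truncated into the percentages.

**PhiPT** is the distance-matrix AMOVA analogue of $F_{ST}$:
$SS_{within} = \sum_g \sum_{i<j \in g} d^2_{ij}/n_g$,
$SS_{total} = \sum_{i<j} d^2_{ij}/N$, classical mean squares, and
$\Phi_{PT} = \sigma^2_{among}/(\sigma^2_{among} + \sigma^2_{within})$.
Significance comes from permuting individual group labels; p-values use
the add-one rule $(1 + \#\{\Phi^* \ge \Phi\})/(B + 1)$ so they are never
exactly 0. The permutation unit is the individual across groups (the
natural choice when the grouping being tested is the label itself).
The test oracle exploits that for scalar data with
$d^2_{ij} = (x_i - x_j)^2$ these sums equal classical one-way ANOVA sums
of squares, giving an independent closed-form check.

**LD screen.** The study design behind this package reports only that no
locus pair showed significant linkage disequilibrium, without naming a
method; for codominant unphased data the package uses a permutation test
whose statistic is the sum over allele pairs of squared covariances
between allele-dosage vectors, permuting one locus's genotypes across
individuals. This is a documented stand-in, not a reimplementation of any
specific published LD test.

# Identification keys

Cultivars, not individuals, are keyed: each cultivar is first reduced to a
modal **consensus genotype** per locus (ties break toward the
lexicographically smaller allele pair; the deviating fraction is surfaced,
with a warning above 0.2, since a seed-propagated cultivar has no
meaningful consensus). Alleles occurring among consensus profiles at the
key loci are labelled `a1…`, `b1…`, `c1…` ascending by fragment size.
`find_key()` searches subsets of size 1, 2, … exhaustively (up to
`exhaustive_limit`, default 4; $\binom{16}{4} = 1820$ subsets is trivial)
and returns the smallest subset whose profiles are all distinct, breaking
ties by fewer total labelled alleles, then lexicographic locus names.
Beyond the exhaustive limit a greedy forward selection is used and
documented as such. If nothing discriminates, the best-separating subset
is returned with `unique = FALSE` and the colliding cultivar groups. The
package does not attempt to reproduce any particular published three-locus
choice — selection criteria were never stated — only the uniqueness
property and the allele accounting.

# Likelihood assignment of unknown trees

Unknown (male) trees are assigned by single-parent likelihood. For query
genotype $g_o$ and candidate parental genotype $g_p$ at a locus with
frequencies $p$:

$$ T(g_o \mid g_p) = \sum_{a \in g_p} w_a \, \Pr(g_o \mid \text{gamete } a),
   \qquad w_a = \tfrac12 \text{ (1 if homozygous)}, $$

with the second gamete drawn from the population pool, and $P(g_o)$ the
HWE frequency ($2p_ap_b$ het, $p_a^2$ hom). The per-locus LOD contribution
is $\ln[((1-e)T + eP)/P]$: a Mendelian mismatch contributes the finite
$\ln e$ when the mistyping rate $e > 0$ (default 0.01), and $-\infty$ with
a warning when $e = 0$. The error model — "with probability $e$ the
observed genotype is an independent HWE draw" — is a deliberate
simplification of the full mistyping algebra of likelihood parentage
software; it preserves the two qualitative behaviours that matter here
(finite negative mismatch contributions, and negative LODs for candidates
sharing only very common alleles).

**Candidates** are the distinct multilocus genotypes observed within each
cultivar, so a cultivar with variant clones contributes several profiles —
which is how a reference panel of 18 cultivars can legitimately present
several dozen candidate profiles. The per-cultivar LOD is the maximum over
its own profiles (profiles of the same cultivar never penalize each
other), and $\Delta$ is the gap between the best and second-best
*cultivars*.

**Confidence calibration.** `simulate_critical_deltas()` draws `n_sim`
(default 10,000) synthetic offspring — a uniformly chosen candidate
contributes one gamete, the population pool the other, then per-locus
mistyping at rate $e$ — scores them against all candidates, and records
$\Delta$ and success. The critical $\Delta$ at confidence $c$ (0.95
strict, 0.80 relaxed) is the smallest threshold whose tail success
proportion reaches $c$ (0 if the whole set qualifies; $+\infty$ with a
warning if unreachable, as happens with indistinguishable candidates).

**Exact ties are unassignable.** When two cultivars achieve exactly equal
best LOD — which happens systematically when a mislabelled clone gives two
cultivars an identical candidate profile — no amount of confidence
calibration can pick between them, and any deterministic tie-break would
misassign every query from one side of the pair. Tied queries are
therefore reported with confidence `"none"`, and calibration counts tied
trials as failures. This is the one place the implementation refines the
plain $\Delta \ge \Delta_{crit}$ rule, and it is what keeps the strict
tier honest (≥ 95% correct among certified assignments) in the presence
of mislabels.

Remaining calibration caveats, stated rather than hidden: simulated true
parents are drawn uniformly across candidate *profiles* while real
unknowns arise per *cultivar*; the probability that the true parent is
outside the candidate list is fixed at 0. Both mirror the design of the
reference study, which evaluated only its listed cultivars.

# The synthetic generator

`sim_config()` defaults encode the stated world this package is built
for: 16 loci with 4–11 alleles on 2-bp ladders, Dirichlet(1) background
frequencies, 18 cultivars sampled 7–39 trees deep (the range of the
published per-cultivar sample sizes), one seed-propagated cultivar, 63
males, 1% typing error (the published mistyping setting). Where no value
was stated, a choice was made once and documented:

* `founder_het_prob = 0.5` — forced heterozygosity at half the loci plus
  the chance heterozygosity of free background draws (~0.7 at these
  diversities) leaves founders heterozygous at roughly 80–85% of loci,
  matching the published mean polymorphic-locus percentage (~82%).
* `variant_clone_rate = 0.02`, `mislabel_rate = 0.01` — "occasional":
  small enough that consensus profiles are unambiguous, large enough that
  variant clones and duplicated profiles actually occur in a default
  dataset.
* Variant clones mutate one allele by one step on the locus allele ladder
  (SSR stepwise mutation), producing the small nonzero within-cultivar
  dissimilarities seen in real clone collections.
* Males receive their non-maternal gamete from the oasis-wide background,
  not from the source cultivar, because orchard pollen is a mix from few,
  unselected male trees.
* The seed-propagated cultivar draws members as independent HWE genotypes
  from a 50/50 mixture of founder alleles and background — a pragmatic
  stand-in for open pollination over a few generations, tunable but not a
  demographic model.

Everything is a pure function of the config (seeded per stage), so
identical configs give identical datasets.

What the generator does **not** emulate: linkage and real chromosomal
structure (loci are independent, which is also the assumption of the
distance sum), genotyping artefacts other than whole-call replacement
(no allele dropout or stutter binning errors), locality structure beyond a
round-robin site label, and any demographic history behind the background
frequencies. A green parameter-recovery test therefore establishes that
the statistics recover what the generator planted — not that the generator
matches every property of field data.

# Numerical choices and degenerate inputs

* Allele identity is the exact integer fragment size; no automatic
  binning. Half-missing calls are rejected, not imputed; missing is
  explicit (`0` in the GenAlEx dialect, empty cells in tidy CSV).
* The GenAlEx layout stores only sample, population and calls, so
  locality/sex do not survive a GenAlEx round trip (tidy CSV round-trips
  everything, byte-identically).
* $F$ is `NA` for monomorphic loci/groups rather than 0 or $\pm\infty$.
* Permutation p-values use add-one smoothing; permutation streams are
  seeded and restore the caller's RNG state.
* PCoA treats eigenvalues below $10^{-9} \lambda_{max}$ as zero;
  coordinates are only produced for positive axes.
* Singleton cultivars get a within-cultivar dissimilarity of 0 with a
  `singleton` flag rather than `NaN`.
* Seeds derived for pipeline stages are kept inside the 32-bit signed
  range.

# Known limitations

* The LD statistic is a pragmatic dosage-covariance test, not a
  likelihood-ratio LD test; use it as a screen, not an estimator.
* The assignment model is single-parent only; joint mother–father
  parentage and exclusion-based approaches are out of scope.
* Allele frequencies for assignment come from the reference (female)
  panel, which is clone-inflated: frequencies are genotype-weighted, not
  lineage-weighted. This matches common practice for cultivar panels but
  overweights heavily sampled cultivars.
* The key is built on consensus profiles; a cultivar with within-cultivar
  variation above the warning threshold should be keyed with care (the
  warning is emitted, the key is still produced).
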