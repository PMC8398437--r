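---
title: "Methods: co-occurrence inference and grazing-preference analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence inference and grazing-preference analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagonet)
```

## The problem

Soil phagotrophic protists graze the microbiome and thereby shape soil food
webs, but their species-level interactions — intraguild competition,
predation, preferential grazing — are almost never observable directly in
field data. In species-poor, abiotically extreme soils (polar deserts being
the canonical case) co-occurrence patterns become a usable signal: with few
taxa and strong environmental gradients, a pair of OTUs that shares sites
far more or less often than chance deserves attention. `phagonet` implements
the full inference chain for such data: exact pairwise co-occurrence
testing, per-guild association networks, abiotic-versus-biotic variation
partitioning, MANOVA controls on individual associations, and a bacterial
palatability / growth-rate analysis of grazing preference. A synthetic
community generator with planted structure provides ground truth for every
stage.

Sites are rows and OTUs are columns everywhere; all containers carry
explicit id vectors. OTUs are genus-level units for eukaryotes and
family-level for bacteria, each labelled with one of eleven functional
groups (the five phagotrophic guilds — Cercozoa, Ciliophora, Amoebozoa,
Discoba, 'other phagotrophic protists' — plus Metazoa, Fungi, Chlorophyta,
Streptophyta, Stramenopiles, Bacteria).

## Exact co-occurrence model

Abundances are first normalized by the total-counts method (each site row
scaled to a common sum, correcting for uneven sequencing depth) and then
thresholded to presence/absence. The default presence threshold is 0 — any
non-zero normalized abundance counts as present — because no detection
floor is scientifically forced; the threshold is exposed for sensitivity
analysis. Note that total-counts normalization never changes the zero
pattern, so presence calls at threshold 0 are invariant to it.

For OTUs occupying $N_1$ and $N_2$ of $N$ sites, the probability of
observing exactly $j$ shared sites under random, independent placement is
hypergeometric:

$$P(j) = \frac{\binom{N_1}{j}\binom{N-N_1}{N_2-j}}{\binom{N}{N_2}}.$$

Two one-tailed tests are run per pair, both tails inclusive of the observed
count $j_{obs}$: $p_{gt} = \sum_{j \ge j_{obs}} P(j)$ flags aggregation,
$p_{lt} = \sum_{j \le j_{obs}} P(j)$ flags segregation, classified at
$\alpha = 0.05$ with a strict inequality. Pairs whose expected
co-occurrence $N_1 N_2 / N$ is at most 1 (inclusive at exactly 1) are
excluded from classification — their tails are uninformative — but retained
in the output with status `excluded`, since reporting needs them.

Numerics: binomial coefficients are evaluated as exact integer-valued
doubles (`choose`) for $N \le 25$ and in log space (`lchoose`) beyond, so
no floating factorial ever overflows. The test suite checks the tails
against exhaustive enumeration of all site subsets for every margin
combination up to $N = 12$.

No multiple-testing adjustment is applied by default, matching the
package's classical convention for this model; a Benjamini–Hochberg option
(`p_adjust = "BH"`) is available but off by default. With tens of thousands
of pairs, users should expect the significant set to contain false
positives at close to the nominal one-tailed rate; the exact test is
conservative (discrete tails), so the realized rate sits below $\alpha$.

## Guild networks

Significant pairs (aggregate or segregate) touching at least one OTU of a
focal guild form that guild's unweighted, simple, unipartite network; edges
carry only their sign (p-values are kept as optional metadata, not
weights). An edge linking two guilds appears in both guild networks but is
counted once in the global tally — the deduplicated convention; a
`dedup_global = FALSE` switch sums the per-guild panels instead, since
published totals do not always state which convention they use. Networks
export to GraphML (node attributes: functional group, lineage; edge
attribute: sign) and round-trip losslessly through igraph.

## Variation partitioning

For each response guild, the site-by-OTU abundance matrix $Y$ is regressed
on an abiotic block and a biotic block, and its variation is decomposed on
the adjusted-$R^2$ scale. With $R^2_{adj}$ from the three models (abiotic,
biotic, both):

- $a$ (abiotic-only) $= R^2_{adj}(full) - R^2_{adj}(biotic)$
- $c$ (biotic-only) $= R^2_{adj}(full) - R^2_{adj}(abiotic)$
- $b$ (shared) $= R^2_{adj}(abiotic) + R^2_{adj}(biotic) - R^2_{adj}(full)$
- $d$ (residual) $= 1 - R^2_{adj}(full)$

so $a+b+c+d = 1$ identically. RDA is implemented as multivariate least
squares of the centered response on the centered explanatory block, with
$R^2$ the fitted-to-total sum-of-squares ratio — algebraically the
constrained fraction of an RDA; the implementation is cross-checked against
`vegan::rda`/`vegan::varpart` in the test suite. The Ezekiel adjustment
uses the *rank* of the explanatory block, not its column count, and
negative adjusted fractions are reported as computed — no clamping
anywhere, since small-$n$ adjusted decompositions legitimately stray
outside $[0, 1]$.

**Collinearity screen.** Before partitioning, abiotic variables are
screened pairwise: offending pairs ($|r| > 0.70$) are visited in descending
$|r|$ and, within a pair, the variable with the larger mean absolute
correlation to everything else is dropped (ties break toward the later
column), repeating until clean. Variance inflation factors of the retained
set are reported and should sit below 10. The greedy rule is deterministic
and auditable; the report records every drop and its trigger.

**PLS biotic components.** A biotic grouping may contain more OTUs than
there are sites, so its presence/absence matrix is compressed by two-block
partial least squares (NIPALS, regression mode, centered, unscaled):
components maximize covariance between the predictor block and the protist
response abundances. Retention: at least the first two components, extended
until the cumulative covariance share reaches 50%, capped at
$\min(n_{sites}-1, n_{predictors})$. The "either the first two or enough
for 50%" phrasing admits two readings; the inclusive one (floor of two,
more if needed) is the default and a `strict_two` mode gives exactly two.
Covariance share is defined per component as the squared score covariance
normalized over all extractable components. To avoid circularity, the
response guild is always removed from its own explanatory set; the
`all_biota` block is everything except the response guild.

**Permutation tests.** Full-model fractions (a+b, b+c) are tested by freely
permuting site rows of $Y$; unique fractions (a, c) use residual
permutation under the reduced model (ter Braak): residuals of $Y$ on the
covariable block are permuted and added back to the reduced-model fit. In
both cases $p = (\#\{F^\pi \ge F\} + 1)/(n_{perm}+1)$. The reference
protocol uses 999 permutations; the analysis drivers default to 199, which
bounds the attainable p at 0.005 and keeps the 55-run suite fast — pass a
different count to `run_varpart_suite()` to change it.

The suite planner runs, per response guild, one all-biota partition plus
one per remaining single grouping: with all eleven groupings present that
is 10 subgroup runs per guild, 50 in total, plus the 5 all-biota runs.
Empty response groups are skipped with a logged reason.

## MANOVA controls on individual associations

A significant association may reflect shared habitat or dispersal rather
than interaction. Each pair's sites are labelled with co-occurrence states
(`11` co-present, `10`/`01` one present, `00` co-absent); the states form a
single (up to) four-level factor and are tested against two dependent
blocks in separate one-way MANOVAs: raw planar geographic coordinates
(dispersal limitation) and abiotic principal components (habitat
filtering). The abiotic block is standardized and compressed by PCA to the
smallest number of components reaching 90% explained variance (the target
is configurable; 90% is a conventional default the analysis states
explicitly).

Assumptions are checked *after* partitioning by state — the conservative
order: every analyzed state group needs more sites than dependent
variables, and each group must pass a Henze–Zirkler multivariate normality
test at $\alpha = 0.05$ (Mardia's skewness/kurtosis available as an
alternative). If any check fails, no statistic is reported and the pair is
`untestable` — with 18-site data this is the typical outcome, which is
itself informative about how conservative the control is. Otherwise
Pillai's trace and its F approximation are reported; with one dependent
variable the statistic reduces exactly to the one-way ANOVA F (asserted in
the tests to 1e-10). The Henze–Zirkler statistic uses the moment-matched
log-normal null; the implementation is validated in the tests against
frozen reference values from an independent implementation.

Verdicts: `biotic` when both MANOVAs are analyzable and both $p > 0.05$;
`abiotic_or_dispersal` when any analyzable test rejects; `untestable`
otherwise.

## Grazing preference

Each bacterial family in a significant association with a phagotrophic
protist is scored 0–3, one point per palatability-increasing trait:
gram-negative cell wall, nitrogen fixation, carbon fixation. Trait flags
are pure input data — the package deliberately hardcodes no
taxonomy-to-trait map, because published trait assignments involve
judgment calls that belong in the input table, not in code.

Growth rate is proxied by rRNA operon copy number, reported at genus level
by rrnDB-style databases; the family estimate is the mean and median over
the family's genera found in the database. Families with no genus in the
database, and OTUs resolved only above family rank, are excluded with
logged statuses. The chart's x-axis uses the family mean (the median is
carried alongside); richness of associated protists is counted as distinct
taxa at genus and phylum level, separately per association sign, because
the preferential-grazing signal of interest concerns the negative
associations specifically.

Kendall's tau-b (tie-corrected) correlates richness with either axis. The
p-value is an exact two-sided permutation enumeration for $n \le 10$
(implemented in C++; all $n!$ orderings) and the tie-corrected normal
approximation otherwise; both branches are validated against
`stats::cor.test` where its exact branch applies.

Interaction annotation applies two rules to significant pairs: segregate +
identical trophic role → `competitive_exclusion_candidate`; aggregate +
(consumer role, eligible prey) → `trophic_candidate`. The consumer→prey
eligibility map is an argument with a documented default (bacterivores eat
bacteria; cytophages eat protists; omnivores eat bacteria, protists,
metazoans, fungi). Pairs with missing role labels are skipped and logged.

## The synthetic community generator

The generator emulates the *shape* of an 18-site polar-desert survey, not
its biology: `mdv_like_preset()` emits 18 sites, 90 phagotrophic protist
OTUs across the five guilds, 80 bacterial families spanning 12 phyla, a
handful of metazoan/fungal/plant/stramenopile OTUs, matched trait and
copy-number tables, and ten planted pairs (7 aggregate, 3 segregate,
strengths 0.8–0.95).

Mechanisms, chosen for closed-form verifiability:

- **Null OTUs** occupy sites as independent Bernoulli draws with per-OTU
  occupancy drawn uniformly from [0.3, 0.7].
- **Planted pairs** couple per site: with probability $s$ (the strength)
  both OTUs threshold one shared uniform — comonotone for aggregates,
  antithetic for segregates — otherwise they draw independently. Marginals
  are preserved exactly and co-presence probability is
  $s\min(p_a,p_b) + (1-s)p_ap_b$ (aggregate) or
  $s\max(0,p_a+p_b-1) + (1-s)p_ap_b$ (segregate); at $s=1$ these are the
  Fréchet bounds, so a strength-1 segregate never co-occurs and a
  strength-1 segregate between OTUs whose occupancies sum above 1 is
  rejected as infeasible.
- **Environment-driven OTUs** shift occupancy along a latent standardized
  gradient on the logit scale (preset effect: 2.5 per SD); the same
  gradient leaks into moisture and total C so the abiotic table is
  realistically structured.
- **Abundances** conditional on presence are log-normal (meanlog 3,
  sdlog 1) — any positive continuous model suffices since downstream
  analysis is presence-based or normalization-invariant.
- **Collinear pair**: C:N is constructed from total C by exact
  orthogonalization so the sample Pearson r equals the target (preset
  0.85); distance-to-coast similarly tracks elevation above 0.70, giving
  the screen two pairs to act on, as in real dry-valley transects.

What the generator does *not* emulate: spatial autocorrelation and
dispersal kernels, phylogenetically correlated traits, compositional
(closure) artifacts of relative abundances, and indirect-interaction
structure. Passing the recovery and calibration suites therefore shows the
chain is correct and well calibrated under independent-site, planted-pair
conditions — not that real metagenome associations are interactions.

## Problem sizes and numerical choices

The validation suites run at sizes chosen to make their Monte Carlo
assertions stable: exact-tail enumeration over all margins up to $N = 12$;
null calibration on 500 disjoint independent pairs at 18 sites (call rate
$\le \alpha$; the exact test is conservative, so the assertion is an
inequality, not an approximation); planted recovery at strength 0.8 over
200 replicates per sign at 40 sites (power $\ge 0.8$; the mixture coupling
at these conditions was designed to sit well above that floor); the
four-fraction identity to 1e-10 on 100 random instances; driver
attribution on 100 abiotic-gradient replicates at 199 permutations; MANOVA
null calibration over 500 replicates (rejection within [0.03, 0.07]); and
a 1000-draw tau-b oracle battery. NIPALS iterates to a relative tolerance
of 1e-10; PCA/eigen comparisons assert 1e-10; tau-b against the brute-force
oracle asserts 1e-12.

Degenerate inputs are errors, not silent repairs: zero-sum site rows,
constant abiotic columns, categorical texture columns (encode fractions
instead), unmapped OTU ids, fewer than two OTUs or states. Circular aspect
is expanded to sine and cosine at ingestion because linear models cannot
consume degrees.

## Known limitations

- The co-occurrence model conditions on observed occupancy counts and
  assumes exchangeable sites; environmental filtering violates this, which
  is exactly why the MANOVA/variation-partitioning controls exist.
- PLS components are supervised by the response, so the biotic fraction's
  permutation test (scores held fixed under permutation) does not account
  for component selection and can be liberal; results for fraction c
  through `run_varpart_suite()` should be read comparatively, not as
  calibrated tests. The direct-matrix interface (`partition_variation()`)
  is calibrated and is what the acceptance suite checks.
- With 18 sites, most per-pair MANOVAs fail the post-partition assumption
  checks; this conservatism is by design.
- Exact tau-b enumeration is capped at $n = 10$; beyond that the
  tie-corrected normal approximation is used.
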