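---
title: "Scoring natural-product libraries for drug-likeness and drug-similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring natural-product libraries for drug-likeness and drug-similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large natural-product (NP) libraries — marine invertebrate metabolite
collections are the motivating case — contain far more compounds than can
be assayed. Triage needs a cheap, systematic ranking of how "drug-like"
each metabolite is. No single index captures this: property-histogram
scores (QED), likelihood-ratio scores (RDL), hard physico-chemical filters
(rule of five), predicted-toxicity summaries (ADMET-score) and
chemical-space or structural proximity to approved drugs all emphasise
different information, and they are only weakly correlated on real
libraries. `npdrugspace` computes all of them from common inputs and
combines them into a single summed drug index whose tails identify the
consistently drug-like and consistently un-drug-like metabolites.

Three compound categories structure every analysis: `drug` (the reference
set, e.g. approved small-molecule drugs), `np` (the library being
triaged), and `toxin` (a bioactive non-drug reference that controls for
"active but harmful" chemistry).

## The indices

**Eight properties.** All property-based scores use the same eight
molecular descriptors: molecular weight (MW, Da), the octanol:water
log-partition estimate (ALOGP), hydrogen-bond donor and acceptor counts
(HBD, HBA), topological polar surface area (PSA, Å²), rotatable-bond
count (ROTB), aromatic-ring count (AROM) and structural-alert count
(ALERTS). They are computed from 2D structures with Open Babel
(`ChemmineOB`) plus SSSR ring perception from `ChemmineR`; PSA is
topological (TPSA) because inputs are 2D. The aromatic-ring count is the
number of SSSR rings whose bonds are all aromatic — fused-system counting
is otherwise ambiguous, and SSSR is deterministic. Rotatable bonds are
non-ring single bonds between two non-terminal heavy atoms, amide C–N
excluded (the common convention). ALOGP is an atomic-contribution log P
model; different log P models disagree at the ±0.5 level, so
self-consistency across the three compound sets matters more than
agreement with any particular web service.

**QED** (quantitative estimate of drug-likeness) is the unweighted
geometric mean of eight per-property desirability scores,
$\mathrm{QED} = (\prod_{i=1}^{8} d_i)^{1/8}$. Each $d_i$ is a smoothed
histogram of the property over the reference drugs, normalised so its
peak is 1 and floored at $\varepsilon = 10^{-6}$: property values common
among drugs are desirable, tail values are not. The original QED fits
parametric asymmetric-double-sigmoid curves; this package uses the
histogram itself (Freedman–Diaconis bins on the drug sample, 3-bin
moving-average smoothing) because it is assumption-free and directly
reflects the reference sample. The floor keeps the geometric mean
strictly positive; reported QED values of 0 in tail classifications are
2-decimal rounded display values.

**RDL** (relative drug likelihood) replaces desirability with a
likelihood ratio. For each property, histogram densities $f_{drug}$ and
$f_{ref}$ (reference = the toxin set) are estimated on a shared grid with
pseudocount $10^{-9}$, and the relative likelihood is
$RL = f_{drug}/(f_{drug} + f_{ref}) \in (0, 1)$. RDL is the geometric
mean of the eight $RL_i$; values near 1 mean the property profile is far
more typical of drugs than of toxins.

**Rule of five.** The violation count over the four Lipinski thresholds
(log P < 5, MW < 500 Da, HBD < 5, HBA < 10), from 0 (most drug-like) to
4. The inequalities are strict as printed, so boundary values (MW exactly
500) count as violations.

**ADMET-score.** A weighted sum over 18 binary ADMET endpoints (1 =
predicted beneficial, 0 = harmful), $\sum_i w_{1i} w_{2i} w_{3i} v_i$,
where $w_1$ is the frequency of the beneficial value among reference
drugs (recomputed from whatever drug set is supplied), and $w_2$
(QSAR-model performance) and $w_3$ (endpoint importance) are inherited
from the upstream endpoint predictor. When no $w_2$/$w_3$ table is
supplied they default to 1 and this is logged — the package deliberately
does not invent model-performance numbers. Raw scores are standardised to
the drug range, $(raw - \min_{drug})/(\max_{drug} - \min_{drug})$, so
drugs span [0, 1] and other categories may fall outside; values are not
clipped. Endpoint QSAR prediction itself is out of scope: endpoint tables
are inputs. Whether $w_1$ should use the beneficial value or the majority
value is ambiguous in the source formulation; frequency-of-beneficial is
used.

## Chemical-space similarity

Descriptor tables (any continuous descriptor panel; the synthetic default
emulates a 51-variable ADME panel) are **drug-range scaled**:
$(x - \min_{drug})/(\max_{drug} - \min_{drug})$ per variable. Drug values
span [0, 1]; NP and toxin values may fall outside and the out-of-range
cell count is logged. PCA is run on the covariance of the scaled data —
no second z-scoring, preserving the scaled variables' relative spreads.
Variable contributions per axis are $100 \cdot \ell_{jk}^2 / \sum_j
\ell_{jk}^2$ (loadings $\ell$), so each axis sums to 100% and the
uniform baseline for $p$ variables is $100/p$ (1.96% at $p = 51$).

**PERMANOVA** tests category separation without dimension reduction:
with squared Euclidean distances, $SS_{total} = \frac{1}{N}\sum_{i<j}
d_{ij}^2$, $SS_{within} = \sum_g \frac{1}{n_g} \sum_{i<j \in g}
d_{ij}^2$, pseudo-$F = \frac{SS_{among}/(k-1)}{SS_{within}/(N-k)}$, with
the null built by uniform permutation of the label vector. The p-value
uses the $(1+b)/(1+m)$ estimator so it can never be 0 and is bounded
below by $1/(m+1)$. Whether the reference analysis ran the test on all
scaled variables or on PCA scores is not decidable from its description;
scaled variables are used (the test is rotation-invariant under full-rank
PCA anyway). An exact mode enumerates all distinct label arrangements for
small instances and is verified against an independent brute-force oracle
in the tests.

**Quantitative Jaccard (Ružička) similarity**, $\sum_j \min(x_j, y_j) /
\sum_j \max(x_j, y_j)$, measures proximity of a compound to each drug in
scaled descriptor space; averaging over drugs gives the compound's
distance to the centre of the drug cloud. It requires non-negative
inputs, so scaled values are clipped to [0, 1] first (count logged); an
all-zero pair is defined as identical (similarity 1). The identity
$J = 1 - 2B/(1+B)$ links it to Bray–Curtis dissimilarity $B$.

**Structural similarity** combines two Tanimoto measures. Atom-pair
fingerprints (the `sdf2ap`/`desc2fp` lineage, folded to 1024 bits) give
$T_{fp} = c/(a + b - c)$ over set bits; molecules that cannot be
fingerprinted are dropped with a report. The MCS Tanimoto uses the
maximum common induced subgraph of the two molecular graphs: atoms
matched by element, bonds by order-agnostic connectivity, hydrogens
excluded, connectivity of the common subgraph not required. It is found
exactly as a maximum clique on the modular product graph
(branch-and-bound); a per-pair time cap (default 5 s) returns the
best-found clique flagged as a lower bound when exceeded.
$T_{mcs} = |MCS| / (|A| + |B| - |MCS|)$ in heavy atoms. The combined
index is $T_{fp}^2 + T_{mcs}^2$ as printed in the source formulation;
whether a square root was intended (the Euclidean norm) cannot be
resolved, so `euclid` mode provides it while `sum_sq` stays the default.
Per-NP values are means over the (optionally subsampled, seeded) drug
set, memoised over unique structure pairs.

## The summed index

Five components enter the composite: mean Jaccard, mean combined
Tanimoto index, RDL, ADMET-score, and the Ro5 count. Each is
z-standardised over the scored compound set (population SD; the $n$ vs
$n-1$ choice is immaterial at library scale but fixed for
reproducibility), the Ro5 z-score is negated so positive always means
drug-like, and the five z-scores are summed. The dataset mean is 0 by
construction — which is why standardisation is computed over the ranked
library (the NPs) rather than pooled with the reference sets; a pooled
mode is available by passing the pooled vectors directly. QED is reported
alongside but excluded from the sum (it is negatively correlated with the
spatial measures and carries distinct information); external
target-database hit counts are likewise excluded.

Tail classification uses four corner regions of the (summed, QED) plane.
The default thresholds are the printed cut values of the motivating
analysis (summed > 2.42 with QED > 0.55; summed > 2.06 with QED = 0;
summed < −12.94 with QED = 0; summed < −2.6 with QED > 0.53, where
"QED = 0" means the 2-decimal rounded value). Those cuts are tails of one
particular library, so `quadrant_thresholds()` accepts any disjoint
rectangles and errors on overlap; percentile-based cuts are the sensible
alternative for other libraries. Corners take precedence over the
interior and every compound gets exactly one label.

## The synthetic-data generator

Real inputs for this kind of study come from subscription databases and
commercial descriptor software that cannot be redistributed. The
generator replaces them with statistical stand-ins that preserve exactly
the features the pipeline relies on:

- **Descriptor tables**: each category multivariate Gaussian (identity
  covariance) with mean `delta * u_g` along fixed orthogonal basis
  directions, so `delta` maps monotonically to expected PERMANOVA r².
  Defaults: 51 variables, `delta = 1`.
- **Property tables**: drugs unimodal around oral-drug-typical values
  (log-normal MW, median 350 Da, sdlog 0.35; Poisson counts; gamma PSA),
  NPs with a heavier MW tail (median 420 Da, sdlog 0.65) and broader
  lipophilicity, toxins with elevated alert rates (mean ALERTS 2.0 vs
  0.35 for drugs). These centres are conventional medicinal-chemistry
  magnitudes chosen once and documented here.
- **Endpoint tables**: independent Bernoulli per endpoint with beneficial
  probability 0.75 (drug), 0.85 (NP), 0.45 (toxin) — the NP > drug >
  toxin ordering the motivating comparisons report. Endpoint
  independence is assumed; no correlation structure is modelled.
- **Structures**: synthetic compounds are statistical records; when the
  structural-similarity components are needed, each compound is assigned
  a structure drawn with replacement from a curated list of well-known
  small molecules. No novel structures are generated.

Default sizes (200 drugs / 560 NPs / 200 toxins, full-scale ratios
divided by ten) keep a full pipeline run within about a minute; the
acceptance script scores 500 NPs. What passing tests on this data shows
is that the *pipeline* recovers configured differences in the configured
directions (QED and RDL medians: drug > NP; ADMET-score: NP > drug;
PERMANOVA size and power; composite recovery of a drug-like subgroup).
What it does not show: behaviour under real descriptor correlation
structures, multimodal property distributions, structure–property
coherence (synthetic properties are not computed from the assigned
structures), or fingerprint statistics of real chemical diversity.

## Numerical choices and degenerate inputs

- Desirability floor $10^{-6}$; RDL pseudocount $10^{-9}$; both keep
  geometric means strictly inside (0, 1).
- Degenerate histograms (all drug values identical) collapse to a single
  unit cell with the floor elsewhere.
- Values outside a fitted grid: QED evaluates to the floor (tails are
  undesirable by construction); RDL evaluates at the nearest boundary
  cell.
- Zero-variance components abort z-standardisation with the component
  named; variables constant over drugs abort scaling (or drop with a
  warning in lenient mode).
- All-zero vector pairs in Jaccard and empty-vs-empty fingerprints are
  defined as identical (similarity 1) and logged.
- Ties in the ranked report break lexicographically by id.
- SMILES entries that fail to parse are counted and reported, never
  silently dropped; a strict mode aborts instead.
- The shipped structural-alert file is a curated, hand-written subset
  (~40 patterns) of the published Brenk alert set; it is user-replaceable
  by any SMARTS pattern file, and alert counts are "distinct patterns
  matched", not total matches.

## Known limitations

- OpenBabel's log P and acceptor conventions differ from other
  descriptor packages at the margin; cross-package agreement is checked
  in the tests at tolerances reflecting those definitional differences.
- The exact MCS search is exponential in the worst case; large flexible
  molecule pairs will hit the time cap and return flagged lower bounds.
- LigPrep-style multi-structure averaging is not emulated: each input
  structure is scored as given, whatever tautomer/protonation state it
  carries.
- Quadrant thresholds are library-specific; reusing the defaults on a
  new library classifies against another dataset's tails.
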