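# npdrugspace

Drug-likeness and drug-similarity scoring for natural-product (NP)
libraries. Given three compound sets — reference **drugs**, the **NP**
library to triage, and a bioactive non-drug **toxin** reference — the
package computes the standard drug-likeness indices and chemical-space
similarity measures, and combines them into a single summed drug index
whose tails single out the consistently drug-like (and consistently
un-drug-like) metabolites.

## What it computes

Per molecule, from 2D structures and descriptor/endpoint tables:

| score | definition |
| --- | --- |
| **QED** | geometric mean of eight per-property desirability scores `(∏ dᵢ)^(1/8)`, each `dᵢ` a peak-normalised drug property histogram (MW, ALOGP, HBD, HBA, PSA, ROTB, AROM, ALERTS) |
| **RDL** | geometric mean of relative likelihoods `f_drug/(f_drug + f_ref)` over the same eight properties (reference = toxins) |
| **Ro5** | Lipinski violations: count of {log P < 5, MW < 500, HBD < 5, HBA < 10} not satisfied (0–4, strict thresholds) |
| **ADMET-score** | `Σ w₁ᵢw₂ᵢw₃ᵢvᵢ` over 18 binary endpoints, drug-range standardised; `w₁` = beneficial-value frequency among drugs |
| **Jaccard** | mean quantitative (Ružička) similarity `Σmin/Σmax` to every drug in drug-range-scaled descriptor space |
| **Tanimoto index** | `T_fp² + T_mcs²`: atom-pair fingerprint Tanimoto plus maximum-common-substructure Tanimoto, averaged over the drugs |
| **Summed index** | sum of the five z-standardised components (Jaccard, Tanimoto, RDL, ADMET, −Ro5); mean 0 by construction, tails classified into quadrants against QED |

Chemical space itself is characterised by drug-range scaling, covariance
PCA with per-axis variable contributions, and a PERMANOVA of the
category separation (pseudo-F, r², permutation p).

A synthetic-data module generates drug/NP/toxin libraries — shifted
multivariate descriptor clouds, unimodal drug property histograms with
heavier NP molecular-weight tails and elevated toxin alert rates,
category-specific ADMET endpoint rates — so the entire pipeline is
testable without subscription databases. See the methods vignette
(`vignettes/np-drug-likeness.Rmd`) for models, parameters and design
choices.

## Worked example

The `analysis/` scripts run the full study on a synthetic library
(200 drugs / 560 NPs / 200 toxins, seed fixed):

```sh
Rscript analysis/01_simulate.R   # tables -> results/
Rscript analysis/02_likeness.R
Rscript analysis/03_chemspace.R
Rscript analysis/04_composite.R
```

`02_likeness.R` prints, for this seed:

```
Likeness profiles for 960 compounds
  qed       medians: drug 0.615 | np 0.334 | toxin 0.400  (KW chi2 = 264.0, p = 4.71e-58)
  rdl       medians: drug 0.541 | np 0.477 | toxin 0.388  (KW chi2 = 230.8, p = 7.62e-51)
  admet_std medians: drug 0.551 | np 0.767 | toxin -0.120  (KW chi2 = 529.7, p = 9.38e-116)
  Ro5 >= 1 exceedance: drug 25% | np 56% | toxin 28%
  QED-RDL correlation (all compounds): 0.683
```

Drugs score highest on QED and RDL (their properties sit at the
reference histogram peaks), NPs exceed at least one Lipinski threshold
far more often (heavier MW tail), yet NPs beat drugs on the ADMET-score
(their endpoint beneficial-rates are set higher) — the
"not drug-like, but like drugs" pattern the indices are designed to
expose. `04_composite.R` then ranks the NPs:

```
Summed drug index over 560 NPs: mean -1.36e-16, SD 2.37
Quadrant counts:
consistent_druglike            interior            qed_only
                 22                 536                   2
```

The summed index has mean 0 by construction; its upper tail
(`consistent_druglike`: summed > 2.42 and QED > 0.55) is the shortlist a
triage campaign would take forward.

Library-scale scoring in code:

```r
library(npdrugspace)
cfg <- sim_config(n_drug = 200, n_np = 560, n_toxin = 200, seed = 1)
lib <- simulate_library(cfg)
res <- score_library(assign_fixture_structures(cfg), lib$properties,
                     lib$descriptors, bind_endpoint_tables(lib$endpoints),
                     time_cap = 1, drug_sample = 10, seed = 1)
head(res$report)   # ranked by summed index
```

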