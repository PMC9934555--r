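---
title: "Scoring TileSeq variant effect maps and calibrating clinical evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring TileSeq variant effect maps and calibrating clinical evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavescore)
```

## The measurement model

A TileSeq selection experiment observes, for every programmed variant, read
counts before and after competitive growth, in each of several replicates,
within short amplicon tiles sequenced deeply enough that parts-per-million
frequencies are measurable. The scoring model makes three assumptions:

* **Log-linear enrichment.** A variant's frequency change under selection is
  exponential in its growth-rate effect, so the log enrichment ratio is an
  affine function of fitness. This is what justifies anchoring the score
  scale on the nonsense and synonymous medians:
  `FS = ln(Φ/Φ_STOP) / ln(Φ_SYN/Φ_STOP)`, which maps the median nonsense
  variant to 0 and the median synonymous variant to 1.
* **Shared error floor.** Sequencing/PCR artifacts generate spurious counts
  at rates that are variant-specific but identical between the mutant pool
  and a wild-type-control template sequenced alongside. Hence the two-part
  treatment: frequencies within 3 control standard deviations of the control
  mean are indistinguishable from background and dropped, and the control
  mean is subtracted from retained frequencies.
* **Frequency-dependent noise.** Counting noise makes replicate disagreement
  a decreasing function of pre-selection frequency, which motivates the
  error-regularization prior described below.

Scoring is performed per region and per replicate (each mutagenized region
is an independent library with its own anchors), replicate scores are then
averaged, and the averaged map is re-anchored per region so that the
synonymous median is exactly 1 and the nonsense median exactly 0. That final
affine step is what makes the anchoring property exact by construction
rather than approximate; it is an identity transform whenever the replicate
medians already agree.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| background filter width | 3 | control SDs | separates real variants from the shared error floor |
| `max_se` | 0.3 | score units | removes scores too noisy to interpret |
| `min_freq` | 5e-5 | frequency (0.005%) | below this, subtraction leaves mostly noise |
| `min_cpm` | 10 | counts per million | "well-measured" bound on library representation |
| `terminal_exclusion` | 14 | residues | C-terminal truncations may retain function and would corrupt the nonsense anchor |
| `nu` | 2 | pseudo-replicates | weight of the error prior relative to the observed replicate SD |
| `pseudo_count` | 1 | reads | floor for fully depleted select frequencies |
| calibration prior | 0.10 | probability | prior probability of pathogenicity used by the evidence-threshold search |

All threshold comparisons are **inclusive on the retained side** (`≥ 3` SD,
`se ≤ 0.3`, `freq ≥ 0.005%`, `≥ 10` cpm). The source descriptions of these
rules mix strict and non-strict phrasing; a single convention avoids
boundary surprises and is covered by explicit boundary tests.

## Error regularization

With two replicates the observed standard deviation of a variant's score is
itself extremely noisy. We therefore shrink it toward a prior predicted
from variants of similar pre-selection frequency: the replicate SDs are
smoothed with a running median in log-log space, forced monotone
(non-increasing in frequency) by isotonic regression, and interpolated.
The posterior variance is

```
var_post = (nu * sd_prior^2 + (n - 1) * sd_obs^2) / (nu + n - 1)
```

with `nu = 2` pseudo-replicates, and the reported standard error is
`sqrt(var_post / n)`. Two limits sanity-check the estimator: when every
variant has identical replicate agreement the prior equals the observed SD
and no shrinkage occurs (`se = sd/sqrt(n)`), and a variant with zero
observed disagreement still receives a positive error pulled from its
frequency neighborhood. Variants with a single usable replicate fall back
to the prior alone.

## Depleted variants

A variant strongly depleted by selection can have a select-condition
frequency at or below the control background. Dropping such variants would
censor exactly the most interesting (null-like) part of the map, so their
adjusted select frequency is floored at one pseudo-read at tile depth and
the variant is flagged `select_floored`; its score lands near 0 as
intended. Variants whose *nonselect* frequency fails the background filter
carry `wt_indistinguishable` and are not scored, since their enrichment
denominator is meaningless.

## Cross-isoform assembly

The two isoform maps are both expressed in ubiquitous coordinates
(erythroid position + 17) on ingest, so that map comparison is
well-defined. Although per-region anchoring already places both maps on a
nominal 0–1 scale, differences in selection stringency bend the scale
between isoforms; the erythroid map is therefore rescaled by ordinary
least squares — the affine transform minimizing the mean squared score
difference over shared quality-passing variants. "Scale + offset" is the
default and a scale-only variant is available; with anchored maps the
fitted transform is close to the identity, and the closed-form fit is
verified in tests against both a grid search and the `lm`-equivalent
normal equations. Squared-error (rather than absolute-error) minimization
was chosen for its closed form; the difference only matters under gross
outliers, which the quality filters remove first.

Combined scores use inverse-variance weighting with
`σ²_combined = 1/(1/σ₁² + 1/σ₂²)`. (A combined-error expression that
simplifies to `σ₁² + σ₂²` circulates in descriptions of this design; it is
dimensionally inconsistent with the weighting and is treated here as a
typographical slip.) Variants present in only one isoform — including
ubiquitous positions 1–17, which have no erythroid image — enter the
combined map with their single-isoform score and error.

## Clinical calibration

Balanced precision replaces the reference-set class ratio with equal
priors: `BP = recall / (recall + FPR)`. It is invariant to duplicating
either class, which matters because curated positive sets are much larger
than negative sets in rare-disease genes. The curve is indexed by every
distinct score threshold under the rule "score below threshold predicts
pathogenic", with a final above-maximum threshold so recall reaches 1;
AUBPRC integrates the recall-sorted curve by trapezoid, anchored at recall
0 with the first defined balanced precision.

LLRp is the log10 ratio of Gaussian maximum-likelihood densities (mean and
population SD) fitted to the positive- and negative-set scores. Base 10 is
forced by consistency with the evidence-threshold scale: the calibrated
very-strong odds round to 350, and `log10 350 = 2.544` is the printed
very-strong threshold; halving the exponent per level gives
strong = 1.272, moderate = 0.636, supporting = 0.318, with benign
thresholds mirrored. Full precision is carried everywhere; two-decimal
display rounding of the moderate level is ambiguous (0.63 vs 0.64) and is
treated as presentation only.

The threshold search itself encodes the ACMG/AMP evidence-combining rules
as plain data (one row per combination, each with the posterior band it
must satisfy: >0.99 pathogenic, >0.90 likely pathogenic, <0.10 likely
benign, <0.01 benign). One deliberate design choice: the "two strong"
combination is constrained at the likely-pathogenic band rather than the
pathogenic band. On the exponent-halving scale with prior 0.10 that
combination can only reach pathogenic posterior at odds above ~891, which
would contradict the calibrated value of 350 that every other rule
supports; the framework this search follows makes the same observation and
accepts the two-strong combination at likely-pathogenic posterior. Users
who disagree can edit the rule table (`acmg_rule_set()`,
`write_rule_set()`) — the search then reports whatever that encoding
implies, or fails naming the binding rule. The "most conservative" odds is
the smallest satisfying value, found by integer grid search plus bisection
and rounded to two significant figures, with both raw and rounded values
reported.

For map evaluation, a configurable interval list can mask positions where
the assay is known to under-report pathogenic impact (default 160–215, a
region where rescue appears not to require the functions those residues
support). Masking is position-level: all variants at a masked position are
excluded, which is the stricter of the two possible readings and is
configurable.

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the scoring chain is
sensitive to: bimodal missense fitness with a 2.5% hyper-complementing
fraction (`w > 1` identifies exactly that class), synonymous fitness pinned
at 1 and nonsense at 0 (except the last 14 residues, where truncations are
generated as tolerated so the anchor-exclusion rule has something to do),
a mean of 1.7 amino-acid changes per clone spread over each mutagenized
region, log-normal library abundance (sdlog 0.5), deterministic competitive
selection through the growth map `g(w) = exp(r(w−1))` with `r = 1` over 3
generations (the assay's real selection strength in enrichment units is
not published; `r` and `generations` are free parameters chosen to give
clear nonsense/synonymous separation at the default depth), multinomial
tile sequencing, and a Poisson error floor (5e-6 per variant, the scale of
duplex-calling artifacts) shared in distribution with the wild-type
control. Every random draw comes from a named RNG stream keyed off the
seed, so identical seeds give byte-identical tables and streams are
independent across (tile, replicate, condition).

It does **not** emulate: read-level errors or FASTQ structure, PCR
jackpots/chimeras, codon-level NNK bias, linkage between multiple
mutations on one clone (marginal frequencies are treated independently
within tiles), or replicate-level biological drift beyond counting noise.
Consequently, passing parameter-recovery tests demonstrates that the
scoring chain correctly inverts the model it assumes — not that the model
captures every pathology of real libraries. The default scaled-down depth
is 200,000 reads per tile (the real-scale design uses ~2,000,000); tests
use 361-residue (default) and 60–80-residue (unit-test) proteins so the
full suite runs in seconds.

## Degenerate inputs and tie-breaks

* Anchor computation aborts a region (with a diagnostic) when fewer than 3
  usable nonsense or synonymous variants remain, or when the two anchor
  medians coincide.
* Rescaling falls back to the identity transform with a warning when the
  shared score set has zero variance.
* Density fitting refuses constant score sets (zero-variance Gaussian).
* `balanced_precision(0, 0)` is undefined and returned as `NA`; such
  points are dropped from the area integral.
* Evidence categories at exactly a threshold belong to the stronger
  category (comparisons are inclusive), mirroring the filter convention.

## Known limitations

* The aggregation order (per-replicate scores averaged after per-replicate
  anchoring, then re-anchored) is one of several defensible orders; it is
  pinned by the oracle test but other implementations may differ in edge
  cases.
* Scores are amino-acid-level only; nucleotide-level effects (notably
  splicing) are invisible to this design.
* The combined map's inverse-variance weights treat isoform errors as
  independent, which underestimates the combined error if systematic error
  components are shared.
* The imputation used before preference export (per-site median fill) is a
  documented stand-in for unspecified upstream processing; it can be
  disabled.
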